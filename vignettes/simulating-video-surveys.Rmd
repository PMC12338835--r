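---
title: "Simulating error propagation from detection models to biodiversity metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating error propagation from detection models to biodiversity metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maxnsim)
```

## The question

Remote cameras make it cheap to record communities and expensive to watch
the recordings. Automated pipelines — an object detector followed by a
species classifier — promise to close that gap, but both models err:
detectors miss individuals (imperfect recall) and hallucinate them
(imperfect precision), and classifiers mislabel what the detector found
(imperfect accuracy). `maxnsim` simulates the whole chain, from a known
multi-species community on a fixed 10-minute video to the biodiversity
metrics computed from pipeline outputs, so that the *bias* each error
source induces can be measured exactly — something impossible with real
videos, where the truth is unknown.

The estimator under study is MaxN: the abundance of a species is the
maximum number of its individuals visible simultaneously in a single
analysed frame. Total abundance, species richness and Hill–Shannon
diversity (the exponential of Shannon entropy, an effective species
number) are computed from MaxN vectors, and estimates are compared with
the truth through Jaccard (composition) and Bray–Curtis (abundance
structure) similarity.

## The ground-truth community model

A regional pool of 30 species is split into 8 groups spanning the range of
abundance and temporal behaviour seen in camera surveys
(`default_design()`): a group of 20 gregarious individuals present 20% of
the time in 5 bouts, two small-group species present 90% and 30% of the
time in 15 bouts, burst visitors (8 individuals in a single slot), and
several rare singletons down to one individual present 0.5% of the time.
Each video samples 15 of the 30 species (1–3 per group, uniformly within
group).

A species' timeline is built in four steps:

1. mean slot duration = occupancy seconds / number of slots;
2. each slot duration ~ Normal(mean, sd = sqrt(mean)), rounded to whole
   seconds (the simulation unit) and clamped to ≥ 1 s;
3. slots are placed left to right; the gap before each slot is drawn from
   a discrete uniform between 1 s and the free time still available after
   reserving one second of gap per remaining slot. This always packs, and
   for single-slot species it reduces to a uniformly random start — which
   is what makes the rarest species (a 3-second pass) stochastically
   missable at low processing rates. A rule whose lower bound grows with
   the number of remaining slots was considered and rejected: for the
   90%-occupancy group (15 slots, 60 free seconds) such bounds alone would
   require 120 s of gap, an infeasible packing.
4. each second of a slot shows `1 + Binomial(abundance − 1,
   presence_prob)` individuals: a presence slot always shows at least one
   animal (that is what makes it a presence slot), and each remaining
   group mate is on screen independently.

The default `presence_prob = 0.9034` is calibrated so a default video
exposes ≈ 5,295 fish instances at 1 fps (1284 + 4440·p instance-seconds in
expectation). Two properties of this "always ≥ 1" reading matter
downstream, and both were decisive in choosing it over a plain
`Binomial(abundance, p)` per-second count: the realized ground truth
equals the nominal 65 individuals in essentially every community, and a
species is undetectable at a given rate only when its slots fall between
analysed seconds — which yields mean detectable species of 14.40 (sd 0.65)
at 0.25 fps and 14.81 (sd 0.42) at 0.5 fps analytically, with all 15
species always detectable at 1 fps. A zero-capable binomial would instead
let whole rare-species slots go empty, making species undetectable even
when every frame is analysed.

Truth is simulated at 1-second resolution and expanded implicitly to
30 fps: all 30 frames of a second carry that second's counts, so
processing rates above 1 fps multiply the number of looks without adding
information — a deliberate property of the design.

## The pipeline model

For a configuration (fps, recall, precision, accuracy, threshold):

* **Frame subsampling** keeps the first frame of each second and spreads
  the rest evenly (`select_frames()`); rates below 1 fps keep the first
  frame of every 1/fps-th second.
* **Detection**: every individual on an analysed frame is found
  independently with probability `recall`; misses are gone for good. The
  number of background false positives is `round(TP × (1 − precision) /
  precision)` — so realized precision equals the configured one up to a
  single rounding — scattered uniformly over analysed frames.
* **Classification**: a detected individual keeps its true label with
  probability `accuracy`, otherwise receives one of the other 29 labels
  uniformly. Background false positives have no true class; the
  classifier always outputs a learned class, so they are labelled
  uniformly over all 30 — and every one of them is a misidentification.
* **Confidence threshold**: a misidentification is discarded ("unsure")
  with probability *p*, a correct identification with probability *p*/20;
  `NA` disables the step.
* **MaxN** per species = maximum per-frame count of retained labels.

`run_pipeline()` materialises every bounding box as a record and is the
reference implementation. `run_grid()` runs the same model through a
count-based engine (binomial detection counts per species-frame cell;
only mislabels and false positives become individual records; threshold
thinning as a binomial count plus uniform subset, which is exchangeably
identical to per-record Bernoulli draws). The two routes agree exactly
for error-free pipelines and distributionally under errors; the test
suite checks both. The full 14,406-configuration grid over 10 videos runs
in a few minutes on one CPU.

Sub-seeds are derived per stage and per cell from the master seed, so
detection draws are shared across all threshold (and precision, accuracy)
levels of a cell: comparing thresholds never re-rolls the detector.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `duration_seconds` | 600 | video length; 10 min trades temporal contrast against data volume |
| `record_fps` | 30 | recording rate; the 30-fold frame expansion is count-conserving |
| `presence_prob` | 0.9034 | per-second presence of each non-focal group mate; calibrated as above |
| `n_videos` | 10 | replicate surveys per experiment |
| grid levels | 7×7×7×7×6 | 0.25–30 fps; 0.60–0.99 recall/precision/accuracy; thresholds none, 0.80–0.99 |

## Degenerate inputs and conventions

Hill–Shannon diversity of an empty community is 0; Jaccard of two empty
sets and Bray–Curtis of two zero vectors are 1 (identical emptiness).
All three are flagged with warnings and arise only in extreme
configurations. Natural logarithm is used in the entropy, as the Hill
formulation requires. FP-count rounding is round-half-to-even (base R
`round`).

## What the generator does not emulate

No spatial structure, trajectories, bounding-box geometry or confidence
score distributions: the threshold step models score filtering directly
as the p / p-over-20 relabelling rule. Misidentifications are even across
species pairs; real confusion matrices are structured (look-alike species,
class imbalance), so real-world richness inflation can concentrate on
fewer species than simulated here. False positives are placed
independently and uniformly, while real ones cluster on confusing
background. Passing tests therefore validate the error-propagation
arithmetic, not any claim about a particular real detector.

## Problem sizes used in the tests

Unit tests run on single videos and small grids; the composition
uniformity check uses 3,000 draws, slot statistics 400–1,000 timelines,
detection/classification rates ≥ 10⁵ records (3σ binomial bands), and the
end-to-end suite includes the full 14,406 × 10 grid, which completes in a
few minutes. Stochastic comparisons with published means use 10–100
replicate videos with tolerances of two standard errors of the published
values.
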