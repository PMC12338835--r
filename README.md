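# maxnsim

Automated processing of camera-survey videos — an object detector followed
by a species classifier — promises to replace hours of expert screen time,
but both models make mistakes, and those mistakes propagate into the
biodiversity numbers conservation decisions are based on. `maxnsim` is a
simulation laboratory for quantifying that propagation: it generates
ground-truth fish communities on fixed 10-minute videos, pushes them
through simulated processing pipelines with controlled error rates, and
measures the bias of MaxN-based biodiversity metrics. It is aimed at
ecologists designing video-survey protocols and at computer-vision
practitioners deciding which model property (recall, precision, accuracy,
post-processing) is worth improving.

## The model in brief

A regional pool of 30 species in 8 groups (abundance 1–20, temporal
occupancy 0.5–90%, 1–15 presence slots) populates each video with 15
species. A species' per-second count within a presence slot is
`1 + Binomial(abundance − 1, 0.9034)`. A pipeline configuration is a
tuple (processing rate *fps*, detection recall *r*, detection precision
*q*, classification accuracy *a*, confidence threshold *p*):

* each individual on an analysed frame is detected with probability *r*;
* `round(TP·(1−q)/q)` background false positives are added uniformly;
* a detection keeps its true label with probability *a*, else gets one of
  the other 29 uniformly; false positives get any of the 30;
* a misidentification is discarded with probability *p*, a correct
  identification with probability *p*/20 (threshold "none" skips this);
* the abundance of species *s* is its MaxN,
  `max` over analysed frames of the count of retained labels *s*.

Estimates are scored with total abundance, species richness, Hill–Shannon
diversity `exp(−Σ pᵢ ln pᵢ)`, and Jaccard / Bray–Curtis
(`2Σmin(Nᵢⱼ,Nᵢₖ)/Σ(Nᵢⱼ+Nᵢₖ)`) similarity to the realized truth. The
default factorial grid crosses 7 rates × 7 recalls × 7 precisions × 7
accuracies × 6 thresholds = 14,406 pipelines over 10 replicate videos.

## Worked example

```r
library(maxnsim)

videos <- simulate_videos(10, seed = 1)
nominal_truth(videos[[1]])$nominal
#>  2  6  8  7 10 11 14 13 19 18 25 22 23 27 30
#> 20  2  2  2  8  8  8  8  1  1  1  1  1  1  1
hill_shannon(nominal_truth(videos[[1]])$nominal)
#> [1] 8.713867

g <- grid_spec(fps = 1, recall = 0.99, precision = 0.99, accuracy = 0.99,
               threshold = c(NA, 0.99), seed = 1)
summarize_grid(run_grid(g, videos))[, c("threshold", "total_abundance_mean",
                                        "richness_mean", "jaccard_mean")]
#> # A tibble: 2 x 4
#>   threshold total_abundance_mean richness_mean jaccard_mean
#>       <dbl>                <dbl>         <dbl>        <dbl>
#> 1      0.99                 65.7          15.7        0.957
#> 2     NA                    83            29.6        0.507
```

The ground truth is 65 individuals in 15 species (effective diversity
8.71). Even this near-perfect pipeline (recall, precision and accuracy
all 0.99) without post-processing inflates richness to ~30: its ~53 false
positives and ~52 misclassifications scatter across the whole learned
pool, so almost every absent species picks up at least one label. A 0.99
confidence threshold discards most of those wrong labels at the cost of
5% of correct ones, pulling abundance back to ~65 and Jaccard similarity
from 0.5 to ~0.96.

A command-line wrapper is installed with the package
(`system.file("exec", "maxnsim", package = "maxnsim")`) with subcommands
`simulate`, `run-grid` and `summarize`; see `?maxnsim_cli`.

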