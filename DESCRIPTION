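Package: maxnsim
Title: Simulating Error Propagation from Detection and Classification
    Models to Biodiversity Metrics in Video Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates fixed-camera community surveys and their automated
    processing by imperfect detection and species-classification models.
    Ground-truth multi-species abundance timelines are generated for
    10-minute videos from an eight-group community design, then pushed
    through simulated pipelines with controlled frame processing rates,
    detection recall and precision, classification accuracy, and
    confidence-threshold post-processing. Species abundances are estimated
    with the MaxN metric and the bias of total abundance, species richness,
    Hill-Shannon diversity, Jaccard and Bray-Curtis similarity is
    quantified across a full factorial grid of pipeline configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
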