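Package: bioticindices
Title: Presence-Based Biotic Indices and Trait Analysis for Stream
    Bioassessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bioassessment of running waters from benthic macroinvertebrate
    community matrices. Computes presence-based biotic tolerance indices
    (BMWP-Col, ABI, AAMBI and the derived average score per taxon) with
    ecological-condition classification, allocates functional feeding groups
    and summarises their composition, and computes Rao's quadratic entropy on
    feeding traits. Includes hand-implemented community statistics
    (Bray-Curtis dissimilarity, non-metric multidimensional scaling,
    PERMANOVA with pairwise FDR-adjusted post hoc comparisons, Spearman rank
    correlation), a packaged presence/absence data set from a high-Andean
    stream survey, and a synthetic community generator that plants a known
    disturbance gradient for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    vegan
VignetteBuilder: knitr
Config/testthat/edition: 3
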