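Package: pulmosphere
Title: Quantify Spheroid Invasion and Antifibrotic Drug Response in
    Pulmosphere Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the pulmosphere invasion assay, an ex-vivo model in
    which 3D spheroids derived from primary lung tissue are embedded in
    collagen and their outward cell invasion is measured. The package
    segments single-spheroid micrographs into a dense core (area R) and a
    total invaded region (area H), computes the zone-of-invasion statistic
    ZOI% = (H - R)/R * 100, scores per-patient drug response as the median
    treated/untreated ZOI% fold change (median < 1 defines a responder),
    attaches exact Clopper-Pearson confidence intervals to response rates,
    and reproduces the cohort-level analyses of such a study: nonparametric
    group comparisons, paired treated-versus-untreated tests, simple linear
    regressions against lung-function decline and matrix-protein expression,
    progressor stratification, and delta-delta-Ct relative expression. A
    synthetic-data module generates single-spheroid images with known
    ground-truth areas and whole cohorts with controlled effect sizes so
    every stage is testable without any experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
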