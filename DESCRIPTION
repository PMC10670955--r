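Package: uroquant
Title: Quantification Toolkit for Urothelial Barrier Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable, tested implementations of the quantitative procedures
    used in mouse bladder blood-urine-barrier experiments: urothelial
    nuclear-density estimation from two-channel fluorescence micrographs
    (band segmentation, nucleus detection with area-threshold filtering,
    medial-axis band-length measurement, threshold sensitivity analysis),
    Ussing-chamber transepithelial electrical resistance (TEER) processing
    and normalization, ROI-based fluorescence densitometry, and the
    small-sample statistics that accompany such studies (exact Mann-Whitney
    U testing, Shapiro-Wilk-routed two-group comparisons, qPCR negative
    delta-Ct, urinary potassium-per-creatinine normalization, and adjusted-p
    filtered deregulated-gene set logic). A synthetic-data module generates
    calibrated tissue phantoms, chamber traces and assay tables with exact
    ground truth so every stage is testable without microscope or animal
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
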