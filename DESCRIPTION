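Package: phenescan
Title: Spatial Tissue Phene Discovery and Survival-Based Patient
    Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery of prognostic image-based tissue biomarkers
    ("phenes") from object-level tissue maps. Rasterizes marker-labelled
    cell positions and classified gland polygons into micron-calibrated
    heatmaps, constructs a tumor-microenvironment region system (tumor,
    inner border, tight and wide outer borders, healthy glands, stroma),
    computes per-region measurement families (counts, densities,
    k-nearest-neighbour distances, gland co-occurrence texture), expands
    them into a named phene-candidate matrix, and mines the matrix
    against disease-free survival: minimum log-rank-p cutpoint
    optimization, leave-one-out cross-validated ranking with top-5
    robustness counts, accuracy and correlation filters, family-wise and
    false-discovery-rate multiple-testing correction, CART
    selection-frequency subset selection, permutation-based significance,
    and uni- and multi-variate patient stratification with Kaplan-Meier
    reporting. Includes a synthetic cohort generator with planted
    prognostic effects so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
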