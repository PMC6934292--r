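Package: cellhet
Title: Molecular and Spatial Heterogeneity Metrics for Multiplexed
    Single-Cell Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies intratumoral heterogeneity from spatially resolved
    per-cell marker-intensity tables such as those produced by multiplexed
    immunofluorescence (MxIF) segmentation workflows. Marker intensities are
    quantized into ordinal low/medium/high levels at the 33rd and 67th
    quantiles, concatenated over ordered cancer-hallmark marker sets into
    base-3 molecular state codes, and summarized per sample as a normalized
    Shannon entropy of molecular states.  A cell-contact neighbor graph
    (centers closer than 1.3 times the sum of the circle-equivalent radii)
    yields per-cell spatial states (same-state neighbor counts) and a
    normalized Shannon entropy of spatial states.  The package also provides
    the accompanying cell-phenotype workflow (winsorized, standardized
    log2 intensities; K-means over a range of K with silhouette, Calinski
    and consensus-clustering model selection; lollipop profiles and
    per-sample compositions), per-subject group comparisons (pooled t,
    Mann-Whitney, replicate correlation), low/medium/high multimodal
    discretization with hierarchical clustering, and a synthetic spatial
    cohort generator with known latent phenotype structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
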