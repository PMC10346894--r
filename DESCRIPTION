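Package: fcsweep
Title: Smoothing-Sensitivity Analysis for Group-Level fMRI Functional
    Connectivity
Version: 0.1.0
Authors@R:
    person("fcsweep", "maintainers", email = "fcsweep@example.org",
           role = c("aut", "cre"))
Description: Tools to study how the full-width-half-maximum (FWHM) of the
    Gaussian spatial smoothing kernel affects group-level functional
    connectivity analyses of 4D fMRI data. Provides a synthetic BOLD
    cohort generator with a planted block correlation structure, separable
    Gaussian smoothing with explicit boundary renormalization, ROI
    time-series extraction with Fisher-z correlation matrices and
    Benjamini-Hochberg FDR edge thresholding, five binary graph metrics
    (global/local efficiency, betweenness centrality, clustering
    coefficient, average path length), group PCA/ICA decompositions with
    per-component kurtosis and skewness summaries, and an orchestrated
    FWHM sweep over resting and task states. Includes a minimal NIfTI-1
    reader/writer so that images round-trip without external imaging
    dependencies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
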