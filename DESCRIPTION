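Package: phenofft
Title: Mode-of-Action Profiling of Live-Cell Imaging Time Series by
    Fourier Feature Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Phenotypic drug profiling from label-free live-cell imaging.
    Simulates per-cell trajectories of eleven morphometric and quantitative
    phase imaging parameters under drug mode-of-action archetypes
    (untreated control, microtubule stabilizer, microtubule disruptor),
    renders synthetic imaging fields (label mask, refractive-index map,
    optical-height map) and recomputes the parameters from them, reduces
    condition-level population time series to the dominant discrete Fourier
    amplitude and phase per parameter, and clusters treatment conditions by
    one-minus-Pearson correlation distance of the normalized Fourier feature
    vectors to recover mode-of-action groupings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    mclust,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
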