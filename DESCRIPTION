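Package: posthoclab
Title: Post-Hoc Labeling of Continuous M/EEG Recordings for Benchmarking
    Neural Decoding Methods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates noise-free, deterministically recoverable labels from
    arbitrary continuous magneto-/electroencephalographic (M/EEG) recordings by
    projecting the sensor signals onto a source subspace (anatomically
    constrained minimum-norm estimation or data-driven independent component
    analysis), extracting the band-power envelope of a selected source via the
    Hilbert transform, and discretizing it into epoch-wise classification or
    regression targets. Includes a linear forward-model simulator of
    pseudo-M/EEG with a planted narrowband oscillatory source among 1/f
    background activity, controlled label-noise models for regression and
    classification targets, reference implementations of common spatial
    patterns (CSP) with shrinkage-regularized linear discriminant analysis and
    source power comodulation (SPoC), and a benchmarking harness that sweeps
    dataset size, label noise and label variability under chronological
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
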