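Package: laminar
Title: Laminar Source Discrimination for MEG with an Empirical Bayesian Beamformer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether band-limited MEG activity originates
    from deep (white-matter) or superficial (pial) cortical laminae. Implements
    paired two-surface source spaces, an analytic spherical-conductor forward
    model for axial gradiometer arrays, the empirical Bayesian beamformer
    source inversion with ReML hyperparameter optimisation and free-energy
    model comparison, Morlet and multitaper time-frequency power, the
    ROI-based laminar discrimination statistic with exact Wilcoxon group
    inference, the associated perturbation controls (lead-field shuffling,
    co-registration error, trial subsampling, white-noise injection), and a
    synthetic-session generator with known laminar ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    MASS,
    igraph,
    yaml,
    jsonlite,
    xml2
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
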