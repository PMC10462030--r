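Package: retinodecode
Title: Bayesian Decoding of Natural Images from Retinal Ganglion Cell Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how populations of primate retinal ganglion cells
    (RGCs) encode natural images in the presence of fixational drift eye movements.
    Implements Linear-Nonlinear-Bernoulli encoding models with recurrent feedback and
    cross-cell coupling (LNBRC), fitted to 1 ms binned spike trains by alternating
    proximal-gradient (FISTA) optimization with L1 and group L2,1 regularization;
    approximate maximum a posteriori image reconstruction by half-quadratic splitting
    with pluggable Gaussian denoiser priors, including an exact 1/F spectral Gaussian
    prior; joint estimation of the stimulus image and an unknown fixational drift
    trajectory by expectation-maximization with a sequential importance resampling
    particle filter; spike-train analyses (PSTHs, shift-predictor-corrected
    cross-correlograms, spike-time perturbation, repeat shuffling); and valid-region,
    shift-searched multi-scale structural similarity (MS-SSIM) evaluation. A built-in
    synthetic retina (receptive-field mosaics, flashed and drift-jittered stimulus
    protocols, Bernoulli spike simulation) makes the full pipeline testable without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    splines,
    pracma,
    yaml,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
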