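Package: thalatrack
Title: Real-Time State and Parameter Estimation for Thalamocortical Relay Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a reduced three-variable conductance-based thalamocortical
    (TC) relay neuron in normal and Parkinsonian regimes, builds a cost-efficient
    piecewise-linear variant of the model whose slopes are representable by
    shift-and-add hardware arithmetic, and reconstructs the hidden gating
    variables (sodium inactivation h, T-type calcium de-inactivation w) and the
    injected current from noisy membrane-potential recordings with a
    2N-sigma-point unscented Kalman filter over the augmented state
    [I_ext, V, h, w]. Includes approximation-error criteria for the reduced
    model, observation-noise generators (Gaussian and mains-harmonic sinusoids),
    scripted robustness and double-blind estimation experiments, and a
    fixed-point arithmetic emulator for the shift-add evaluation path.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
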