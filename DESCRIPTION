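Package: ccmtools
Title: Convergent Cross Mapping for Causal Inference from Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and orients causal relationships between pairs of
    equally spaced time series using convergent cross mapping (CCM).
    Reconstructs shadow manifolds by time-delay embedding, predicts one
    series from the other's manifold by simplex projection (exponentially
    weighted nearest neighbours), quantifies cross-validated predictive
    skill as a Pearson correlation (rho_ccm), and uses the convergence of
    skill with library size as the operational criterion for causality.
    The embedding dimension E and the causal lag tau_p are tuned by cyclic
    coordinate descent, with an exhaustive (E, tau_p) sensitivity surface
    as the audit path, and Whitney bounds on the dimensionality of the
    underlying system are reported. Includes generators for coupled
    chaotic logistic maps and a noisy predator-prey oscillator with known
    causal structure, convergence-curve and sensitivity-surface plots, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    ggplot2,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
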