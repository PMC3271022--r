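Package: gmews
Title: Generalized-Model Early Warning Signals for Critical Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Anticipates critical transitions in ecological systems by
    estimating the Jacobian of a generalized model from short segments of
    time-series data. A generalized model fixes only the structure of a
    system (state variables, gain and loss processes, their dependencies)
    while leaving functional forms unspecified; the unknown Jacobian
    entries are recovered from observed states and process rates via
    one-sided finite differences, balance inference of unobserved
    processes, and assumption-based derivatives. Eigenvalues of the
    reconstructed Jacobian are tracked through time and a warning is
    raised when they trend towards the stability boundary, with the
    transition classified as a real-eigenvalue crossing (fold-like) or a
    complex-pair crossing (Hopf). Includes stochastic simulators for
    three test systems (an Allee-effect population under rising
    mortality, an annually observed harvested fishery with a hidden
    juvenile stage, and a tri-trophic food chain under rising
    top-predator mortality), ground-truth bifurcation location by
    numerical continuation, and rolling variance and autocorrelation
    baselines for comparison with statistics-based indicators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
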