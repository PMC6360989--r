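Package: titetrial
Title: Time-to-Event Isotonic Regression Designs for Phase I Dose Finding
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Implements the time-to-event isotonic regression (TITE-IR)
    phase I dose-finding design, which estimates per-dose toxicity
    probabilities from partially followed patients, smooths them with
    weighted isotonic regression (pool-adjacent-violators), and assigns
    doses under explicit escalation safety rules so that patients can be
    treated as soon as they enroll.  Also provides the classical 3+3
    design, Storer's up-and-down design D, and isotonic-regression designs
    with and without early stopping, together with a Monte Carlo harness
    for operating characteristics (probability of correct MTD selection,
    toxicity counts, sample size, trial duration, dose allocation),
    calibration of the conservatism offset, and a command-line interface
    for simulation and for dose recommendation in an ongoing trial.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
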