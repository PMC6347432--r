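Package: smrbci
Title: Simulation and Analysis of Sensorimotor-Rhythm BCI Screening Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse screening sessions for sensorimotor-rhythm
    (SMR) brain-computer interfaces. Generates synthetic multichannel EEG with
    class-specific mu/beta event-related desynchronization riding on 1/f background
    activity; implements variance-based artifact rejection, surface-Laplacian
    derivation, subject-specific frequency-band and time-interval selection by
    signed-r2 heuristics, Common Spatial Patterns by simultaneous diagonalization,
    shrinkage linear discriminant analysis, cross-validated and online-feedback
    evaluation, a nine-parameter rest-spectrum model yielding an SMR predictor, and
    rule-based categorization of users with group-level summaries.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
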