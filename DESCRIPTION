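Package: dialyzr
Title: Drug Dialyzability from a Rat Hemodialysis Model with Cross-Species Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies drug removal by hemodialysis in a miniaturized rat
    dialysis model and extrapolates it to patients. Provides the closed-form
    dialysis-adequacy metrics (dialyzer clearance with hematocrit correction,
    second-generation Daugirdas Kt/V), a dialysate-recovery drug removal rate
    with first-order time extrapolation, protein-binding and steady-state
    volume-of-distribution estimation by noncompartmental moment analysis,
    and four candidate cross-species prediction equations fitted by ordinary
    least squares and selected by adjusted R-squared. A two-compartment
    pharmacokinetic simulator with intermittent dialyzer clearance acting on
    the unbound drug fraction generates synthetic animal studies, including
    the post-dialysis rebound, for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
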