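Package: fpact
Title: Low-Dose First-Pass Analysis CT Myocardial Perfusion Timing and
    Quantification
Version: 0.1.0
Authors@R:
    person("FPA", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative myocardial perfusion measurement with the
    low-dose first-pass analysis (FPA) dynamic CT technique. Fits gamma-variate
    models to aortic time-density curves, extracts the base-to-peak timing
    landmark from the second derivative, and derives the injection-time-based
    acquisition rule (delay of half the injection time plus a fixed dispersion
    delay). Simulates bolus-tracking two-volume acquisition protocols,
    computes voxel-wise one-compartment FPA perfusion maps, performs CT
    dosimetry (SSDE, effective dose), and provides the agreement statistics
    (regression, Bland-Altman, Lin's concordance, paired t) used to validate
    the protocol. Includes a synthetic dynamic-CT phantom generator with known
    ground-truth perfusion so the whole pipeline is testable end to end.
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
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
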