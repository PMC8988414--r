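Package: coroflow
Title: Patient-Specific Windkessel Models of Coronary Artery Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lumped-parameter (Windkessel) electrical-equivalent modelling of
    patient-specific coronary trees. Builds resistance-compliance networks from
    vessel-segment tables (Poiseuille segment resistances, RC impedance
    magnitudes, a three-chamber distal boundary with activity-dependent distal
    resistance and Boyle's-law chamber compliance), solves them by exact
    series/parallel reduction with a general nodal solver as cross-check, and
    computes local flow at stenosis measurement sites by three routes: the
    solved network, invasive fractional flow reserve, and benchtop distal
    pressure. Includes Pearson and Bland-Altman method comparison, a seedable
    synthetic patient-cohort generator, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
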