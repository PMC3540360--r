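Package: beadpk
Title: Non-Compartmental Pharmacokinetics of Dual-Route Hepatic Irinotecan
    Delivery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing concentration-time data from studies that
    combine transarterial chemoembolization with irinotecan-eluting beads
    (DEBIRI) and intravenous irinotecan infusion. Provides body-surface-area
    based dose calculation, non-compartmental analysis (trapezoidal AUC,
    terminal-slope half-life, Cmax/Tmax, dose-normalized AUC to infinity,
    bioavailability as the ratio of dose-normalized exposures, and systemic
    or apparent clearance), closed-form two-compartment simulators for
    constant-rate infusion and for bead delivery modelled as an immediate
    bolus fraction plus slow first-order release (flip-flop kinetics),
    compartmental model fitting, a synthetic study generator reproducing the
    7-subject two-cycle crossover design with LLOQ censoring, and an
    end-to-end analysis pipeline with grouped summary reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
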