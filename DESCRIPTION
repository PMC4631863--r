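Package: mechcycle
Title: Enzyme Inhibition Mode Classification and Alpha-Amylase Assay Analysis
Version: 0.1.0
Authors@R: person("Mechcycle", "Maintainers", email = "maintainers@mechcycle.org", role = c("aut", "cre"))
Description: Classifies an enzyme inhibitor's mechanism (noncompetitive versus
    competitive/uncompetitive) from docking-derived equilibrium constants via a
    thermodynamic-cycle consistency test, and quantifies alpha-amylase
    inhibition from the starch-iodine assay: absorbance to activity units to
    percent inhibition to probit IC50 to molar Ki. Includes binding free energy
    and Cheng-Prusoff style constant conversions, one-way ANOVA with Fisher LSD
    post-hoc for group endpoints, and synthetic-data generators (labelled
    docking-constant sets, Michaelis-Menten kinetics based assay plates, and
    Gaussian group measurements) with known ground truth for end-to-end
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
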