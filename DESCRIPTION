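Package: pbpkheart
Title: Whole-Body PBPK Model with a Four-Compartment Heart Sub-Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Whole-body physiologically based pharmacokinetic (PBPK)
    simulator built around a four-compartment heart sub-model (epicardium,
    midmyocardium, endocardium and pericardial fluid) for predicting drug
    concentrations within cardiac tissue. Seventeen perfusion-limited
    compartments are integrated with LSODA; hepatic metabolism is scaled
    from in vitro CYP450 kinetics (Michaelis-Menten, IVIVE with MPPGL and
    ISEF), cardiac metabolism from heart CYP abundances, and renal
    clearance is fixed. Includes a two-stage weighted-least-squares
    parameter estimation workflow (absorption rate and rest-of-body
    partition coefficient against plasma data, then pericardial flow and
    pericardial-epicardial diffusion against heart-tissue data), a
    synthetic concentration-time data generator for end-to-end testing,
    and an amitriptyline reference parameterization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
NeedsCompilation: yes
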