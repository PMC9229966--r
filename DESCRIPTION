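Package: cephpbpk
Title: Whole-Body PBPK Models of Cefazolin and Cefuroxime for Surgical
    Prophylaxis in Obese and Pregnant Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Physiologically based pharmacokinetic (PBPK) modelling of the
    prophylactic cephalosporins cefazolin and cefuroxime in lean, obese,
    pregnant and obese-pregnant virtual populations. Implements a whole-body
    linear ODE disposition model with a permeability-limited adipose
    compartment (interstitial and intracellular water sub-pools),
    Rodgers-Rowland tissue partitioning for monoprotic acids, MDRD-based
    glomerular filtration, transporter-mediated tubular secretion (OAT1/OAT3
    with a gestational OAT3 activity polynomial, MRP4 efflux), Monte-Carlo
    virtual trials, time-above-MIC pharmacodynamic endpoints with
    incision-timing analyses, and the two-fold predicted/observed model
    acceptance procedure against packaged clinical comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
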