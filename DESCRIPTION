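Package: osteopkpd
Title: Coupled Pharmacokinetic-Pharmacodynamic Simulation of Bone Remodeling
    Under Antiresorptive Treatment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Material-point simulator of bone remodeling coupled to
    pharmacokinetic-pharmacodynamic (PK/PD) models of two antiresorptive
    drugs, the anti-RANK-L antibody denosumab and the bisphosphonate
    ibandronate. Bone-cell population dynamics of the Lemaire type are
    driven by pseudo-steady RANK/RANK-L/OPG and PTH receptor occupancies,
    modulated by a strain-based mechanical stimulus and by microdamage.
    Tissue state (bone volume fraction, mineralization ash fraction,
    fatigue microdamage and elastic modulus) is tracked daily under
    multi-dose schedules, reproducing dose-response and dosing-interval
    behaviour of trabecular, cortical and osteoporotic bone.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
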