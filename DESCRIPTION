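Package: tgskit
Title: Kinetic Target-Guided Synthesis Screening Analytics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis chain for kinetic target-guided synthesis (TGS)
    screening campaigns against a protein target: molecular-formula
    arithmetic and exact-mass enumeration of in-situ click (triazole)
    product libraries, construction and verification of orthogonal
    pooling designs, simulation of templated versus background product
    formation with LC-MS-like noise, ppm-tolerance feature matching and
    intersection-based hit deconvolution, four-parameter logistic
    dose-response (IC50/pIC50/Ki) analytics, non-compartmental
    pharmacokinetics and in-vitro ADME parameter estimation (microsomal
    clearance, plasma stability, Caco-2 permeability), and a simplified
    two-state SAXS conformational-mixture analysis (Guinier radius of
    gyration, open/closed volume-fraction fitting).
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
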