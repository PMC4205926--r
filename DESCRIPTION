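Package: visp
Title: Virtual Systems Pharmacology Simulation of Glucose-Lipid Metabolism
    and Antidiabetic Drug Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A desk-scale quantitative systems pharmacology toolkit built
    around a mechanistic whole-body model of glucose and lipid homeostasis
    in healthy and type-2-diabetic virtual patients.  The metabolic core is
    a deterministic ODE system (gut nutrient absorption, hepatic glycogen
    and gluconeogenic fluxes, insulin/glucagon/incretin regulation, renal
    glucose spill) coupled to compartmental pharmacokinetic sub-models for
    metformin and the GPR40 agonist fasiglifam (TAK-875, with
    enterohepatic recirculation), whose plasma exposures drive Hill-type
    multipliers on the physiological rates.  A model-agnostic simulation
    manager expands virtual-patient by therapy selections into batches of
    fully specified, text-serialisable simulation tasks, runs them in
    parallel, and computes clinical trial endpoints (fasting glucose and
    insulin, OGTT glucose AUC) from the simulated time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
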