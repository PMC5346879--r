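Package: clscale
Title: Size and Maturation Models for Scaling Clearance in Paediatric
    Pharmacokinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Systematic comparison of published models for scaling drug
    clearance by body size and age in children. Provides a catalogue of
    allometric and maturation model structures normalised to a 70 kg adult
    (fixed, estimated, stepwise and continuously varying allometric
    exponents; sigmoid-Emax, linear and exponential maturation functions),
    maximum-likelihood fitting of study-level clearance records under an
    exponential (log-normal) residual error model, AIC-based model
    comparison decomposed by age group, parametric-uncertainty simulation
    of typical clearance with confidence intervals and steady-state dose
    rates, visual predictive checks, and a synthetic study-level data
    generator for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
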