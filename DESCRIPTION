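Package: lungbrain
Title: Simulation and Analysis of PEEP Effects on Intracranial Pressure and
    Cerebrovascular Reactivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying lung-brain interactions under mechanical
    ventilation in a crossover animal design. Provides a seeded generator of
    multichannel physiological waveforms (arterial, intracranial, venous,
    airway and esophageal pressures) with configurable cerebrovascular
    reactivity and PEEP effects; a trend pipeline that coarse-grains
    waveforms to 0.1 Hz, rejects artifacts, and computes the pressure
    reactivity index (PRx), the compensatory reserve index (RAP),
    intracranial pulse amplitude (AMP) and cerebral perfusion pressure;
    respiratory-mechanics derivations (elastances, transpulmonary pressures,
    mechanical power) from end-inspiratory and end-expiratory occlusion
    holds; and the crossover statistical analysis (carry-over, sequence and
    period tests, two-way and repeated-measures ANOVA, baseline covariate
    screen) on per-period summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
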