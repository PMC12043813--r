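Package: pdrcea
Title: Markov Cohort Cost-Effectiveness Model for Proliferative Diabetic
    Retinopathy Treatments
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A cohort Markov model comparing intravitreal anti-VEGF drugs
    (ranibizumab, aflibercept, bevacizumab) and panretinal photocoagulation
    (PRP), alone or in combination, for treating proliferative diabetic
    retinopathy without diabetic macular oedema. Nine health states (eight
    10-letter bands of best corrected visual acuity plus death) evolve over
    3-monthly cycles from age 56 to a lifetime horizon with half-cycle
    correction and 3.5% annual discounting. Transition probabilities are
    derived from normally distributed annual acuity change; mortality uses a
    life table with a diabetes hazard ratio. Outputs are discounted costs,
    QALYs, net monetary benefit, a fully incremental cost-effectiveness
    frontier with extended dominance, probabilistic sensitivity analysis,
    and a deterministic scenario battery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
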