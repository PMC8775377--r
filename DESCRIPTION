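Package: glucosim
Title: Whole-Day Simulation of Glucose Homeostasis Under Diet and
    Physical Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates 24-hour plasma glucose dynamics in healthy,
    normal-weight adults with an extended Bergman minimal model coupling
    the classical glucose-insulin core to an exercise subsystem (hepatic
    glucose production, peripheral uptake, exercise-induced insulin
    removal, oxygen-consumption dynamics and glycogen depletion), a
    two-pool slow/fast carbohydrate meal bolus, and heart-rate-derived
    exercise intensity. Includes a Monte Carlo virtual-population
    generator, daily-schedule templating, a MET-based active/sedentary
    lifestyle classifier, and cohort-level analyses contrasting glucose
    dynamics with and without physical activity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
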