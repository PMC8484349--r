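Package: twogenfit
Title: Two-Generation Fitness Projection for Gregarious Egg Parasitoids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating the fitness consequences of clutch-size
    decisions in gregarious egg parasitoids across two generations. Projects
    grand-offspring (F2) fertility from first-generation clutch sizes via a
    declining clutch-size to fertility mapping, enumerates clutch
    configurations, distributes offspring over host eggs from empirical
    clutch-size frequencies, simulates factorial host-plant oviposition
    experiments (no-choice, choice, fictitious-host designs) with dish-level
    overdispersion, and reproduces the associated statistical comparison
    structure (LM, binomial GLM, binomial and Poisson mixed models with a
    dish random intercept, likelihood-ratio model comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
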