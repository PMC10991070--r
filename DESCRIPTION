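Package: irtforge
Title: Item Response Calibration and Automated Short-Form Test Construction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates pools of four-alternative forced-choice items with
    Rasch (1PL) and Birnbaum (2PL) item response models under a fixed
    guessing floor, diagnoses item fit (infit/outfit mean squares),
    reliability (KR-20, Andrich person-separation) and differential item
    functioning, and automatically selects an optimally sized,
    Rasch-conforming, difficulty-spread item subset by simulated annealing
    with an expected-log-predictive-density stopping rule. Includes
    counterbalanced trial-order generation with an age-of-acquisition
    difficulty gradient and a synthetic-cohort generator for recovery and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
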