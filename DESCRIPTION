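Package: sedprompt
Title: Just-in-Time Sedentary-Behavior Prompting Engine and Perioperative
    Activity Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a just-in-time adaptive intervention (JITAI) engine for
    disrupting prolonged sedentary behavior around major abdominal surgery:
    minute-level sedentary-bout accumulation from wearable step streams,
    symptom-tailored prompt thresholds (60 or 120 consecutive sedentary
    minutes depending on daily symptom severity ratings), wake-window gating,
    walk-response detection with positive feedback, wear-time filtering and
    adherence metrics, daily and phase-level sedentary-bout and step
    summaries, small-sample trial statistics (proportions, Pearson
    chi-square, two-sample t tests from summary statistics), and a
    deterministic synthetic perioperative cohort simulator for end-to-end
    testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
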