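Package: leashwalk
Title: Leash-Tension and Behavioral Analysis of On-Leash Dog Walks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing recordings from a canine leash tension meter
    together with coded behavioral observations and handler questionnaires.
    Converts raw force/direction traces into evenly sampled, tarred and
    smoothed series, detects pull events against a body-weight-scaled
    threshold with gradient-based burst splitting, attributes each pull to
    the dog or the handler from the accelerometer direction channel, and
    summarises walks into net/dog/handler tension metrics and pulling
    frequencies. Also summarises ethogram-coded point and state events,
    quantifies coder agreement with time-binned Cohen's kappa, scores a
    13-item exit questionnaire into two reverse-coded factors with
    Cronbach's alpha, and links personality to walk outcomes through linear
    mixed models with crossed random effects, bivariate screening, backward
    elimination with BIC tracking and variance-inflation-factor checks.
    Includes a synthetic-data generator producing traces with planted pull
    events, behavior logs, questionnaires and whole cohorts with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
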