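Package: ecoadl
Title: Ecological Assessment of Autonomy from Tracked-Person Activity Streams
Version: 0.1.0
Authors@R: person("EcoADL", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Recognizes instrumental activities of daily living (IADL) and
    walking tasks from tracked-person streams using constraint-based temporal
    event models, extracts gait and activity features into a per-participant
    behavioral profile, stages autonomy by completed-activity cut-offs, and
    classifies autonomy level and diagnosis group with a Gaussian naive Bayes
    classifier combined with best-first wrapper feature selection under
    stratified k-fold cross-validation. Includes a synthetic scene simulator
    that generates cohorts of track streams with known ground truth, plus
    Mann-Whitney and Spearman batch statistics over profile features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
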