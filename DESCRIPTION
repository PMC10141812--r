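Package: deceptrf
Title: Deception Detection from Facial Landmark and Pulse-Rate Time Series
Version: 0.1.0
Authors@R: person("deceptrf", "developers", email = "deceptrf@example.org",
    role = c("aut", "cre"))
Description: Extracts per-frame geometric facial features (brow, eye, iris,
    mouth geometry normalized by nasal-bridge length) and rolling-variance /
    event-count temporal features from facial-landmark tracker output and
    1 Hz wearable pulse-rate recordings, assigns per-frame deception labels
    from annotated utterance onsets, preprocesses (missing-value removal,
    quartile-fence outlier removal, class-balancing undersampling), and
    classifies deceptive speech windows with a random-forest classifier
    evaluated by stratified 10-fold cross-validation, including
    impurity-based feature-importance rankings. A synthetic session
    generator emulates all three input streams with configurable
    deception-window effects so the full pipeline is testable without
    human-subject recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    withr,
    optparse,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
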