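Package: pupilbound
Title: Pupil-Linked Arousal at Auditory Event Boundaries and Temporal Memory
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline linking tone-evoked pupil dilation to the
    temporal organization of episodic memory in an auditory event-boundary
    paradigm. Provides pupillometry preprocessing (artifact detection, linear
    interpolation, block exclusion, epoching, baseline correction), evoked
    dilation contrasts, temporal principal component analysis of pupil
    waveforms with Kaiser-normalized Varimax rotation, scoring of temporal
    order, temporal distance, and auditory source memory tests, and
    subtraction-score pupil-memory correlation and trial-level mixed-model
    analyses. A synthetic-data generator with known ground truth supports
    parameter-recovery testing of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
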