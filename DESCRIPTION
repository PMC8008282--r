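Package: oculoeffort
Title: Pupillary and Microsaccadic Measures of Cognitive Effort
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for task-evoked pupillometry and microsaccadic
    responses to cognitive effort under affective priming in multi-attribute
    decision making. Implements blink handling, binocular averaging, dispersion
    based fixation segmentation, velocity-threshold microsaccade detection with
    main-sequence validation, baseline-referenced pupil dilation (BCPD), the
    Low/High Index of Pupillary Activity (LHIPA), per-cue-epoch differential
    measures, and nested linear mixed models with likelihood-ratio tests.
    Ships a synthetic-experiment generator that reproduces the trial and effect
    structure of a cue-based decision task so the full pipeline can be exercised
    and validated without eye-tracking recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
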