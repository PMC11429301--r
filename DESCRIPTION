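Package: mgcexam
Title: Automatic Segmentation and Scoring of Telemedicine Myasthenia
    Gravis Examinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments a recorded telemedicine myasthenia gravis (MG)
    examination into the MG-ADL questionnaire window and the nine MG-CE
    test windows, working from abstracted data channels rather than raw
    video: a word-level speech transcript with timestamps and speaker
    labels, a per-frame gaze-direction stream, and a per-frame body
    landmark stream. Provides keyword-timestamp phrase search on the
    transcript, exact one-dimensional two-cluster splitting of
    instruction times, sliding-window gaze-class density segmentation of
    the ocular tests, armpit-angle gating for the arm extension test,
    head-height gradient peak detection for sit-to-stand, the
    categorical MG-CE item-scoring rubric, report generation with
    WebVTT export, an accelerated-review playback plan, a seeded
    synthetic-session generator with ground truth, and an evaluation
    harness for segmentation accuracy.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
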