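test_that("transcript JSON reads with unit conversion, sorting, speaker mapping", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    unit = "ms", session_id = "s1",
    words = list(
      list(text = "up", start = 2000, end = 2300, speaker = "A",
           confidence = 0.9),
      list(text = "look", start = 1500, end = 1900, speaker = "A",
           confidence = 0.8),
      list(text = "yes", start = 2500, end = 2700, speaker = "B",
           confidence = 0.7)
    )
  ), path, auto_unbox = TRUE)
  tr <- read_transcript(path)
  expect_equal(tr$text, c("look", "up", "yes"))  # sorted on load
  expect_equal(tr$start_s[1], 1.5)               # ms -> s
  expect_equal(tr$speaker, c("doctor", "doctor", "patient"))

  # multi-party calls collapse: examiner channel is the doctor, the rest
  # cannot be attributed and stay unknown
  jsonlite::write_json(list(unit = "s", words = list(
    list(text = "a", start = 1, end = 2, speaker = "A", confidence = 1),
    list(text = "b", start = 3, end = 4, speaker = "B", confidence = 1),
    list(text = "c", start = 5, end = 6, speaker = "C", confidence = 1)
  )), path, auto_unbox = TRUE)
  tr3 <- read_transcript(path)
  expect_equal(tr3$speaker, c("doctor", "unknown", "unknown"))
  expect_equal(tr3$start_s, c(1, 3, 5))  # unit = s honored
})

test_that("transcript edge cases: empty file, malformed JSON, negative times", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(unit = "ms", words = list()), path,
                       auto_unbox = TRUE)
  tr <- read_transcript(path)
  expect_s3_class(tr, "mgce_transcript")
  expect_equal(nrow(tr), 0)

  writeLines("{not json", path)
  expect_error(read_transcript(path), "malformed")

  jsonlite::write_json(list(unit = "ms", words = list(
    list(text = "x", start = -5, end = 10, speaker = "A", confidence = 1)
  )), path, auto_unbox = TRUE)
  expect_error(read_transcript(path), "negative timestamp")
})

test_that("transcript write/read round-trips at millisecond precision", {
  ses <- simulate_session(mgce_sim_config(seed = 7))
  path <- withr::local_tempfile(fileext = ".json")
  write_transcript(ses$transcript, path)
  back <- read_transcript(path)
  expect_equal(back$text, ses$transcript$text)
  expect_equal(back$start_s, ses$transcript$start_s, tolerance = 1e-3)
  expect_equal(back$speaker, ses$transcript$speaker)
  # a second round trip is exact
  path2 <- withr::local_tempfile(fileext = ".json")
  write_transcript(back, path2)
  expect_identical(read_transcript(path2), back)
})

test_that("gaze and pose CSV round-trip and validation", {
  g <- make_gaze(c("up", "up"), fps = 30)
  path <- withr::local_tempfile(fileext = ".csv")
  write_stream(g, path)
  g2 <- read_stream(path, "gaze")
  expect_equal(nrow(g2), 2)
  expect_equal(g2$label, c("up", "up"))

  ses <- simulate_session(mgce_sim_config(seed = 3, fps = 10))
  gsub <- gaze_stream(ses$gaze$t_s[1:100], ses$gaze$label[1:100],
                      ses$gaze$confidence[1:100], fps = 10)
  write_stream(gsub, path)
  back <- read_stream(path, "gaze")
  expect_equal(back$t_s, gsub$t_s, tolerance = 1e-3)
  expect_equal(back$label, gsub$label)

  ppath <- withr::local_tempfile(fileext = ".csv")
  psub <- ses$pose[1:100, ]
  write_stream(psub, ppath)
  pback <- read_stream(ppath, "pose")
  expect_equal(pback$y_0, psub$y_0, tolerance = 1e-3)

  # invariant violations are rejected
  bad <- psub
  bad$v_0[3] <- 1.2
  expect_error(pose_stream(bad), "visibility")
  readr::write_csv(tibble::tibble(t_s = c(0, 0.1), label = c("up", "up")),
                   path)
  expect_error(read_stream(path, "gaze"), "lacks column")
  expect_error(gaze_stream(c(0, 0.1, 0.1), rep("up", 3)),
               "strictly increase")
})

test_that("report JSON round-trips and WebVTT cues format correctly", {
  segs <- dplyr::bind_rows(lapply(mgce_tests(), detected_segment))
  rep0 <- mgce_report("empty", segs)
  jpath <- withr::local_tempfile(fileext = ".json")
  vpath <- withr::local_tempfile(fileext = ".vtt")
  write_report(rep0, jpath)
  export_webvtt(rep0, vpath)
  expect_identical(read_report(jpath)$segments, rep0$segments)
  expect_equal(readLines(vpath), "WEBVTT")  # no cues

  segs$start_s[segs$test == "ptosis"] <- 30
  segs$end_s[segs$test == "ptosis"] <- 90
  segs$status[segs$test == "ptosis"] <- "successful"
  segs$detectability[segs$test == "ptosis"] <- "full"
  rep1 <- mgce_report("one", segs)
  export_webvtt(rep1, vpath)
  expect_true("00:00:30.000 --> 00:01:30.000" %in% readLines(vpath))

  # full synthetic report with scores round-trips losslessly
  ses <- simulate_session(mgce_sim_config(seed = 11))
  rep <- segment_session(ses$transcript, ses$gaze, ses$pose)
  rep <- score_report(rep, list(
    ptosis_category = "no_ptosis", diplopia_onset_s = c(30, 45),
    cheek_category = "normal_seal", tongue_category = "full_convex",
    dysarthria_onset_count = Inf, drift_time_s = 100, sbc_count = 27,
    sts_category = "no_difficulty"
  ))
  write_report(rep, jpath)
  back <- read_report(jpath)
  expect_equal(back$item_scores, rep$item_scores)
  expect_equal(back$segments$start_s, rep$segments$start_s,
               tolerance = 1e-3)
  expect_equal(back$segments$status, rep$segments$status)
})

test_that("all reported intervals are valid and within the session", {
  ses <- simulate_session(mgce_sim_config(seed = 5))
  rep <- segment_session(ses$transcript, ses$gaze, ses$pose)
  seg <- dplyr::filter(rep$segments, !is.na(start_s))
  expect_true(all(seg$end_s >= seg$start_s))
  expect_true(all(seg$start_s >= 0))
  expect_true(all(seg$end_s <= max(ses$pose$t_s) + 1))
})
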