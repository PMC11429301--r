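test_that("ocular phase bounds come from keywords with sensible fallbacks", {
  dict <- default_dictionary()
  words <- c(rep("chat", 10), "look", "up", "at", "the", "ceiling",
             rep("hold", 20), "now", "puff", "your", "cheeks")
  tr <- clean_transcript(make_tr(words, gap = 1))
  b <- ocular_phase_bounds(tr, dict, adl_end = 5)
  expect_equal(b[1], find_phrase(tr, "look up")$t_s)
  expect_equal(b[2], find_phrase(tr, "puff your cheeks")$t_s)

  # no ocular keyword: phase starts at the questionnaire end
  tr2 <- clean_transcript(make_tr(c(rep("chat", 10), "puff", "your",
                                    "cheeks"), gap = 1))
  b2 <- ocular_phase_bounds(tr2, dict, adl_end = 3)
  expect_equal(b2[1], 3)
  expect_equal(b2[2], find_phrase(tr2, "puff your cheeks")$t_s)

  # neither keyword: fixed-length fallback
  tr3 <- clean_transcript(make_tr(rep("chat", 8), gap = 1))
  expect_equal(ocular_phase_bounds(tr3, dict, adl_end = 2), c(2, 362))

  expect_error(ocular_phase_bounds(tr3, dict, adl_end = 100),
               "unusable")
})

test_that("gaze density is exact on degenerate streams", {
  all_up <- make_gaze(rep("up", 100), fps = 10)
  expect_true(all(gaze_density(all_up, "up")$density == 1))
  expect_true(all(gaze_density(all_up, "left")$density == 0))

  alt <- make_gaze(rep(c("up", "neutral"), 50), fps = 10)
  d <- gaze_density(alt, "up")$density
  interior <- d[26:75]
  expect_true(all(abs(interior - 0.5) < 0.02))
})

test_that("gaze density equals the brute-force recount on random streams", {
  set.seed(99)
  g <- make_gaze(sample(c("up", "left", "right", "neutral", "no_value"),
                        300, replace = TRUE), fps = 10)
  for (lab in c("up", "left", "right")) {
    expect_equal(gaze_density(g, lab)$density, oracle_density(g, lab),
                 tolerance = 1e-12)
  }
})

test_that("class densities conserve the window count", {
  set.seed(5)
  g <- make_gaze(sample(c("up", "left", "right", "neutral", "no_value"),
                        200, replace = TRUE), fps = 8)
  total <- Reduce(`+`, lapply(c("up", "left", "right", "neutral",
                                "no_value"), function(lab) {
    gaze_density(g, lab)$density
  }))
  expect_equal(total, rep(1, 200), tolerance = 1e-12)
})

test_that("longest dense segment follows the worked examples", {
  flat <- tibble::tibble(t_s = 0:99, density = 0)
  expect_null(longest_dense_segment(flat))

  bump <- tibble::tibble(t_s = 0:99,
                         density = ifelse(0:99 >= 20 & 0:99 < 70, 1, 0))
  seg <- longest_dense_segment(bump)
  expect_equal(seg$start_s, 20)
  expect_equal(seg$duration_s, 50)

  two <- tibble::tibble(
    t_s = 0:99,
    density = ifelse((0:99 >= 5 & 0:99 < 25) |
                       (0:99 >= 50 & 0:99 < 90), 0.8, 0))
  seg2 <- longest_dense_segment(two)
  expect_equal(seg2$start_s, 50)  # the 40 s bump beats the 20 s bump
})

test_that("longest dense segment equals the exhaustive run scan", {
  set.seed(17)
  for (i in 1:30) {
    cv <- random_curve(n = sample(30:150, 1))
    got <- longest_dense_segment(cv)
    want <- oracle_longest_run(cv)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$start_s, want$start_s)
      expect_equal(got$duration_s, want$duration_s)
    }
  }
})

test_that("detectability boundaries are closed at 10 and 45 seconds", {
  expect_equal(classify_detectability(8), "none")
  expect_equal(classify_detectability(30), "partial")
  expect_equal(classify_detectability(50), "full")
  expect_equal(classify_detectability(10), "partial")
  expect_equal(classify_detectability(45), "partial")
  expect_equal(classify_detectability(45.001), "full")
  expect_equal(classify_detectability(NULL), "none")
  # monotone in duration
  dur <- seq(0, 60, by = 0.5)
  lvl <- match(vapply(dur, classify_detectability, character(1)),
               c("none", "partial", "full"))
  expect_true(all(diff(lvl) >= 0))
})

test_that("ocular segmentation recovers scripted holds by gaze class", {
  ses <- simulate_session(mgce_sim_config(seed = 4, noise = "none"))
  truth <- ses$script
  ocu <- truth[truth$test %in% c("ptosis", "diplopia_right",
                                 "diplopia_left"), ]
  phase <- c(min(ocu$start_s), max(ocu$end_s) + 5)
  oc <- segment_ocular(ses$gaze, phase)
  for (test in c("ptosis", "diplopia_right", "diplopia_left")) {
    row <- oc[oc$test == test, ]
    expect_equal(row$detectability, "full")
    expect_lt(abs(row$start_s -
                    truth$active_start_s[truth$test == test]), 1)
    expect_lt(abs(row$end_s - truth$active_end_s[truth$test == test]), 1)
  }

  # assignment is by gaze class: removing left frames only loses that test
  g2 <- ses$gaze
  g2$label[g2$label == "left"] <- "neutral"
  oc2 <- segment_ocular(g2, phase)
  expect_equal(oc2$detectability[oc2$test == "diplopia_left"], "none")
  expect_equal(oc2$detectability[oc2$test == "ptosis"], "full")
})

test_that("segments survive 20% gaze wander within 5 s of truth", {
  ses <- simulate_session(mgce_sim_config(seed = 21, gaze_misclass = 0.2,
                                          fps = 30))
  truth <- ses$script
  ocu <- truth[truth$test %in% c("ptosis", "diplopia_right",
                                 "diplopia_left"), ]
  phase <- c(min(ocu$start_s), max(ocu$end_s) + 5)
  oc <- segment_ocular(ses$gaze, phase)
  for (test in c("ptosis", "diplopia_right", "diplopia_left")) {
    row <- oc[oc$test == test, ]
    expect_lt(abs(row$start_s -
                    truth$active_start_s[truth$test == test]), 5)
  }
})

test_that("the toy gaze classifier meets its contract on synthetic eyes", {
  set.seed(8)
  labs <- c("up", "left", "right", "neutral")
  train_labels <- rep(labs, each = 120)
  train <- lapply(train_labels, render_eye_region)
  clf <- toy_gaze_classifier(train, train_labels)

  test_labels <- rep(labs, each = 40)
  test_imgs <- lapply(test_labels, render_eye_region)
  stream <- classify_gaze(test_imgs, clf, fps = 30)
  acc <- mean(stream$label == test_labels)
  expect_gte(acc, 0.95)

  # frames at or below the confidence threshold are recorded as no_value
  expect_true(all(stream$label[stream$confidence <= 0.95] == "no_value"))
  ambiguous <- 0.5 * render_eye_region("neutral", noise_sd = 0) +
    0.5 * render_eye_region("left", noise_sd = 0)
  amb <- classify_gaze(c(test_imgs, list(ambiguous)), clf, fps = 30)
  low <- amb$confidence <= 0.95
  expect_true(all(amb$label[low] == "no_value"))

  # a centered pupil is neutral
  centered <- lapply(1:10, function(i) render_eye_region("neutral"))
  expect_true(mean(classify_gaze(centered, clf)$label %in%
                     c("neutral", "no_value")) == 1)

  expect_error(toy_gaze_classifier(train[1:10], rep("up", 10)),
               "at least 2")
})
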