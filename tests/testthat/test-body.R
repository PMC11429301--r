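# independent oracle: angle via atan2 of cross/dot products
atan2_angle <- function(a, b) {
  abs(atan2(a[1] * b[2] - a[2] * b[1], sum(a * b))) * 180 / pi
}

one_frame_pose <- function(coords, vis = 0.95) {
  cols <- list(t_s = 0, present = TRUE)
  for (id in names(coords)) {
    cols[[paste0("x_", id)]] <- coords[[id]][1]
    cols[[paste0("y_", id)]] <- coords[[id]][2]
    cols[[paste0("v_", id)]] <- vis
  }
  pose_stream(tibble::as_tibble(cols), fps = 30)
}

test_that("armpit angles match the geometry on canonical poses", {
  # T-pose: arms horizontal, torso vertical -> 90 degrees
  tpose <- one_frame_pose(list(
    `0` = c(0.5, 0.3), `11` = c(0.4, 0.4), `12` = c(0.6, 0.4),
    `13` = c(0.2, 0.4), `14` = c(0.8, 0.4),
    `23` = c(0.4, 0.7), `24` = c(0.6, 0.7)))
  a <- armpit_angles(tpose)
  expect_equal(a$left_deg, 90, tolerance = 1e-9)
  expect_equal(a$right_deg, 90, tolerance = 1e-9)

  # arms hanging straight down along the torso -> 0 degrees
  down <- one_frame_pose(list(
    `0` = c(0.5, 0.3), `11` = c(0.4, 0.4), `12` = c(0.6, 0.4),
    `13` = c(0.4, 0.6), `14` = c(0.6, 0.6),
    `23` = c(0.4, 0.7), `24` = c(0.6, 0.7)))
  a0 <- armpit_angles(down)
  expect_equal(a0$left_deg, 0, tolerance = 1e-9)
  expect_equal(a0$right_deg, 0, tolerance = 1e-9)
})

test_that("armpit angles equal the atan2 oracle on random landmark placements", {
  set.seed(31)
  for (i in 1:25) {
    pts <- lapply(1:7, function(j) runif(2))
    names(pts) <- c("0", "11", "12", "13", "14", "23", "24")
    a <- armpit_angles(one_frame_pose(pts))
    want_l <- atan2_angle(pts[["13"]] - pts[["11"]],
                          pts[["23"]] - pts[["11"]])
    want_r <- atan2_angle(pts[["14"]] - pts[["12"]],
                          pts[["24"]] - pts[["12"]])
    expect_equal(a$left_deg, want_l, tolerance = 1e-9)
    expect_equal(a$right_deg, want_r, tolerance = 1e-9)
    # shoulder-line convention against its own oracle
    a2 <- armpit_angles(one_frame_pose(pts), convention = "shoulder_line")
    expect_equal(a2$left_deg,
                 atan2_angle(pts[["13"]] - pts[["11"]],
                             pts[["12"]] - pts[["11"]]),
                 tolerance = 1e-9)
  }
})

test_that("angles are invariant under image-plane similarity transforms", {
  set.seed(77)
  pts <- lapply(1:7, function(j) runif(2))
  names(pts) <- c("0", "11", "12", "13", "14", "23", "24")
  base <- armpit_angles(one_frame_pose(pts))
  for (i in 1:10) {
    phi <- runif(1, 0, 2 * pi)
    s <- runif(1, 0.2, 3)
    shift <- runif(2, -1, 1)
    rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
    tpts <- lapply(pts, function(p) as.numeric(s * rot %*% p + shift))
    got <- armpit_angles(one_frame_pose(tpts))
    expect_equal(got$left_deg, base$left_deg, tolerance = 1e-6)
    expect_equal(got$right_deg, base$right_deg, tolerance = 1e-6)
  }
})

test_that("missing landmarks give undefined angles, not errors", {
  p <- make_pose_angles(rep(70, 10))
  p$x_13 <- NA_real_
  p$v_13 <- 0
  a <- armpit_angles(pose_stream(p, fps = 10))
  expect_true(all(is.na(a$left_deg)))
  expect_false(any(a$elbows_present))
  expect_false(any(is.na(a$right_deg)))
})

test_that("arm extension finds the longest raised-arm run with status rules", {
  fps <- 10
  # 30 s low, 120 s raised, 20 s low
  angles <- c(rep(10, 30 * fps), rep(70, 120 * fps), rep(10, 20 * fps))
  pose <- make_pose_angles(angles, fps = fps)
  seg <- detect_arm_extension(pose, search_start = 0)
  expect_equal(seg$status, "successful")
  expect_lt(abs(seg$start_s - 30), 0.5)
  expect_lt(abs((seg$end_s - seg$start_s) - 120), 0.5)

  # ~14% of the run's frames with dropped elbows: interval found, uncertain
  ev <- rep(0.95, length(angles))
  ev[seq(31 * fps, 149 * fps, by = 7)] <- 0.2
  pose2 <- make_pose_angles(angles, fps = fps, elbow_vis = ev)
  seg2 <- detect_arm_extension(pose2, search_start = 0)
  expect_false(is.na(seg2$start_s))
  frac <- seg2$diagnostics[[1]]$arm.elbow_missing_frac
  expect_gt(frac, 0.1)
  expect_equal(seg2$status, "uncertain")

  # arms never above the gate
  seg3 <- detect_arm_extension(make_pose_angles(rep(40, 200)), 0)
  expect_equal(seg3$status, "unavailable")
  # search starts after the first counting exercise
  seg4 <- detect_arm_extension(pose, search_start = 160)
  expect_equal(seg4$status, "unavailable")
})

test_that("arm extension equals an exhaustive scan over qualifying runs", {
  set.seed(55)
  fps <- 5
  for (i in 1:15) {
    n <- 150
    angles <- 45 + cumsum(rnorm(n, 0, 4))
    pose <- make_pose_angles(angles, fps = fps)
    got <- detect_arm_extension(pose, 0, min_run_s = 0.5)
    a <- armpit_angles(pose)
    qual <- !is.na(a$left_deg) & a$left_deg > 45 & a$right_deg > 45 &
      a$arm_visibility > 0.9
    # oracle: every (i, j) pair of qualifying frames with no
    # disqualifying frame between them (all frames defined and visible
    # here, so bridging never applies)
    best <- NULL
    dt <- 1 / fps
    idx <- which(qual)
    for (s in idx) {
      js <- idx[idx >= s]
      js <- js[vapply(js, function(j) all(qual[s:j]), logical(1))]
      if (length(js) > 0) {
        j <- max(js)
        dur <- a$t_s[j] - a$t_s[s] + dt
        if (is.null(best) || dur > best$dur) best <- list(s = s, dur = dur)
      }
    }
    if (is.null(best) || best$dur < 0.5) {
      expect_equal(got$status, "unavailable")
    } else {
      expect_equal(got$start_s, a$t_s[best$s])
      expect_equal(got$diagnostics[[1]]$arm.duration_s, best$dur,
                   tolerance = 1e-9)
    }
  }
})

test_that("drift time measures the sustained fall below the plateau", {
  fps <- 10
  # no drift across a 125 s hold -> full duration -> rubric score 0
  steady <- make_pose_angles(rep(70, 125 * fps), fps = fps)
  d0 <- drift_time(steady, c(0, 125))
  expect_equal(d0, 125)
  expect_equal(score_item("arm_strength", d0), 0L)

  # drop of 30 degrees at t = 60
  t <- (seq_len(125 * fps) - 1) / fps
  angles <- ifelse(t < 60, 70, 40)
  d60 <- drift_time(make_pose_angles(angles, fps = fps), c(0, 125))
  expect_lt(abs(d60 - 60), 0.5)

  # near-immediate drop, measured with a short plateau estimate
  angles2 <- ifelse(t < 1, 70, 40)
  d1 <- drift_time(make_pose_angles(angles2, fps = fps), c(0, 60),
                   plateau_s = 1)
  expect_lt(d1, 3)
  expect_equal(score_item("arm_strength", d1), 3L)

  expect_error(drift_time(steady, c(0, 0.5)), "at least 1 s")
})

# head trajectory with logistic sit-to-stand repetitions (independent of
# the simulator's construction)
sts_nose_y <- function(reps, fps = 10, sit_y = 0.45, rise = 0.2,
                       lead_s = 6, period_s = 8) {
  total <- lead_s + reps * period_s + 6
  t <- seq(0, total, by = 1 / fps)
  y <- rep(sit_y, length(t))
  for (r in seq_len(reps)) {
    up <- lead_s + (r - 1) * period_s
    down <- up + 4
    y <- y - rise * (stats::plogis((t - up - 0.75) / 0.2) -
                       stats::plogis((t - down - 0.75) / 0.2))
  }
  list(t = t, y = y)
}

test_that("head height is smooth, sign-correct, and gap-tolerant", {
  p <- make_pose_angles(rep(10, 50), fps = 10)
  hh <- head_height(p)
  expect_true(all(abs(hh$h - hh$h[1]) < 1e-9))

  # standing (smaller image y) raises h
  traj <- sts_nose_y(1)
  p2 <- make_pose_angles(rep(10, length(traj$t)), fps = 10,
                         nose_y = traj$y)
  hh2 <- head_height(p2)
  expect_gt(max(hh2$h) - hh2$h[1], 0.15)
  expect_equal(hh2$h, 1 - traj$y, tolerance = 0.02)

  # short nose dropouts are interpolated
  p3 <- p2
  p3$v_0[30:33] <- 0.05
  hh3 <- head_height(pose_stream(p3, fps = 10))
  expect_false(any(is.na(hh3$h[30:33])))
})

test_that("sit-to-stand recovers 1, 2 and 3 noiseless repetitions exactly", {
  for (reps in 1:3) {
    traj <- sts_nose_y(reps)
    pose <- make_pose_angles(rep(10, length(traj$t)), fps = 10,
                             nose_y = traj$y)
    res <- detect_sit_to_stand(pose, c(0, max(traj$t)))
    expect_equal(nrow(res$events), reps)
    expect_equal(res$segment$status, "successful")
    rises <- 6 + (seq_len(reps) - 1) * 8
    expect_true(all(abs(res$events$start_s - rises) < 1))
    expect_true(all(res$events$rise_height > 0.1))
    expect_true(all(res$events$start_s < res$events$peak_s &
                      res$events$peak_s < res$events$end_s))
  }
})

test_that("sit-to-stand rejects flat traces and dissimilar bumps", {
  flat <- make_pose_angles(rep(10, 300), fps = 10)
  res <- detect_sit_to_stand(flat, c(0, 30))
  expect_equal(res$segment$status, "unavailable")
  expect_equal(nrow(res$events), 0)

  expect_equal(detect_sit_to_stand(flat, c(0, 2))$segment$status,
               "unavailable")  # window too short

  # one real rise and one 5x smaller wiggle: similarity filter keeps one
  traj <- sts_nose_y(1)
  y <- traj$y
  small <- 0.04 * (stats::plogis((traj$t - 20 - 0.75) / 0.2) -
                     stats::plogis((traj$t - 24 - 0.75) / 0.2))
  pose <- make_pose_angles(rep(10, length(traj$t)), fps = 10,
                           nose_y = y - small)
  res2 <- detect_sit_to_stand(pose, c(0, max(traj$t)))
  expect_equal(nrow(res2$events), 1)
  expect_lt(abs(res2$events$start_s - 6), 1)
})

test_that("the transcript chain window follows the automaton rules", {
  # validation pair within 5 s opens the window: "stand up" at t = 100,
  # "sit down" at t = 105; no explanation hit, so a chain opens at the
  # start (100 + 20 s) and the t = 105 hit extends it to 130
  words <- c(rep("x", 100), "stand", "up", rep("y", 3), "sit", "down",
             rep("z", 40))
  tr <- clean_transcript(make_tr(words, gap = 1))
  w <- sts_transcript_window(tr, c("stand up", "sit down"),
                             c("arms crossed"))
  expect_equal(w[1], 100)
  expect_equal(w[2], 130)

  # no pair within 5 s anywhere -> no window
  words2 <- c("stand", "up", rep("x", 20), "sit", "down")
  tr2 <- clean_transcript(make_tr(words2, gap = 1))
  expect_null(sts_transcript_window(tr2, c("stand up", "sit down"),
                                    c("chair")))

  expect_error(sts_transcript_window(tr, character(), "chair"),
               "non-empty")
})

test_that("chain extension matches a hand-stepped example and the oracle", {
  # explanation at 95 opens a chain to 115; validation hits at 100 and 103
  # extend it to 135; the last word inside the chain sets the end
  n <- 150
  words <- rep("word", n)
  words[96] <- "chair"          # t = 95
  words[c(101, 104)] <- "go"    # t = 100, 103 (validation)
  tr <- clean_transcript(make_tr(words, gap = 1))
  w <- sts_transcript_window(tr, "go", "chair")
  expect_equal(w[1], 100)
  expect_equal(w[2], 135)  # last word at t <= 135 is the word at 135

  # randomized agreement with the step-through oracle
  set.seed(123)
  for (i in 1:25) {
    n <- 120
    words <- rep("w", n)
    vpos <- sort(sample(5:115, sample(2:6, 1)))
    epos <- sort(sample(3:100, sample(1:3, 1)))
    epos <- setdiff(epos, vpos)
    if (length(epos) == 0) next
    words[vpos + 1] <- "go"
    words[epos + 1] <- "chair"
    tr <- clean_transcript(make_tr(words, gap = 1))
    got <- sts_transcript_window(tr, "go", "chair")
    want <- oracle_chain_window(vpos, epos, tr$start_s)
    if (is.null(want)) expect_null(got) else expect_equal(got, want)
  }
})
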