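#' Body landmark index configuration
#'
#' Which BlazePose landmark indices mean what. Defaults follow the standard
#' BlazePose numbering: nose 0, shoulders 11 (left) / 12 (right), elbows
#' 13 / 14, hips 23 / 24. All body operations take this list so a stream
#' with different indexing can be accommodated.
#'
#' @param nose,shoulder_left,shoulder_right,elbow_left,elbow_right,hip_left,hip_right
#'   Landmark ids.
#' @return A named list of landmark ids.
#' @export
landmark_config <- function(nose = 0, shoulder_left = 11, shoulder_right = 12,
                            elbow_left = 13, elbow_right = 14,
                            hip_left = 23, hip_right = 24) {
  list(nose = nose, shoulder_left = shoulder_left,
       shoulder_right = shoulder_right, elbow_left = elbow_left,
       elbow_right = elbow_right, hip_left = hip_left, hip_right = hip_right)
}

lm_col <- function(prefix, id) paste0(prefix, "_", id)

lm_xy <- function(pose, id) {
  cbind(pose[[lm_col("x", id)]], pose[[lm_col("y", id)]])
}

lm_v <- function(pose, id) {
  v <- pose[[lm_col("v", id)]]
  if (is.null(v)) rep(NA_real_, nrow(pose)) else v
}

# angle in degrees between row vectors a and b (both n x 2); NA where either
# is degenerate or has missing coordinates
vec_angle_deg <- function(a, b) {
  dot <- a[, 1] * b[, 1] + a[, 2] * b[, 2]
  na <- sqrt(a[, 1]^2 + a[, 2]^2)
  nb <- sqrt(b[, 1]^2 + b[, 2]^2)
  cosv <- dot / (na * nb)
  cosv[na == 0 | nb == 0] <- NA
  acos(pmin(pmax(cosv, -1), 1)) * 180 / pi
}

#' Armpit angles from a pose stream
#'
#' Computes, per frame, the angle at each shoulder between the upper arm
#' (shoulder-to-elbow vector) and a torso reference. With the default
#' `"torso"` convention the reference is the shoulder-to-hip vector, so a
#' hanging arm reads about 0 degrees and a horizontally extended arm about
#' 90 degrees, and "raised" means exceeding the 45 degree gate. The
#' `"shoulder_line"` convention references the line connecting the two
#' shoulders instead. Angles are undefined (NA) when a required landmark is
#' missing or the body is not detected.
#'
#' @param pose A [pose_stream()] tibble.
#' @param landmarks A [landmark_config()] list.
#' @param convention `"torso"` or `"shoulder_line"`.
#' @return A tibble with `t_s`, `left_deg`, `right_deg`, `arm_visibility`
#'   (minimum visibility over both shoulders and both elbows),
#'   `elbows_present` (both elbow visibilities at least 0.5).
#' @export
armpit_angles <- function(pose, landmarks = landmark_config(),
                          convention = c("torso", "shoulder_line")) {
  convention <- match.arg(convention)
  sl <- lm_xy(pose, landmarks$shoulder_left)
  sr <- lm_xy(pose, landmarks$shoulder_right)
  el <- lm_xy(pose, landmarks$elbow_left)
  er <- lm_xy(pose, landmarks$elbow_right)
  ref_l <- if (convention == "torso") {
    lm_xy(pose, landmarks$hip_left) - sl
  } else {
    sr - sl
  }
  ref_r <- if (convention == "torso") {
    lm_xy(pose, landmarks$hip_right) - sr
  } else {
    sl - sr
  }
  left <- vec_angle_deg(el - sl, ref_l)
  right <- vec_angle_deg(er - sr, ref_r)
  vis <- pmin(lm_v(pose, landmarks$shoulder_left),
              lm_v(pose, landmarks$shoulder_right),
              lm_v(pose, landmarks$elbow_left),
              lm_v(pose, landmarks$elbow_right))
  elbows <- lm_v(pose, landmarks$elbow_left) >= 0.5 &
    lm_v(pose, landmarks$elbow_right) >= 0.5
  absent <- !as.logical(pose$present)
  left[absent] <- NA
  right[absent] <- NA
  vis[absent] <- 0
  elbows[absent | is.na(elbows)] <- FALSE
  tibble(t_s = pose$t_s, left_deg = left, right_deg = right,
         arm_visibility = ifelse(is.na(vis), 0, vis),
         elbows_present = elbows)
}

#' Detect the arm-extension window
#'
#' Searches the pose stream from `search_start` (the end of the first
#' counting exercise) for the longest continuous run in which both armpit
#' angles exceed `min_angle_deg` (default 45 degrees, the clinical
#' raised-arm gate) and arm visibility exceeds `min_visibility` (default
#' 0.9). Frames whose angles are undefined because the elbows dropped out
#' do not break a run - they are bridged (up to `max_bridge_s` at a time)
#' and counted toward the elbow-missing fraction; the run itself must start
#' and end on qualifying frames. Detection is `uncertain` when elbows are
#' missing in more than `max_elbow_missing` of the run's frames, and
#' `unavailable` when no run of at least `min_run_s` exists.
#'
#' @param pose A [pose_stream()] tibble.
#' @param search_start Search start (seconds).
#' @param min_angle_deg Raised-arm angle gate (degrees).
#' @param min_visibility Arm visibility gate.
#' @param min_run_s Minimum run duration (seconds).
#' @param max_elbow_missing Elbow-missing fraction above which the run is
#'   uncertain.
#' @param max_bridge_s Longest stretch of undefined-angle frames bridged
#'   inside a run.
#' @inheritParams armpit_angles
#' @return A [detected_segment()] row for `arm_extension` with diagnostics
#'   `arm.duration_s` and `arm.elbow_missing_frac`.
#' @export
detect_arm_extension <- function(pose, search_start = 0, min_angle_deg = 45,
                                 min_visibility = 0.9, min_run_s = 3,
                                 max_elbow_missing = 0.1, max_bridge_s = 2,
                                 landmarks = landmark_config(),
                                 convention = "torso") {
  ang <- armpit_angles(pose, landmarks, convention)
  ang <- ang[ang$t_s >= search_start, ]
  if (nrow(ang) == 0) {
    return(detected_segment("arm_extension", status = "unavailable"))
  }
  defined <- !is.na(ang$left_deg) & !is.na(ang$right_deg)
  qual <- defined & ang$left_deg > min_angle_deg &
    ang$right_deg > min_angle_deg & ang$arm_visibility > min_visibility
  # a run is broken only by a frame whose angles are defined and visible yet
  # below the gate; undefined or poorly visible frames are bridgeable noise
  fail <- !qual & defined & ang$arm_visibility > min_visibility
  # state per frame: 2 = qualifying, 1 = bridgeable, 0 = disqualifying
  state <- ifelse(qual, 2L, ifelse(fail, 0L, 1L))
  t <- ang$t_s
  dt <- if (length(t) >= 2) median(diff(t)) else 1 / 30
  best <- NULL
  i <- 1L
  n <- length(state)
  while (i <= n) {
    if (state[i] != 2L) {
      i <- i + 1L
      next
    }
    # extend a run from i over qualifying frames, bridging missing-elbow
    # stretches no longer than max_bridge_s
    j <- i
    last_qual <- i
    while (j < n) {
      nxt <- j + 1L
      if (state[nxt] == 2L) {
        j <- nxt
        last_qual <- nxt
      } else if (state[nxt] == 1L && (t[nxt] - t[last_qual]) <= max_bridge_s) {
        j <- nxt
      } else {
        break
      }
    }
    j <- last_qual  # trim trailing bridged frames
    cand <- list(start = i, end = j,
                 dur = t[j] - t[i] + dt,
                 miss_frac = mean(!ang$elbows_present[i:j]))
    if (is.null(best) || cand$dur > best$dur) best <- cand
    i <- j + 1L
  }
  if (is.null(best) || best$dur < min_run_s) {
    return(detected_segment("arm_extension", status = "unavailable",
                            diagnostics = list(arm.duration_s = 0)))
  }
  end_s <- if (best$end < n) t[best$end + 1L] else t[best$end] + dt
  detected_segment(
    "arm_extension", t[best$start], end_s,
    status = if (best$miss_frac > max_elbow_missing) "uncertain"
             else "successful",
    diagnostics = list(arm.duration_s = best$dur,
                       arm.elbow_missing_frac = best$miss_frac)
  )
}

#' Time to arm drift within the arm-extension window
#'
#' Downward arm drift is the scored deficit of the arm-strength domain. The
#' initial plateau angle of each arm is the median over the first
#' `plateau_s` seconds of the window; drift occurs at the first sample where
#' either angle falls more than `drift_angle_deg` below its plateau,
#' sustained for at least `sustain_s`. Returns the window duration when no
#' drift occurs.
#'
#' @param pose A [pose_stream()] tibble.
#' @param arm_interval Numeric `c(start_s, end_s)` of the detected window.
#' @param drift_angle_deg Drop below the plateau that counts as drift.
#' @param sustain_s How long the drop must persist.
#' @param plateau_s Length of the initial plateau estimate.
#' @inheritParams armpit_angles
#' @return Seconds from window start to drift onset.
#' @export
drift_time <- function(pose, arm_interval, drift_angle_deg = 10,
                       sustain_s = 1, plateau_s = 5,
                       landmarks = landmark_config(), convention = "torso") {
  dur <- arm_interval[2] - arm_interval[1]
  if (!is.finite(dur) || dur < 1) {
    abort("arm interval must be at least 1 s long")
  }
  ang <- armpit_angles(pose, landmarks, convention)
  ang <- ang[ang$t_s >= arm_interval[1] & ang$t_s < arm_interval[2], ]
  if (nrow(ang) == 0) return(dur)
  head_w <- ang$t_s <= arm_interval[1] + plateau_s
  plat_l <- median(ang$left_deg[head_w], na.rm = TRUE)
  plat_r <- median(ang$right_deg[head_w], na.rm = TRUE)
  drop <- (!is.na(ang$left_deg) & ang$left_deg < plat_l - drift_angle_deg) |
    (!is.na(ang$right_deg) & ang$right_deg < plat_r - drift_angle_deg)
  r <- rle(drop)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    run_dur <- ang$t_s[ends[k]] - ang$t_s[starts[k]]
    if (run_dur >= sustain_s ||
        (ends[k] == nrow(ang) && arm_interval[2] - ang$t_s[starts[k]] >= sustain_s)) {
      return(ang$t_s[starts[k]] - arm_interval[1])
    }
  }
  dur
}

#' Head-height time series
#'
#' `h(t) = 1 - y(nose)`: image `y` grows downward, so standing up raises
#' `h`. Frames where the body is absent or the nose is invisible are
#' missing; gaps up to `max_gap_s` are linearly interpolated, longer gaps
#' stay missing (the series is effectively split there). The series is
#' smoothed by a centered moving average of `smooth_s`.
#'
#' @param pose A [pose_stream()] tibble.
#' @param smooth_s Moving-average window (seconds).
#' @param max_gap_s Longest gap bridged by interpolation (seconds).
#' @param min_visibility Nose visibility below which the frame is missing.
#' @inheritParams armpit_angles
#' @return A tibble with `t_s`, `h`.
#' @export
head_height <- function(pose, smooth_s = 0.5, max_gap_s = 1,
                        min_visibility = 0.2,
                        landmarks = landmark_config()) {
  y <- pose[[lm_col("y", landmarks$nose)]]
  v <- lm_v(pose, landmarks$nose)
  h <- 1 - y
  h[!as.logical(pose$present) | is.na(v) | v < min_visibility] <- NA
  t <- pose$t_s
  dt <- if (length(t) >= 2) median(diff(t)) else 1 / 30
  maxgap <- max(1, round(max_gap_s / dt))
  h <- zoo::na.approx(h, x = t, maxgap = maxgap, na.rm = FALSE)
  # centered moving average with edge truncation, missing-aware
  half <- smooth_s / 2
  hi <- findInterval(t + half, t)
  lo <- findInterval(t - half, t, left.open = TRUE)
  ok <- !is.na(h)
  cs <- c(0, cumsum(ifelse(ok, h, 0)))
  cn <- c(0, cumsum(ok))
  nwin <- cn[hi + 1] - cn[lo + 1]
  hs <- ifelse(nwin > 0, (cs[hi + 1] - cs[lo + 1]) / nwin, NA)
  hs[!ok] <- NA  # do not invent values inside unbridged gaps
  tibble(t_s = t, h = hs)
}

#' Detect sit-to-stand events from head-height dynamics
#'
#' Standing up moves the head up, so repetitions appear as positive peaks in
#' the time derivative of the smoothed head height. Candidate peaks are
#' local maxima exceeding half the gradient maximum (and an absolute floor
#' of `min_peak`), separated by at least `min_sep_s`; up to
#' `max_reps` peaks whose heights lie within a factor of
#' `similarity_factor` of the tallest are kept (patients perform the
#' maneuver 1 to 3 times). Each event's start/end are the nearest flanking
#' samples where the head is stable (`|gradient| < eps` sustained for
#' `sustain_s`), i.e. seated before and standing after.
#'
#' @param pose A [pose_stream()] tibble.
#' @param window Numeric `c(start_s, end_s)` to search within.
#' @param max_reps Maximum repetitions kept.
#' @param peak_rel Relative prominence gate (fraction of the maximum
#'   gradient).
#' @param min_peak Absolute gradient floor for a candidate peak
#'   (normalized height units per second).
#' @param min_sep_s Minimum separation between peaks (seconds).
#' @param eps Stability threshold on `|gradient|`.
#' @param sustain_s Stability duration requirement (seconds).
#' @param similarity_factor Peaks more than this factor below the tallest
#'   are discarded as dissimilar.
#' @inheritParams head_height
#' @return A list with `events` (tibble `start_s`, `peak_s`, `end_s`,
#'   `rise_height`) and `segment` (a [detected_segment()] row for
#'   `sit_to_stand`).
#' @export
detect_sit_to_stand <- function(pose, window, max_reps = 3, peak_rel = 0.5,
                                min_peak = 0.05, min_sep_s = 2, eps = 0.02,
                                sustain_s = 1, similarity_factor = 2,
                                smooth_s = 0.5, max_gap_s = 1,
                                landmarks = landmark_config()) {
  no_events <- tibble(start_s = numeric(), peak_s = numeric(),
                      end_s = numeric(), rise_height = numeric())
  unavailable <- list(
    events = no_events,
    segment = detected_segment("sit_to_stand", status = "unavailable",
                               diagnostics = list(sts.reps = 0))
  )
  inwin <- pose[pose$t_s >= window[1] & pose$t_s < window[2], ]
  if (nrow(inwin) < 3 || diff(range(inwin$t_s)) < 3) return(unavailable)
  hh <- head_height(inwin, smooth_s = smooth_s, max_gap_s = max_gap_s,
                    landmarks = landmarks)
  t <- hh$t_s
  h <- hh$h
  n <- length(h)
  g <- rep(NA_real_, n)
  g[2:(n - 1)] <- (h[3:n] - h[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  g[1] <- (h[2] - h[1]) / (t[2] - t[1])
  g[n] <- (h[n] - h[n - 1]) / (t[n] - t[n - 1])
  if (all(is.na(g))) return(unavailable)
  gmax <- max(g, na.rm = TRUE)
  floor_g <- max(min_peak, peak_rel * gmax)
  local_max <- c(FALSE, g[2:(n - 1)] >= g[1:(n - 2)] &
                   g[2:(n - 1)] >= g[3:n], FALSE)
  cand <- which(!is.na(g) & local_max & g > floor_g)
  if (length(cand) == 0) return(unavailable)
  # enforce separation greedily by height
  cand <- cand[order(-g[cand])]
  kept <- integer()
  for (i in cand) {
    if (all(abs(t[i] - t[kept]) >= min_sep_s)) kept <- c(kept, i)
  }
  # similarity filter against the tallest, then cap repetitions
  tallest <- max(g[kept])
  kept <- kept[g[kept] >= tallest / similarity_factor]
  kept <- kept[order(-g[kept])][seq_len(min(max_reps, length(kept)))]
  kept <- sort(kept)

  stable <- !is.na(g) & abs(g) < eps
  r <- rle(stable)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok_runs <- which(r$values &
                     t[ends] - t[pmax(starts, 1)] >= sustain_s)
  events <- purrr::map_dfr(kept, function(i) {
    pre <- ok_runs[ends[ok_runs] < i]
    post <- ok_runs[starts[ok_runs] > i]
    s_idx <- if (length(pre) > 0) ends[pre[length(pre)]] else 1L
    e_idx <- if (length(post) > 0) starts[post[1]] else n
    tibble(start_s = t[s_idx], peak_s = t[i], end_s = t[e_idx],
           rise_height = h[e_idx] - h[s_idx])
  })
  segment <- detected_segment(
    "sit_to_stand", min(events$start_s), max(events$end_s),
    status = "successful",
    diagnostics = list(sts.reps = nrow(events))
  )
  list(events = events, segment = segment)
}

#' Sit-to-stand window from the transcript chain method
#'
#' Transcript-only bound on the sit-to-stand test. The start is the first
#' occurrence of two validation-word hits within `pair_window_s` of each
#' other. Each explanation-word hit opens a chain of `chain_s` seconds; any
#' validation-word hit falling inside an open chain extends that chain's end
#' by `extend_s` (repeatably). The window end is the time of the last
#' transcript word inside the most recently extended chain.
#'
#' @param tr A cleaned transcript.
#' @param validation_words Phrases confirming execution (e.g. "stand up",
#'   "sit down").
#' @param explanation_words Phrases preceding the instructions.
#' @param pair_window_s Window for the validation pair (seconds).
#' @param chain_s Initial chain length (seconds).
#' @param extend_s Extension per validation hit (seconds).
#' @return Numeric `c(start_s, end_s)`, or `NULL` when no validation pair
#'   exists.
#' @export
sts_transcript_window <- function(tr, validation_words, explanation_words,
                                  pair_window_s = 5, chain_s = 20,
                                  extend_s = 10) {
  if (length(validation_words) == 0 || length(explanation_words) == 0) {
    abort("validation and explanation word lists must be non-empty")
  }
  val <- sort(purrr::map_dfr(validation_words, ~find_phrase(tr, .x))$t_s)
  if (length(val) < 2) return(NULL)
  pair <- which(diff(val) <= pair_window_s)
  if (length(pair) == 0) return(NULL)
  start <- val[pair[1]]
  exp_hits <- sort(purrr::map_dfr(explanation_words, ~find_phrase(tr, .x))$t_s)
  if (length(exp_hits) == 0) exp_hits <- start
  chains <- lapply(exp_hits, function(e) {
    end <- e + chain_s
    last_ext <- -Inf
    for (v in val[val > e]) {
      if (v <= end) {
        end <- end + extend_s
        last_ext <- v
      }
    }
    list(start = e, end = end, last_ext = last_ext)
  })
  extended <- vapply(chains, function(ch) ch$last_ext, numeric(1))
  pick <- if (any(is.finite(extended))) {
    which.max(extended)
  } else {
    which.max(vapply(chains, function(ch) ch$end, numeric(1)))
  }
  ch <- chains[[pick]]
  inchain <- tr$start_s[tr$start_s >= ch$start & tr$start_s <= ch$end]
  end <- if (length(inchain) > 0) max(inchain) else ch$end
  c(start, max(start, end))
}
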