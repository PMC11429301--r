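#' Segmentation configuration
#'
#' Every tunable threshold of the pipeline with its default. Defaults are
#' the protocol values where the method states them (5 s density window,
#' 0.6 relative density threshold, 10 s / 45 s detectability boundaries,
#' 45 degree arm gate, 0.9 arm visibility, 10% elbow-missing limit,
#' 20 s / 10 s / 5 s sit-to-stand chain constants, 10x fast-forward) and
#' package choices elsewhere.
#'
#' @param ... Name-value overrides of any default.
#' @return A named list.
#' @export
mgce_config <- function(...) {
  defaults <- list(
    phrase_max_gap_s = 2,
    adl_min_fraction = 2 / 3,
    adl_window_s = 30,
    adl_min_questions = 4,
    adl_silence_s = 10,
    count_max_skip = 5,
    count_max_gap_s = 5,
    count_min_tokens = 5,
    count_lookback_s = 30,
    cheek_pad_before_s = 5,
    cheek_pad_after_s = 30,
    ocular_window_s = 5,
    ocular_rel_threshold = 0.6,
    ocular_denominator = "all",
    ocular_partial_min_s = 10,
    ocular_full_min_s = 45,
    ocular_fallback_len_s = 360,
    gaze_conf_threshold = 0.95,
    arm_min_angle_deg = 45,
    arm_min_visibility = 0.9,
    arm_min_run_s = 3,
    arm_max_elbow_missing = 0.1,
    arm_convention = "torso",
    drift_angle_deg = 10,
    sts_pair_window_s = 5,
    sts_chain_s = 20,
    sts_extend_s = 10,
    sts_window_pad_s = 5,
    sts_eps = 0.02,
    sts_min_sep_s = 2,
    sts_similarity_factor = 2,
    sts_max_reps = 3,
    smooth_s = 0.5,
    playback_fast = 10,
    playback_slow = 1
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  utils::modifyList(defaults, overrides)
}

# subtract already-claimed windows from an interval; keep the largest
# remaining piece so detected intervals stay pairwise disjoint
clip_interval <- function(interval, claimed) {
  pieces <- list(interval)
  for (i in seq_len(nrow(claimed))) {
    cs <- claimed$start_s[i]
    ce <- claimed$end_s[i]
    pieces <- purrr::flatten(purrr::map(pieces, function(p) {
      if (ce <= p[1] || cs >= p[2]) return(list(p))
      out <- list()
      if (cs > p[1]) out <- c(out, list(c(p[1], cs)))
      if (ce < p[2]) out <- c(out, list(c(ce, p[2])))
      out
    }))
  }
  if (length(pieces) == 0) return(NULL)
  lens <- vapply(pieces, function(p) p[2] - p[1], numeric(1))
  if (max(lens) <= 0) return(NULL)
  pieces[[which.max(lens)]]
}

#' Segment a full examination session
#'
#' Runs the divide-and-conquer segmentation over the available channels:
#' the MG-ADL questionnaire is located first from the transcript; the two
#' counting exercises are pinned by their number sequences; the brief
#' cheek-puff / tongue-to-cheek phase is located by instruction keywords
#' outside the windows already claimed; the ocular phase is bounded by
#' keywords and its three tests cut from the gaze stream by class density;
#' the arm extension is found in the pose stream from the end of the first
#' counting exercise; and sit-to-stand is searched in the transcript-chain
#' window (intersected with the vision analysis) or, failing that, the
#' residual unclaimed time. Every claimed window is excluded from later
#' stages, so the reported intervals are pairwise disjoint. A missing gaze
#' or pose stream makes the dependent tests `unavailable`; everything else
#' still runs.
#'
#' @param tr A [transcript()] tibble (raw; cleaned internally).
#' @param gaze Optional [gaze_stream()].
#' @param pose Optional [pose_stream()].
#' @param dictionary Keyword dictionary (default shipped one).
#' @param config A [mgce_config()] list.
#' @return An [mgce_report()].
#' @examples
#' \donttest{
#' ses <- simulate_session(mgce_sim_config(seed = 1))
#' rep <- segment_session(ses$transcript, ses$gaze, ses$pose)
#' tidy(rep)
#' }
#' @export
segment_session <- function(tr, gaze = NULL, pose = NULL,
                            dictionary = default_dictionary(),
                            config = mgce_config()) {
  validate_transcript(tr)
  if (nrow(tr) == 0) abort("empty transcript: unusable recording")
  tr <- clean_transcript(tr)
  session_end <- max(tr$end_s)
  if (!is.null(gaze)) session_end <- max(session_end, max(gaze$t_s))
  if (!is.null(pose)) session_end <- max(session_end, max(pose$t_s))

  segs <- list()
  claimed <- tibble(start_s = numeric(), end_s = numeric())
  claim <- function(seg_row) {
    if (is.na(seg_row$start_s)) return(seg_row)
    piece <- clip_interval(c(seg_row$start_s, seg_row$end_s), claimed)
    if (is.null(piece)) {
      return(detected_segment(seg_row$test, status = "unavailable",
                              detectability = seg_row$detectability,
                              diagnostics = c(seg_row$diagnostics[[1]],
                                              list(clipped_away = 1))))
    }
    seg_row$start_s <- piece[1]
    seg_row$end_s <- piece[2]
    claimed <<- bind_rows(claimed,
                          tibble(start_s = piece[1], end_s = piece[2]))
    seg_row
  }

  # --- MG-ADL questionnaire -------------------------------------------------
  adl <- detect_adl(tr, dictionary,
                    min_fraction = config$adl_min_fraction,
                    window_s = config$adl_window_s,
                    min_questions = config$adl_min_questions,
                    silence_s = config$adl_silence_s)
  segs$adl <- claim(if (is.null(adl$interval)) {
    detected_segment("adl", status = "unavailable",
                     diagnostics = adl$diagnostics)
  } else {
    detected_segment("adl", adl$interval[1], adl$interval[2],
                     status = adl$status, diagnostics = adl$diagnostics)
  })
  adl_end <- if (is.null(adl$interval)) 0 else adl$interval[2]

  # --- counting exercises ---------------------------------------------------
  numbers <- extract_numbers(tr)
  runs <- find_runs(numbers, max_skip = config$count_max_skip,
                    max_gap_s = config$count_max_gap_s,
                    min_tokens = config$count_min_tokens)
  cls <- classify_runs(runs, tr, dictionary,
                       lookback_s = config$count_lookback_s)
  run_segment <- function(test, run, status, diag_prefix) {
    if (is.null(run)) {
      return(detected_segment(test, status = "unavailable"))
    }
    keys <- grep(paste0("^", diag_prefix), names(cls$diagnostics),
                 value = TRUE)
    detected_segment(test, run$start_s, run$end_s, status = status,
                     diagnostics = cls$diagnostics[keys])
  }
  segs$count_to_50 <- claim(run_segment("count_to_50", cls$count_to_50,
                                        cls$status[["count_to_50"]],
                                        "count50"))
  segs$single_breath_count <- claim(run_segment("single_breath_count",
                                                cls$sbc,
                                                cls$status[["sbc"]], "sbc"))

  # --- cheek puff / tongue-to-cheek phase -----------------------------------
  ct <- detect_cheek_tongue(tr, dictionary, excluded_windows = claimed,
                            pad_before_s = config$cheek_pad_before_s,
                            pad_after_s = config$cheek_pad_after_s,
                            session_end_s = session_end)
  if (is.null(ct$starts)) {
    segs$cheek_puff <- detected_segment("cheek_puff",
                                        status = "unavailable",
                                        diagnostics = ct$diagnostics)
    segs$tongue_to_cheek <- detected_segment("tongue_to_cheek",
                                             status = "unavailable",
                                             diagnostics = ct$diagnostics)
  } else {
    first_test <- names(ct$starts)[which.min(ct$starts)]
    second_test <- setdiff(names(ct$starts), first_test)
    s1 <- min(ct$starts)
    s2 <- max(ct$starts)
    mk <- function(test, a, b) {
      claim(detected_segment(test, a, b, status = ct$status,
                             diagnostics = ct$diagnostics))
    }
    segs[[first_test]] <- mk(first_test, s1, max(s1, s2))
    segs[[second_test]] <- mk(second_test, s2, max(s2, ct$phase[2]))
  }

  # --- ocular tests ---------------------------------------------------------
  ocular_ids <- c("ptosis", "diplopia_right", "diplopia_left")
  phase <- tryCatch(
    ocular_phase_bounds(tr, dictionary, adl_end,
                        fallback_len_s = config$ocular_fallback_len_s),
    error = function(e) NULL
  )
  if (is.null(gaze) || is.null(phase)) {
    for (id in ocular_ids) {
      segs[[id]] <- detected_segment(id, status = "unavailable",
                                     detectability = "none")
    }
  } else {
    oc <- segment_ocular(gaze, phase,
                         window_s = config$ocular_window_s,
                         rel_threshold = config$ocular_rel_threshold,
                         denominator = config$ocular_denominator,
                         partial_min_s = config$ocular_partial_min_s,
                         full_min_s = config$ocular_full_min_s)
    for (id in ocular_ids) {
      segs[[id]] <- claim(oc[oc$test == id, ])
    }
  }

  # --- arm extension --------------------------------------------------------
  if (is.null(pose)) {
    segs$arm_extension <- detected_segment("arm_extension",
                                           status = "unavailable")
  } else {
    search_start <- if (!is.null(cls$count_to_50)) {
      cls$count_to_50$end_s
    } else {
      adl_end
    }
    arm <- detect_arm_extension(
      pose, search_start,
      min_angle_deg = config$arm_min_angle_deg,
      min_visibility = config$arm_min_visibility,
      min_run_s = config$arm_min_run_s,
      max_elbow_missing = config$arm_max_elbow_missing,
      convention = config$arm_convention
    )
    if (!is.na(arm$start_s)) {
      d <- arm$diagnostics[[1]]
      d$arm.drift_time_s <- drift_time(
        pose, c(arm$start_s, arm$end_s),
        drift_angle_deg = config$drift_angle_deg,
        convention = config$arm_convention
      )
      arm$diagnostics <- list(d)
    }
    segs$arm_extension <- claim(arm)
  }

  # --- sit-to-stand ---------------------------------------------------------
  if (is.null(pose)) {
    segs$sit_to_stand <- detected_segment("sit_to_stand",
                                          status = "unavailable")
  } else {
    tw <- sts_transcript_window(
      tr,
      validation_words = dictionary$tests$sit_to_stand$validation,
      explanation_words = dictionary$tests$sit_to_stand$explanation,
      pair_window_s = config$sts_pair_window_s,
      chain_s = config$sts_chain_s,
      extend_s = config$sts_extend_s
    )
    window_source <- if (!is.null(tw)) 1 else 0  # 1 transcript, 0 residual
    win <- if (!is.null(tw)) {
      c(max(0, tw[1] - config$sts_window_pad_s), tw[2])
    } else {
      resid_start <- if (nrow(claimed) > 0) max(claimed$end_s) else adl_end
      c(resid_start, session_end)
    }
    sts <- detect_sit_to_stand(
      pose, win, max_reps = config$sts_max_reps,
      min_sep_s = config$sts_min_sep_s, eps = config$sts_eps,
      similarity_factor = config$sts_similarity_factor,
      smooth_s = config$smooth_s
    )
    seg <- sts$segment
    d <- c(seg$diagnostics[[1]], list(sts.window_source = window_source))
    seg$diagnostics <- list(d)
    segs$sit_to_stand <- claim(seg)
  }

  mgce_report(session_id(tr), bind_rows(segs[MGCE_TESTS]), config = config)
}

#' Accelerated-review playback plan
#'
#' Tiles the session into intervals with playback speeds for clinician
#' review: test segments play at `slow` (default real time), everything
#' else fast-forwards at `fast` (default 10x). The questionnaire window is
#' treated as non-exercise time. The plan covers `[0, session_duration)`
#' exactly, without overlap.
#'
#' @param report An `mgce_report`.
#' @param session_duration Total session length (seconds).
#' @param fast,slow Speed multipliers.
#' @return A tibble with `start_s`, `end_s`, `speed`, `review_s`; attribute
#'   `review_s_total` gives the estimated total review time.
#' @export
review_schedule <- function(report, session_duration,
                            fast = 10, slow = 1) {
  seg <- filter(report$segments, !is.na(.data$start_s),
                .data$test != "adl")
  seg <- arrange(seg, .data$start_s)
  if (nrow(seg) > 1 &&
      any(seg$start_s[-1] < seg$end_s[-nrow(seg)])) {
    abort("report intervals overlap; cannot build a playback plan")
  }
  bounds <- unique(pmin(pmax(
    c(0, rbind(seg$start_s, pmin(seg$end_s, session_duration)),
      session_duration), 0), session_duration))
  bounds <- sort(bounds)
  plan <- tibble(start_s = bounds[-length(bounds)], end_s = bounds[-1])
  plan <- filter(plan, .data$end_s > .data$start_s)
  in_seg <- vapply(plan$start_s, function(s) {
    any(s >= seg$start_s & s < seg$end_s)
  }, logical(1))
  plan$speed <- ifelse(in_seg, slow, fast)
  plan$review_s <- (plan$end_s - plan$start_s) / plan$speed
  attr(plan, "review_s_total") <- sum(plan$review_s)
  plan
}

#' Evaluate a report against ground truth
#'
#' Compares detected segment boundaries with a session script's true active
#' windows. Success criteria follow the segmentation study design: a start
#' located within 10 s, and the stricter 5 s tolerance used for the ocular
#' tests.
#'
#' @param report An `mgce_report`.
#' @param script A session-script tibble (see [simulate_session()]) with
#'   columns `test`, `active_start_s`, `active_end_s`.
#' @param tolerances Numeric start tolerances evaluated as flags (seconds).
#' @return A tibble with one row per scripted test: `delta_start_s`,
#'   `delta_end_s`, `ok_<tol>s` flags, `status`, `detectability`.
#' @export
evaluate_segmentation <- function(report, script, tolerances = c(5, 10)) {
  stopifnot(inherits(report, "mgce_report"))
  sid <- attr(script, "session_id")
  if (!is.null(sid) && !identical(sid, report$session_id)) {
    abort("report and script belong to different sessions")
  }
  det <- select(report$segments, "test", det_start_s = "start_s",
                det_end_s = "end_s", "status", "detectability")
  out <- left_join(
    select(as_tibble(script), "test", "active_start_s", "active_end_s"),
    det, by = "test"
  )
  out$delta_start_s <- out$det_start_s - out$active_start_s
  out$delta_end_s <- out$det_end_s - out$active_end_s
  for (tol in tolerances) {
    out[[paste0("ok_", tol, "s")]] <-
      !is.na(out$delta_start_s) & abs(out$delta_start_s) < tol
  }
  out
}
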