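#' Synthetic-session generator configuration
#'
#' Parameters of the seeded session simulator. The generator emulates the
#' three abstracted channels of a telemedicine MG examination - word-level
#' transcript, gaze-class stream, body-landmark stream - together with the
#' ground-truth timeline, so every stage of the pipeline can be exercised
#' offline. The `noise` preset `"default"` reproduces the documented
#' study-condition noise (transcript timing jitter, counting token dropout,
#' gaze misclassification and rejected frames, landmark jitter and
#' visibility dropout, instruction paraphrasing, and the roughly
#' half-of-eight MG-ADL question usage); `"none"` zeroes all noise and asks
#' every questionnaire question, for exact-recovery checks.
#'
#' @param seed Integer seed; identical configurations produce identical
#'   sessions.
#' @param noise `"default"` or `"none"`.
#' @param fps Frame rate of the gaze and pose streams.
#' @param adl_include_p Probability each of the 8 MG-ADL questions is asked.
#' @param paraphrase_p Probability an instruction uses an alternative
#'   dictionary phrasing, and that a question drops up to a third of its
#'   keywords.
#' @param word_gap_sd Jitter (s) on inter-word gaps and word durations.
#' @param count_dropout Probability a counting token is missing from the
#'   transcript.
#' @param count_gap_s Nominal cadence of the count to 50 (s per number).
#' @param gaze_misclass Per-frame gaze misclassification probability.
#' @param gaze_no_value Per-frame probability of a rejected (`no_value`)
#'   gaze frame.
#' @param angle_noise_sd Frame noise on the armpit angles (degrees).
#' @param pos_noise_sd Frame noise on landmark coordinates (normalized
#'   units).
#' @param visibility_dropout Per-frame, per-landmark probability of a
#'   visibility dropout.
#' @param ocular_active_s Active hold of each ocular test (s).
#' @param arm_active_s Nominal arm-extension hold (s).
#' @param arm_plateau_deg Raised-arm plateau angle (degrees).
#' @param drift_p Probability the arms drift during the hold.
#' @param drift_range_s Range the drift onset is drawn from (s after the
#'   active start).
#' @param sbc_max Highest number reached on the single breath; drawn from
#'   20..32 when `NULL`.
#' @param sts_reps Sit-to-stand repetitions (1-3); drawn when `NULL`.
#' @param diplopia_order_random Whether the right/left diplopia order is
#'   randomized.
#' @return A named list of class `mgce_sim_config`.
#' @export
mgce_sim_config <- function(seed = 1, noise = c("default", "none"),
                            fps = 15, adl_include_p = NULL,
                            paraphrase_p = NULL, word_gap_sd = NULL,
                            count_dropout = NULL, count_gap_s = 0.8,
                            gaze_misclass = NULL, gaze_no_value = NULL,
                            angle_noise_sd = NULL, pos_noise_sd = NULL,
                            visibility_dropout = NULL,
                            ocular_active_s = 60, arm_active_s = 120,
                            arm_plateau_deg = 70, drift_p = 0.5,
                            drift_range_s = c(60, 110), sbc_max = NULL,
                            sts_reps = NULL, diplopia_order_random = TRUE) {
  noise <- match.arg(noise)
  noisy <- noise == "default"
  cfg <- list(
    seed = as.integer(seed),
    noise = noise,
    fps = fps,
    adl_include_p = adl_include_p %||% (if (noisy) 0.5 else 1),
    paraphrase_p = paraphrase_p %||% (if (noisy) 0.2 else 0),
    word_gap_sd = word_gap_sd %||% (if (noisy) 0.05 else 0),
    count_dropout = count_dropout %||% (if (noisy) 0.1 else 0),
    count_gap_s = count_gap_s,
    gaze_misclass = gaze_misclass %||% (if (noisy) 0.1 else 0),
    gaze_no_value = gaze_no_value %||% (if (noisy) 0.05 else 0),
    angle_noise_sd = angle_noise_sd %||% (if (noisy) 1 else 0),
    pos_noise_sd = pos_noise_sd %||% (if (noisy) 0.002 else 0),
    visibility_dropout = visibility_dropout %||% (if (noisy) 0.02 else 0),
    ocular_active_s = ocular_active_s,
    arm_active_s = arm_active_s,
    arm_plateau_deg = arm_plateau_deg,
    drift_p = drift_p,
    drift_range_s = drift_range_s,
    sbc_max = sbc_max,
    sts_reps = sts_reps,
    diplopia_order_random = diplopia_order_random
  )
  probs <- cfg[c("adl_include_p", "paraphrase_p", "count_dropout",
                 "gaze_misclass", "gaze_no_value", "visibility_dropout")]
  if (any(unlist(probs) < 0 | unlist(probs) > 1)) {
    abort("probabilities must lie in [0, 1]")
  }
  structure(cfg, class = c("mgce_sim_config", "list"))
}

# words for a counting value; compounds come out as two adjacent tokens
number_word <- function(v) {
  if (v <= 9) return(names(ONES_WORDS)[v])
  if (v <= 19) return(names(TEENS_WORDS)[v - 9])
  tens <- (v %/% 10) * 10
  ones <- v %% 10
  tw <- names(TENS_WORDS)[match(tens, TENS_WORDS)]
  if (ones == 0) tw else c(tw, names(ONES_WORDS)[ones])
}

FILLER <- c("okay", "alright", "good", "great", "job", "well", "done",
            "thank", "you", "perfect", "relax", "moment", "ready")

#' Generate a synthetic examination session
#'
#' Builds a full scripted session: the MG-ADL questionnaire (each of the 8
#' questions included with the configured probability), then the nine MG-CE
#' tests, each with explanation / active / conclusion sub-phases. The
#' transcript carries the examiner's instruction phrases (sampled from the
#' shipped dictionary, with paraphrase variation), the patient's counting
#' sequences with token dropout, and conversational filler. The gaze stream
#' follows the active ocular windows with misclassification noise; the pose
#' stream realizes raised-arm angle trajectories (plateau, then linear
#' decline when a drift is scripted) and logistic head-height steps for
#' each sit-to-stand repetition. Identical configurations produce
#' byte-identical outputs.
#'
#' @param config An [mgce_sim_config()].
#' @return A list with `script` (ground-truth tibble: `test`, `start_s`,
#'   `active_start_s`, `active_end_s`, `end_s`; attributes `session_id` and
#'   `params`), `transcript`, `gaze`, `pose`, and `params` (scenario draws:
#'   drift onset, SBC maximum, repetitions, questions asked).
#' @export
simulate_session <- function(config = mgce_sim_config()) {
  stopifnot(inherits(config, "mgce_sim_config") || is.list(config))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(config$seed)

  jit <- function(mu, sd = config$word_gap_sd, lo = 0.02) {
    max(lo, mu + if (sd > 0) rnorm(1, 0, sd) else 0)
  }

  # ---- transcript accumulator ----
  words <- new.env(parent = emptyenv())
  words$text <- character()
  words$start <- numeric()
  words$end <- numeric()
  words$speaker <- character()
  cursor <- 0
  say <- function(text, speaker, at = NULL) {
    t0 <- at %||% cursor
    for (w in text) {
      dur <- jit(0.25, config$word_gap_sd / 2, lo = 0.08)
      words$text <- c(words$text, w)
      words$start <- c(words$start, t0)
      words$end <- c(words$end, t0 + dur)
      words$speaker <- c(words$speaker, speaker)
      t0 <- t0 + dur + jit(0.1)
    }
    cursor <<- max(cursor, t0)
    invisible(t0)
  }
  pause <- function(s) cursor <<- cursor + s

  dict <- default_dictionary()
  pick_phrase <- function(test) {
    phrases <- dict$tests[[test]]$explanation
    if (length(phrases) == 1 || runif(1) >= config$paraphrase_p) {
      phrases[1]
    } else {
      sample(phrases[-1], 1)
    }
  }
  say_instruction <- function(test) {
    say(c("now", "i", "would", "like", "you", "to"), "doctor")
    say(strsplit(pick_phrase(test), " ")[[1]], "doctor")
    say(c("for", "me", "please"), "doctor")
  }
  say_conclusion <- function() {
    say(sample(FILLER, 5, replace = TRUE), "doctor")
    pause(1)
  }

  # ---- ground-truth script and channel plans ----
  script <- list()
  gaze_plan <- list()    # (start, end, label)
  arm_keys <- list()     # (t, angle) keyframes
  sts_moves <- list()    # (rise_start, fall_start) per repetition
  add_script <- function(test, start, active_start, active_end, end) {
    script[[length(script) + 1]] <<- tibble(
      test = test, start_s = start, active_start_s = active_start,
      active_end_s = active_end, end_s = end
    )
  }

  # ---- MG-ADL questionnaire ----
  say(c("hello", "welcome", "lets", "begin", "with", "your", "daily",
        "living", "questions"), "doctor")
  pause(0.8)
  asked <- character()
  adl_last_answer <- cursor
  for (q in names(dict$adl_questions)) {
    if (runif(1) >= config$adl_include_p) next
    asked <- c(asked, q)
    bag <- dict$adl_questions[[q]]
    if (config$paraphrase_p > 0 && runif(1) < config$paraphrase_p &&
        length(bag) >= 3) {
      bag <- bag[-sample(length(bag), floor(length(bag) / 3))]
    }
    say(c("do", "you", "have", "any"), "doctor")
    say(bag, "doctor")
    say(c("these", "days"), "doctor")
    pause(0.5)
    adl_last_answer <- say(sample(c("no", "not", "really", "sometimes",
                                    "a", "little"), 3), "patient")
    pause(0.8)
  }
  adl_end <- adl_last_answer
  add_script("adl", 0, 0, adl_end, adl_end)
  pause(1.5)

  # ---- test order: ocular block first, diplopia order may swap ----
  dip <- c("diplopia_right", "diplopia_left")
  if (config$diplopia_order_random && runif(1) < 0.5) dip <- rev(dip)
  order_rest <- c("cheek_puff", "tongue_to_cheek", "count_to_50",
                  "arm_extension", "single_breath_count", "sit_to_stand")
  test_order <- c("ptosis", dip, order_rest)

  params <- list(
    adl_questions = asked,
    sbc_max = config$sbc_max %||% sample(20:32, 1),
    sts_reps = config$sts_reps %||% sample(1:3, 1),
    drift_at_s = if (runif(1) < config$drift_p) {
      round(runif(1, config$drift_range_s[1], config$drift_range_s[2]))
    } else {
      NA_real_
    },
    test_order = test_order
  )

  gaze_label_of <- c(ptosis = "up", diplopia_right = "right",
                     diplopia_left = "left")

  for (test in test_order) {
    t_start <- cursor
    if (test %in% names(gaze_label_of)) {
      say_instruction(test)
      pause(1)
      a0 <- cursor
      a1 <- a0 + config$ocular_active_s
      gaze_plan[[length(gaze_plan) + 1]] <-
        list(start = a0, end = a1, label = gaze_label_of[[test]])
      say(c("keep", "holding"), "doctor", at = a0 + 20)
      cursor <- a1
      say_conclusion()
      add_script(test, t_start, a0, a1, cursor)
    } else if (test %in% c("cheek_puff", "tongue_to_cheek")) {
      say_instruction(test)
      pause(1)
      a0 <- cursor
      a1 <- a0 + 5
      cursor <- a1
      say_conclusion()
      add_script(test, t_start, a0, a1, cursor)
    } else if (test == "count_to_50") {
      say_instruction(test)
      pause(1.2)
      a0 <- cursor
      t_tok <- a0
      last_end <- a0
      for (v in 1:50) {
        if (runif(1) >= config$count_dropout) {
          last_end <- say(number_word(v), "patient", at = t_tok)
        }
        t_tok <- t_tok + jit(config$count_gap_s)
      }
      a1 <- last_end
      cursor <- max(cursor, a1)
      say_conclusion()
      add_script(test, t_start, a0, a1, cursor)
    } else if (test == "single_breath_count") {
      say_instruction(test)
      pause(1.2)
      a0 <- cursor
      t_tok <- a0
      gap <- 0.75
      last_end <- a0
      for (v in seq_len(params$sbc_max)) {
        if (runif(1) >= config$count_dropout || v == 1) {
          last_end <- say(number_word(v), "patient", at = t_tok)
        }
        gap <- max(0.3, gap - 0.012)
        t_tok <- t_tok + jit(gap)
      }
      a1 <- last_end
      cursor <- max(cursor, a1)
      say(c("hmm", "mmm"), "patient")  # exhausted, unrecognizable speech
      say_conclusion()
      add_script(test, t_start, a0, a1, cursor)
    } else if (test == "arm_extension") {
      say_instruction(test)
      pause(2.5)
      a0 <- cursor
      plateau <- config$arm_plateau_deg
      # hold ends early if a scripted drift takes the angle through 45
      decline_rate <- 2
      a1 <- a0 + config$arm_active_s
      arm_keys[[length(arm_keys) + 1]] <- list(t = a0 - 2, angle = 10)
      arm_keys[[length(arm_keys) + 1]] <- list(t = a0, angle = plateau)
      if (!is.na(params$drift_at_s)) {
        dstart <- a0 + params$drift_at_s - 10 / decline_rate
        arm_keys[[length(arm_keys) + 1]] <- list(t = dstart, angle = plateau)
        end_angle <- max(5, plateau - decline_rate * (a1 - dstart))
        arm_keys[[length(arm_keys) + 1]] <- list(t = a1, angle = end_angle)
        arm_keys[[length(arm_keys) + 1]] <- list(t = a1 + 2, angle = 10)
      } else {
        arm_keys[[length(arm_keys) + 1]] <- list(t = a1, angle = plateau)
        arm_keys[[length(arm_keys) + 1]] <- list(t = a1 + 2, angle = 10)
      }
      say(c("keep", "them", "up"), "doctor", at = a0 + 30)
      cursor <- a1
      say_conclusion()
      add_script(test, t_start, a0, a1, cursor)
    } else if (test == "sit_to_stand") {
      say(c("for", "the", "last", "one", "please"), "doctor")
      say(strsplit(pick_phrase("sit_to_stand"), " ")[[1]], "doctor")
      say(c("when", "you", "are", "ready"), "doctor")
      pause(2)
      a0 <- cursor
      t_rep <- a0
      for (r in seq_len(params$sts_reps)) {
        say(c("please", "stand", "up"), "doctor", at = t_rep)
        fall_start <- t_rep + 4  # 1.5 s rise + 2.5 s standing
        say(c("and", "sit", "back", "down"), "doctor", at = fall_start)
        sts_moves[[length(sts_moves) + 1]] <-
          list(rise = t_rep, fall = fall_start)
        t_rep <- fall_start + 4  # 1.5 s descent + 2.5 s seated
      }
      a1 <- t_rep - 4 + 1.5     # end of the last descent
      cursor <- max(cursor, a1)
      say_conclusion()
      add_script(test, t_start, a0, a1, cursor)
    }
    pause(1.5)
  }
  session_end <- cursor + 3

  # ---- assemble transcript ----
  tr <- transcript(words$text, words$start, words$end, words$speaker,
                   confidence = 0.95,
                   session_id = paste0("sim-", config$seed))

  # ---- gaze stream ----
  t_grid <- seq(0, session_end, by = 1 / config$fps)
  n <- length(t_grid)
  label <- rep("neutral", n)
  for (gp in gaze_plan) {
    label[t_grid >= gp$start & t_grid < gp$end] <- gp$label
  }
  if (config$gaze_misclass > 0) {
    mis <- runif(n) < config$gaze_misclass
    if (any(mis)) {
      alt <- c("up", "left", "right", "neutral")
      label[mis] <- vapply(label[mis], function(l) {
        sample(setdiff(alt, l), 1)
      }, character(1))
    }
  }
  conf <- runif(n, 0.955, 1)
  if (config$gaze_no_value > 0) {
    nv <- runif(n) < config$gaze_no_value
    label[nv] <- "no_value"
    conf[nv] <- runif(sum(nv), 0.5, 0.95)
  }
  gaze <- gaze_stream(t_grid, label, confidence = round(conf, 3),
                      fps = config$fps)

  # ---- pose stream ----
  ak_t <- vapply(arm_keys, function(k) k$t, numeric(1))
  ak_a <- vapply(arm_keys, function(k) k$angle, numeric(1))
  angle <- if (length(ak_t) >= 2) {
    stats::approx(ak_t, ak_a, xout = t_grid, rule = 2)$y
  } else {
    rep(10, n)
  }
  if (config$angle_noise_sd > 0) {
    angle <- angle + rnorm(n, 0, config$angle_noise_sd)
  }
  angle <- pmin(pmax(angle, 0), 175)

  dy <- rep(0, n)  # body vertical shift: standing moves everything up
  stand_shift <- -0.2
  blend <- function(t0, len = 1.5) stats::plogis((t_grid - t0 - len / 2) / 0.2)
  for (mv in sts_moves) {
    dy <- dy + stand_shift * (blend(mv$rise) - blend(mv$fall))
  }

  base <- list(
    nose = c(0.50, 0.45), shoulder_l = c(0.42, 0.55),
    shoulder_r = c(0.58, 0.55), hip_l = c(0.44, 0.75), hip_r = c(0.56, 0.75)
  )
  pnoise <- function() {
    if (config$pos_noise_sd > 0) rnorm(n, 0, config$pos_noise_sd) else 0
  }
  elbow_from <- function(sh, hip, theta_deg, outward) {
    ux <- hip[1] - sh[1]
    uy <- hip[2] - sh[2]
    nrm <- sqrt(ux^2 + uy^2)
    ux <- ux / nrm
    uy <- uy / nrm
    th <- outward * theta_deg * pi / 180
    list(x = sh[1] + 0.18 * (cos(th) * ux - sin(th) * uy),
         y = sh[2] + 0.18 * (sin(th) * ux + cos(th) * uy))
  }
  el <- elbow_from(base$shoulder_l, base$hip_l, angle, -1)
  er <- elbow_from(base$shoulder_r, base$hip_r, angle, +1)
  vis <- function() {
    v <- pmin(pmax(0.95 + pnoise(), 0), 1)
    if (config$visibility_dropout > 0) {
      v[runif(n) < config$visibility_dropout] <- 0.2
    }
    v
  }
  pose <- tibble(
    t_s = t_grid, present = TRUE,
    x_0 = base$nose[1] + pnoise(), y_0 = base$nose[2] + dy + pnoise(),
    v_0 = vis(),
    x_11 = base$shoulder_l[1] + pnoise(),
    y_11 = base$shoulder_l[2] + dy + pnoise(), v_11 = vis(),
    x_12 = base$shoulder_r[1] + pnoise(),
    y_12 = base$shoulder_r[2] + dy + pnoise(), v_12 = vis(),
    x_13 = el$x + pnoise(), y_13 = el$y + dy + pnoise(), v_13 = vis(),
    x_14 = er$x + pnoise(), y_14 = er$y + dy + pnoise(), v_14 = vis(),
    x_23 = base$hip_l[1] + pnoise(),
    y_23 = base$hip_l[2] + dy + pnoise(), v_23 = vis(),
    x_24 = base$hip_r[1] + pnoise(),
    y_24 = base$hip_r[2] + dy + pnoise(), v_24 = vis()
  )
  pose <- pose_stream(pose, fps = config$fps)

  script <- bind_rows(script)
  attr(script, "session_id") <- paste0("sim-", config$seed)
  attr(script, "params") <- params
  list(script = script, transcript = tr, gaze = gaze, pose = pose,
       params = params)
}

#' Write / read a session script
#'
#' Ground-truth timelines are serialized as JSON with times in integer
#' milliseconds, alongside the scenario parameters.
#'
#' @param script A script tibble from [simulate_session()].
#' @param path File path.
#' @return `path` invisibly; `read_session_script()` returns the tibble.
#' @export
write_session_script <- function(script, path) {
  out <- list(
    session_id = attr(script, "session_id"),
    params = attr(script, "params"),
    tests = lapply(seq_len(nrow(script)), function(i) {
      list(test = script$test[i],
           start_ms = ms(script$start_s[i]),
           active_start_ms = ms(script$active_start_s[i]),
           active_end_ms = ms(script$active_end_s[i]),
           end_ms = ms(script$end_s[i]))
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_session_script
#' @export
read_session_script <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  script <- bind_rows(lapply(raw$tests, function(x) {
    tibble(test = x$test, start_s = x$start_ms / 1000,
           active_start_s = x$active_start_ms / 1000,
           active_end_s = x$active_end_ms / 1000, end_s = x$end_ms / 1000)
  }))
  attr(script, "session_id") <- raw$session_id
  attr(script, "params") <- raw$params
  script
}

#' Generate a batch of synthetic sessions on disk
#'
#' Writes `n` independent sessions (transcript JSON, gaze CSV, pose CSV,
#' script JSON) with seeds derived deterministically from the base seed,
#' plus a `manifest.json` listing files and seeds. Regenerating from the
#' manifest seeds reproduces identical files.
#'
#' @param config Base [mgce_sim_config()].
#' @param n Number of sessions (>= 1).
#' @param dir Output directory (created if needed).
#' @return A tibble manifest (session id, seed, file paths), invisibly.
#' @export
simulate_batch <- function(config, n, dir) {
  stopifnot(n >= 1)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create directory: ", dir))
  }
  manifest <- purrr::map_dfr(seq_len(n), function(i) {
    seed_i <- (config$seed * 10007 + i) %% 2147483647
    cfg <- config
    cfg$seed <- as.integer(seed_i)
    ses <- simulate_session(cfg)
    id <- sprintf("session_%03d", i)
    files <- c(
      transcript = file.path(dir, paste0(id, "_transcript.json")),
      gaze = file.path(dir, paste0(id, "_gaze.csv")),
      pose = file.path(dir, paste0(id, "_pose.csv")),
      script = file.path(dir, paste0(id, "_script.json"))
    )
    write_transcript(ses$transcript, files[["transcript"]])
    write_stream(ses$gaze, files[["gaze"]])
    write_stream(ses$pose, files[["pose"]])
    write_session_script(ses$script, files[["script"]])
    tibble(id = id, seed = seed_i,
           transcript = basename(files[["transcript"]]),
           gaze = basename(files[["gaze"]]),
           pose = basename(files[["pose"]]),
           script = basename(files[["script"]]))
  })
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", digits = NA)
  invisible(manifest)
}
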