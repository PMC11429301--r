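# Spelled-number vocabulary for 1..50. Compounds ("twenty one") are merged
# from a tens word plus an adjacent ones word.
ONES_WORDS <- c(one = 1, two = 2, three = 3, four = 4, five = 5, six = 6,
                seven = 7, eight = 8, nine = 9)
TEENS_WORDS <- c(ten = 10, eleven = 11, twelve = 12, thirteen = 13,
                 fourteen = 14, fifteen = 15, sixteen = 16, seventeen = 17,
                 eighteen = 18, nineteen = 19)
TENS_WORDS <- c(twenty = 20, thirty = 30, forty = 40, fifty = 50)

#' Extract number tokens from a transcript
#'
#' Recognizes counting tokens in 1-50: digit strings (`"17"`) and spelled
#' numbers (`"seventeen"`, `"twenty one"` as two adjacent words; hyphenated
#' forms are already split by [clean_transcript()]). A tens word followed
#' immediately by a ones word merges into one compound token timestamped at
#' the first word. When the merged compound would leave the 1-50 range
#' (e.g. "fifty one"), the in-range singleton readings are emitted instead
#' (50 then 1) and both tokens are flagged ambiguous.
#'
#' @param tr A cleaned transcript.
#' @return A tibble with columns `value`, `t_s`, `end_s`, `speaker`,
#'   `source` (`"digit"` or `"spelled"`), `ambiguous`.
#' @export
extract_numbers <- function(tr) {
  empty <- tibble(value = integer(), t_s = numeric(), end_s = numeric(),
                  speaker = character(), source = character(),
                  ambiguous = logical())
  if (nrow(tr) == 0) return(empty)
  txt <- tr$text
  spelled <- c(ONES_WORDS, TEENS_WORDS, TENS_WORDS)
  is_digit <- stringr::str_detect(txt, "^[0-9]+$")
  digit_val <- ifelse(is_digit, suppressWarnings(as.integer(txt)), NA_integer_)
  spelled_val <- unname(spelled[txt])
  is_tens <- txt %in% names(TENS_WORDS)
  is_ones <- txt %in% names(ONES_WORDS)

  out <- empty
  i <- 1L
  n <- nrow(tr)
  emit <- function(value, i, j = i, source, ambiguous = FALSE) {
    tibble(value = as.integer(value), t_s = tr$start_s[i], end_s = tr$end_s[j],
           speaker = tr$speaker[i], source = source, ambiguous = ambiguous)
  }
  while (i <= n) {
    if (is_digit[i]) {
      if (!is.na(digit_val[i]) && digit_val[i] >= 1 && digit_val[i] <= 50) {
        out <- bind_rows(out, emit(digit_val[i], i, source = "digit"))
      }
      i <- i + 1L
    } else if (is_tens[i] && i < n && is_ones[i + 1L]) {
      compound <- unname(TENS_WORDS[txt[i]] + ONES_WORDS[txt[i + 1L]])
      if (compound <= 50) {
        out <- bind_rows(out, emit(compound, i, i + 1L, source = "spelled"))
      } else {
        # "fifty one": compound out of range -> fall back to the two
        # in-range singletons, flagged ambiguous
        out <- bind_rows(out,
                         emit(spelled[[txt[i]]], i, source = "spelled",
                              ambiguous = TRUE),
                         emit(spelled[[txt[i + 1L]]], i + 1L,
                              source = "spelled", ambiguous = TRUE))
      }
      i <- i + 2L
    } else if (!is.na(spelled_val[i])) {
      out <- bind_rows(out, emit(spelled_val[i], i, source = "spelled"))
      i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Find increasing counting runs among number tokens
#'
#' Scans the time-sorted tokens for maximal runs in which each value exceeds
#' the previous by 1 to `max_skip + 1` (tolerating up to `max_skip` missed
#' numbers per step, since the recognizer drops tokens) and consecutive
#' tokens are at most `max_gap_s` apart. A token that cannot extend the
#' current run closes it and opens a new one, so a counting restart splits
#' runs. Runs shorter than `min_tokens` are discarded as incidental numbers.
#'
#' @param numbers Tibble from [extract_numbers()].
#' @param max_skip Maximum missing numbers tolerated between tokens.
#' @param max_gap_s Maximum inter-token silence (seconds).
#' @param min_tokens Minimum run length kept.
#' @return A tibble, one row per run: `start_s`, `end_s`, `n_tokens`,
#'   `first_value`, `max_value`, and a `tokens` list-column.
#' @export
find_runs <- function(numbers, max_skip = 5, max_gap_s = 5, min_tokens = 5) {
  empty <- tibble(start_s = numeric(), end_s = numeric(),
                  n_tokens = integer(), first_value = integer(),
                  max_value = integer(), tokens = list())
  if (nrow(numbers) == 0) return(empty)
  numbers <- arrange(numbers, .data$t_s)
  dv <- diff(numbers$value)
  dt <- numbers$t_s[-1] - numbers$end_s[-nrow(numbers)]
  extends <- dv >= 1 & dv <= max_skip + 1 & dt <= max_gap_s
  run_id <- cumsum(c(TRUE, !extends))
  runs <- lapply(split(seq_len(nrow(numbers)), run_id), function(idx) {
    tok <- numbers[idx, ]
    tibble(start_s = tok$t_s[1], end_s = tok$end_s[nrow(tok)],
           n_tokens = nrow(tok), first_value = tok$value[1],
           max_value = max(tok$value), tokens = list(tok))
  })
  out <- bind_rows(runs)
  out <- filter(out, .data$n_tokens >= min_tokens)
  if (nrow(out) == 0) empty else out
}

#' Counting-rate metrics for a run
#'
#' `rate` is tokens-per-second over the run span; `acceleration` is the
#' least-squares slope of the inter-token gaps against token index, in
#' seconds per step: negative values mean the patient is speeding up, which
#' is typical toward the end of the single-breath count.
#'
#' @param run One row of [find_runs()] output, or a token tibble.
#' @return A list with `rate` (numbers/s) and `acceleration` (s per step).
#' @export
run_metrics <- function(run) {
  tokens <- if (is.data.frame(run) && "tokens" %in% names(run)) {
    run$tokens[[1]]
  } else {
    run
  }
  n <- nrow(tokens)
  if (n < 2) abort("run_metrics needs a run of at least 2 tokens")
  span <- tokens$t_s[n] - tokens$t_s[1]
  gaps <- diff(tokens$t_s)
  idx <- seq_along(gaps)
  accel <- if (length(gaps) >= 2) {
    sum((idx - mean(idx)) * (gaps - mean(gaps))) / sum((idx - mean(idx))^2)
  } else {
    0
  }
  list(rate = (n - 1) / span, acceleration = accel)
}

#' Classify counting runs as count-to-50 and single-breath count
#'
#' A run preceded (within `lookback_s`) by a single-breath explanation
#' phrase is the single-breath count (SBC); a run preceded by a count-to-50
#' phrase, or reaching at least 40, is the count to 50. If ambiguity
#' remains, the earlier qualifying run is taken as count-to-50 and the later
#' as SBC. The SBC end is the last recognized token: trailing unrecognized
#' speech is itself evidence that the patient could no longer count
#' clearly. Patients should not count beyond thirty on one breath, so an
#' SBC run exceeding 30 is flagged.
#'
#' @param runs Output of [find_runs()].
#' @param tr The cleaned transcript the runs came from.
#' @param dictionary Keyword dictionary.
#' @param lookback_s How far before a run's first token an explanation
#'   phrase may occur (seconds).
#' @return A list with `count_to_50` and `sbc` (each a one-row run tibble or
#'   `NULL`), `status` (per test), and `diagnostics`.
#' @export
classify_runs <- function(runs, tr, dictionary, lookback_s = 30) {
  out <- list(count_to_50 = NULL, sbc = NULL,
              status = c(count_to_50 = "unavailable", sbc = "unavailable"),
              diagnostics = list())
  if (nrow(runs) == 0) return(out)
  runs <- arrange(runs, .data$start_s)
  kw_sbc <- find_keywords(tr, dictionary, "single_breath_count",
                          roles = "explanation")
  kw_c50 <- find_keywords(tr, dictionary, "count_to_50",
                          roles = "explanation")
  preceded <- function(kw, run_start) {
    any(kw$t_s >= run_start - lookback_s & kw$t_s < run_start)
  }
  runs$is_sbc <- vapply(runs$start_s, preceded, logical(1), kw = kw_sbc)
  runs$is_c50 <- vapply(runs$start_s, preceded, logical(1), kw = kw_c50) |
    runs$max_value >= 40

  pick <- function(flags, exclude = integer()) {
    i <- setdiff(which(flags), exclude)
    if (length(i) > 0) i[1] else NA_integer_
  }
  # prefer unambiguous assignments first
  i_c50 <- pick(runs$is_c50 & !runs$is_sbc)
  if (is.na(i_c50)) i_c50 <- pick(runs$is_c50)
  i_sbc <- pick(runs$is_sbc & !runs$is_c50, exclude = i_c50)
  if (is.na(i_sbc)) i_sbc <- pick(runs$is_sbc, exclude = i_c50)
  # order-based fallback when keywords are missing: earlier run is the
  # count to 50, later is the SBC
  if (is.na(i_c50) && is.na(i_sbc) && nrow(runs) >= 2) {
    i_c50 <- 1L
    i_sbc <- 2L
  }
  conflict <- !is.na(i_c50) && !is.na(i_sbc) && i_c50 == i_sbc
  if (conflict) i_sbc <- NA_integer_

  diagnostics <- list()
  if (!is.na(i_c50)) {
    out$count_to_50 <- runs[i_c50, ]
    out$status[["count_to_50"]] <- if (conflict) "uncertain" else "successful"
    diagnostics[["count50.rate"]] <- run_metrics(runs[i_c50, ])$rate
    diagnostics[["count50.max_value"]] <- runs$max_value[i_c50]
  }
  if (!is.na(i_sbc)) {
    out$sbc <- runs[i_sbc, ]
    out$status[["sbc"]] <- "successful"
    m <- run_metrics(runs[i_sbc, ])
    diagnostics[["sbc.max_value"]] <- runs$max_value[i_sbc]
    diagnostics[["sbc.rate"]] <- m$rate
    diagnostics[["sbc.accelerated"]] <- as.numeric(m$acceleration < -0.01)
    diagnostics[["sbc.beyond_thirty"]] <- as.numeric(runs$max_value[i_sbc] > 30)
  }
  out$diagnostics <- diagnostics
  out
}
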