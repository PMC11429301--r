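#' Locate the MG-ADL questionnaire window
#'
#' Every session opens with the examiner administering the 8-question MG-ADL
#' questionnaire; its end anchors the start of the MG-CE search. Examiners
#' paraphrase freely and on average use only about half of the scripted
#' questions, so detection is frequency-based rather than literal: a
#' question counts as found when at least `min_fraction` of its keyword bag
#' is spoken by the doctor within any `window_s` span, and questions must
#' appear in questionnaire order (later hits for earlier questions are
#' discarded).
#'
#' The questionnaire end is the last patient word before whichever comes
#' first after the last detected question: the first doctor utterance of any
#' MG-CE explanation keyword, or a `silence_s` gap in doctor speech.
#'
#' @param tr A cleaned transcript.
#' @param dictionary Keyword dictionary with `adl_questions` bags.
#' @param min_fraction Fraction of a question's keyword bag that must occur
#'   (default 2/3).
#' @param window_s Span within which the keywords must co-occur (seconds).
#' @param min_questions Questions needed for a `successful` status
#'   (default 4 of 8).
#' @param silence_s Doctor-speech silence that closes the questionnaire.
#' @return A list with `interval` (`c(start_s, end_s)` or `NULL`),
#'   `questions` (tibble `question`, `t_s`), `status`, and `diagnostics`.
#' @export
detect_adl <- function(tr, dictionary, min_fraction = 2 / 3, window_s = 30,
                       min_questions = 4, silence_s = 10) {
  questions <- names(dictionary$adl_questions)
  none <- list(interval = NULL,
               questions = tibble(question = character(), t_s = numeric()),
               status = "unavailable",
               diagnostics = list(n_questions = 0))
  if (nrow(tr) == 0) return(none)

  # candidate anchors per question: times t such that >= ceil(frac * K)
  # distinct keywords of the bag are spoken by the doctor in [t, t + window]
  candidates <- lapply(questions, function(q) {
    bag <- dictionary$adl_questions[[q]]
    hits <- purrr::map_dfr(bag, function(kw) {
      h <- find_phrase(tr, kw, speaker = "doctor")
      if (nrow(h) > 0) h$keyword <- kw
      h
    })
    if (nrow(hits) == 0) return(numeric())
    need <- ceiling(min_fraction * length(bag))
    anchors <- sort(unique(hits$t_s))
    ok <- vapply(anchors, function(t0) {
      inwin <- hits$t_s >= t0 & hits$t_s <= t0 + window_s
      length(unique(hits$keyword[inwin])) >= need
    }, logical(1))
    anchors[ok]
  })
  names(candidates) <- questions

  # monotone assignment in questionnaire order
  assigned <- tibble(question = character(), t_s = numeric())
  prev <- -Inf
  for (q in questions) {
    cand <- candidates[[q]]
    cand <- cand[cand >= prev]
    if (length(cand) > 0) {
      assigned <- bind_rows(assigned, tibble(question = q, t_s = cand[1]))
      prev <- cand[1]
    }
  }
  n_found <- nrow(assigned)
  if (n_found == 0) return(none)

  t_last <- max(assigned$t_s)

  # cutoff 1: first doctor MG-CE explanation keyword after the last question
  mgce_ids <- setdiff(MGCE_TESTS, "adl")
  kw <- find_keywords(tr, dictionary, mgce_ids, roles = "explanation",
                      speaker = "doctor")
  kw <- kw$t_s[kw$t_s > t_last]
  cut_kw <- if (length(kw) > 0) min(kw) else Inf

  # cutoff 2: a silence_s gap in doctor speech after the last question
  doc <- filter(tr, .data$speaker == "doctor", .data$end_s >= t_last)
  cut_sil <- Inf
  if (nrow(doc) >= 2) {
    gaps <- doc$start_s[-1] - doc$end_s[-nrow(doc)]
    i <- which(gaps > silence_s)
    if (length(i) > 0) cut_sil <- doc$end_s[i[1]] + silence_s
  }
  cutoff <- min(cut_kw, cut_sil, max(tr$end_s))

  pat <- filter(tr, .data$speaker == "patient", .data$end_s <= cutoff,
                .data$end_s >= t_last)
  adl_end <- if (nrow(pat) > 0) max(pat$end_s) else min(cutoff, max(tr$end_s))
  start <- min(tr$start_s)
  adl_end <- max(adl_end, start)

  list(
    interval = c(start, adl_end),
    questions = assigned,
    status = if (n_found >= min_questions) "successful" else "uncertain",
    diagnostics = list(
      n_questions = n_found,
      end_by_keyword = as.numeric(is.finite(cut_kw) && cut_kw <= cut_sil)
    )
  )
}
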