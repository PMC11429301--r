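#' Localize the cheek-puff / tongue-to-cheek phase
#'
#' These two brief facial tests are hard to segment individually, so they
#' are treated as one phase that is located and then excluded from all later
#' searches. Instruction keyword hits for both exercises are gathered
#' outside windows already claimed by other tests; when at least two hits
#' exist, the exact two-cluster split of their times ([cluster_two()])
#' yields one mean start estimate per exercise. The phase spans from
#' `pad_before_s` before the first hit to `pad_after_s` after the last hit
#' (the active maneuvers last only a few seconds, and the phase is only
#' excluded, never scored, so a generous pad is safe).
#'
#' @param tr A cleaned transcript.
#' @param dictionary Keyword dictionary.
#' @param excluded_windows Optional tibble/data frame with `start_s`,
#'   `end_s`: windows already claimed (ADL, counting); hits inside them are
#'   ignored.
#' @param pad_before_s,pad_after_s Padding around the extreme hits defining
#'   the discardable phase.
#' @param session_end_s Clip bound for the phase end.
#' @return A list with `phase` (`c(start_s, end_s)` or `NULL`), `starts`
#'   (named numeric `c(cheek_puff=, tongue_to_cheek=)` or `NULL`),
#'   `status`, and `diagnostics` (`cheek.hits`, `tongue.hits`,
#'   `needs_vision_fallback`).
#' @export
detect_cheek_tongue <- function(tr, dictionary, excluded_windows = NULL,
                                pad_before_s = 5, pad_after_s = 30,
                                session_end_s = Inf) {
  hits <- find_keywords(tr, dictionary, c("cheek_puff", "tongue_to_cheek"),
                        roles = "explanation")
  if (!is.null(excluded_windows) && nrow(hits) > 0 &&
      nrow(excluded_windows) > 0) {
    keep <- rep(TRUE, nrow(hits))
    for (i in seq_len(nrow(excluded_windows))) {
      keep <- keep & !(hits$t_s >= excluded_windows$start_s[i] &
                         hits$t_s < excluded_windows$end_s[i])
    }
    hits <- hits[keep, ]
  }
  n_cheek <- sum(hits$test == "cheek_puff")
  n_tongue <- sum(hits$test == "tongue_to_cheek")
  diagnostics <- list(cheek.hits = n_cheek, tongue.hits = n_tongue,
                      needs_vision_fallback = 0)
  if (nrow(hits) < 2) {
    diagnostics$needs_vision_fallback <- 1
    return(list(phase = NULL, starts = NULL, status = "unavailable",
                diagnostics = diagnostics))
  }
  cl <- cluster_two(hits$t_s)
  t1 <- cl$means[1]
  t2 <- cl$means[2]
  # assign the earlier cluster mean to whichever exercise was introduced
  # first; the instruction order is not assumed
  first_cheek <- if (n_cheek > 0) min(hits$t_s[hits$test == "cheek_puff"]) else Inf
  first_tongue <- if (n_tongue > 0) min(hits$t_s[hits$test == "tongue_to_cheek"]) else Inf
  starts <- if (first_cheek <= first_tongue) {
    c(cheek_puff = t1, tongue_to_cheek = t2)
  } else {
    c(cheek_puff = t2, tongue_to_cheek = t1)
  }
  phase <- c(max(0, min(hits$t_s) - pad_before_s),
             min(session_end_s, max(hits$t_s) + pad_after_s))
  status <- if (n_cheek >= 1 && n_tongue >= 1) "successful" else "uncertain"
  list(phase = phase, starts = starts, status = status,
       diagnostics = diagnostics)
}
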