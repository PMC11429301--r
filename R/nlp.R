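#' Default keyword dictionary
#'
#' Loads the shipped keyword dictionary: for each test, the phrases an
#' examiner typically uses to introduce it (`explanation`) or to coach the
#' patient through it (`validation`), plus the eight MG-ADL question keyword
#' bags. The dictionary is a plain list and fully editable; a custom one can
#' be loaded from any JSON file with the same layout.
#'
#' @param path Optional path to a dictionary JSON file; defaults to the
#'   dictionary shipped with the package.
#' @return A list with elements `tests` (per-test phrase lists) and
#'   `adl_questions` (named keyword bags `q1`..`q8`).
#' @export
default_dictionary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mgce_keywords.json", package = "mgcexam")
  }
  dict <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  dict$tests <- lapply(dict$tests, function(x) {
    list(explanation = as.character(x$explanation %||% character()),
         validation = as.character(x$validation %||% character()))
  })
  dict$adl_questions <- lapply(dict$adl_questions, as.character)
  validate_dictionary(dict)
}

validate_dictionary <- function(dict) {
  missing <- setdiff(MGCE_TESTS, names(dict$tests))
  if (length(missing) > 0) {
    abort(paste0("dictionary lacks test(s): ", paste(missing, collapse = ", ")))
  }
  phr <- unlist(lapply(dict$tests, unlist), use.names = FALSE)
  if (any(phr != tolower(phr))) abort("dictionary phrases must be lowercase")
  if (length(dict$adl_questions) != 8) {
    abort("dictionary must define exactly 8 ADL question keyword bags")
  }
  dict
}

# Dash-like punctuation is turned into a separator before tokenization so
# that "tongue-to-cheek" matches the phrase "tongue to cheek"; all other
# punctuation (Unicode P* and symbol marks) is deleted in place, so
# "don't" -> "dont".
clean_token <- function(x) {
  x <- tolower(x)
  x <- stringr::str_replace_all(x, "[\\p{Pd}/]", " ")
  x <- stringr::str_remove_all(x, "[\\p{P}\\p{S}]")
  stringr::str_squish(x)
}

#' Clean a transcript for keyword search
#'
#' Lowercases every word, removes punctuation, and drops words that become
#' empty. Hyphenated tokens are split into their parts (each part keeps the
#' original word's timestamps) so that dictionary phrases like
#' "tongue to cheek" remain matchable. Idempotent; timestamps are never
#' altered.
#'
#' @param tr A [transcript()] tibble.
#' @return A cleaned transcript tibble.
#' @export
clean_transcript <- function(tr) {
  validate_transcript(tr)
  if (nrow(tr) == 0) return(tr)
  cleaned <- clean_token(tr$text)
  parts <- stringr::str_split(cleaned, stringr::fixed(" "))
  counts <- lengths(parts)
  out <- tr[rep(seq_len(nrow(tr)), counts), ]
  out$text <- unlist(parts)
  out <- out[nzchar(out$text), ]
  restore_transcript(out, tr)
}

#' Find a phrase in a transcript
#'
#' Literal multi-word phrase search with timestamps: the transcript is
#' scanned left to right; a match requires the phrase's words to occur
#' contiguously (no interleaved words) with at most `max_gap_s` of silence
#' between consecutive words. Matches are non-overlapping, resolved greedily
#' left to right, and timestamped at the start of their first word.
#'
#' @param tr A cleaned transcript (see [clean_transcript()]).
#' @param phrase Phrase string (will be cleaned the same way); non-empty.
#' @param window Optional numeric `c(start_s, end_s)`; only matches whose
#'   first word starts inside the half-open window are returned.
#' @param speaker Optional speaker filter applied to the first matched word.
#' @param max_gap_s Maximum silence between consecutive matched words
#'   (seconds, default 2) so transcription pauses do not break a phrase.
#' @return A tibble with columns `phrase`, `t_s`, `end_s`, `speaker`,
#'   `first_idx`, `last_idx`, in time order.
#' @examples
#' tr <- clean_transcript(transcript(
#'   c("please", "look", "up", "at", "the", "ceiling"),
#'   start_s = 0:5, end_s = 0:5 + 0.4, speaker = "doctor"))
#' find_phrase(tr, "look up")
#' @export
find_phrase <- function(tr, phrase, window = NULL, speaker = NULL,
                        max_gap_s = 2) {
  phrase <- stringr::str_squish(clean_token(phrase))
  if (!nzchar(phrase)) abort("phrase must be non-empty after cleaning")
  tokens <- strsplit(phrase, " ", fixed = TRUE)[[1]]
  m <- length(tokens)
  n <- nrow(tr)
  empty <- tibble(phrase = character(), t_s = numeric(), end_s = numeric(),
                  speaker = character(), first_idx = integer(),
                  last_idx = integer())
  if (n < m) return(empty)
  cand <- which(tr$text == tokens[1])
  cand <- cand[cand + m - 1 <= n]
  if (m > 1) {
    for (k in 2:m) {
      keep <- tr$text[cand + k - 1] == tokens[k] &
        (tr$start_s[cand + k - 1] - tr$end_s[cand + k - 2]) <= max_gap_s
      cand <- cand[keep]
      if (length(cand) == 0) break
    }
  }
  if (!is.null(window) && length(cand) > 0) {
    cand <- cand[tr$start_s[cand] >= window[1] & tr$start_s[cand] < window[2]]
  }
  if (!is.null(speaker) && length(cand) > 0) {
    cand <- cand[tr$speaker[cand] == speaker]
  }
  if (length(cand) == 0) return(empty)
  # greedy non-overlap: keep a candidate only if it starts after the last
  # kept match ends
  kept <- integer()
  last_end <- 0L
  for (i in cand) {
    if (i > last_end) {
      kept <- c(kept, i)
      last_end <- i + m - 1L
    }
  }
  tibble(
    phrase = phrase,
    t_s = tr$start_s[kept],
    end_s = tr$end_s[kept + m - 1L],
    speaker = tr$speaker[kept],
    first_idx = kept,
    last_idx = kept + m - 1L
  )
}

#' Find all dictionary keywords in a transcript
#'
#' Union of [find_phrase()] over every explanation/validation phrase of the
#' requested tests, labeled with the test and phrase role and sorted by
#' time.
#'
#' @param tr A cleaned transcript.
#' @param dictionary A dictionary (see [default_dictionary()]).
#' @param test_ids Tests to search for (default: all).
#' @param roles Phrase roles to include.
#' @inheritParams find_phrase
#' @return A tibble with columns `test`, `role`, `phrase`, `t_s`, `end_s`,
#'   `speaker`, `first_idx`, `last_idx`.
#' @export
find_keywords <- function(tr, dictionary, test_ids = NULL,
                          roles = c("explanation", "validation"),
                          window = NULL, speaker = NULL, max_gap_s = 2) {
  test_ids <- test_ids %||% MGCE_TESTS
  unknown <- setdiff(test_ids, MGCE_TESTS)
  if (length(unknown) > 0) {
    abort(paste0("unknown test id(s): ", paste(unknown, collapse = ", ")))
  }
  hits <- purrr::map_dfr(test_ids, function(id) {
    purrr::map_dfr(roles, function(role) {
      phrases <- dictionary$tests[[id]][[role]]
      purrr::map_dfr(phrases, function(p) {
        h <- find_phrase(tr, p, window = window, speaker = speaker,
                         max_gap_s = max_gap_s)
        if (nrow(h) > 0) {
          h$test <- id
          h$role <- role
        }
        h
      })
    })
  })
  if (nrow(hits) == 0) {
    return(tibble(test = character(), role = character(), phrase = character(),
                  t_s = numeric(), end_s = numeric(), speaker = character(),
                  first_idx = integer(), last_idx = integer()))
  }
  arrange(select(hits, "test", "role", "phrase", "t_s", "end_s", "speaker",
                 "first_idx", "last_idx"), .data$t_s)
}

#' Exact two-cluster split of one-dimensional timestamps
#'
#' Deterministic, globally optimal two-means in one dimension: the points
#' are sorted and every split point is scanned for the minimal total
#' within-cluster sum of squares (for one dimension the optimal 2-means
#' partition is always an interval split of the sorted values). This
#' replaces iterative k-means so that identical inputs always give
#' identical clusters.
#'
#' @param timestamps Numeric vector, length >= 2.
#' @return A list with `means` (sorted, `means[1] <= means[2]`),
#'   `assignment` (1/2 per input point, in input order), `wss` (total
#'   within-cluster sum of squares), and `degenerate` (`TRUE` when all
#'   points coincide).
#' @examples
#' cluster_two(c(10, 11, 200, 201))
#' @export
cluster_two <- function(timestamps) {
  x <- as.numeric(timestamps)
  n <- length(x)
  if (n < 2) abort("cluster_two needs at least 2 timestamps")
  if (any(!is.finite(x))) abort("timestamps must be finite")
  ord <- order(x)
  xs <- x[ord]
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  k <- seq_len(n - 1)
  wss_left <- cs2[k] - cs[k]^2 / k
  wss_right <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  tot <- wss_left + wss_right
  kbest <- which.min(tot)
  m1 <- cs[kbest] / kbest
  m2 <- (cs[n] - cs[kbest]) / (n - kbest)
  assignment <- integer(n)
  assignment[ord] <- rep(c(1L, 2L), c(kbest, n - kbest))
  list(
    means = c(m1, m2),
    assignment = assignment,
    wss = tot[kbest],
    degenerate = isTRUE(all(xs == xs[1]))
  )
}

#' Word rate within an interval
#'
#' Number of words (optionally restricted to one speaker) whose start time
#' falls in the half-open interval, divided by the interval duration.
#'
#' @param tr A transcript tibble.
#' @param interval Numeric `c(start_s, end_s)` with positive duration.
#' @param speaker Optional speaker filter.
#' @return Words per second.
#' @export
word_rate <- function(tr, interval, speaker = NULL) {
  dur <- interval[2] - interval[1]
  if (!is.finite(dur) || dur <= 0) {
    abort("word_rate requires an interval of positive duration")
  }
  w <- tr$start_s >= interval[1] & tr$start_s < interval[2]
  if (!is.null(speaker)) w <- w & tr$speaker == speaker
  sum(w) / dur
}
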