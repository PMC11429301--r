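#' Build a detected-segment row
#'
#' One row of the segmentation output: the time interval assigned to a test
#' (absent when the test could not be located), a status, an ocular
#' detectability class where applicable, and free-form numeric diagnostics.
#' Intervals are half-open `[start_s, end_s)`.
#'
#' @param test One of [mgce_tests()].
#' @param start_s,end_s Interval bounds in seconds, or `NA` when absent.
#' @param status `"successful"`, `"uncertain"`, or `"unavailable"`.
#' @param detectability `"none"`, `"partial"`, `"full"` (ocular tests only),
#'   else `NA`.
#' @param diagnostics Named list of numbers.
#' @return A one-row tibble with a `diagnostics` list-column.
#' @export
detected_segment <- function(test, start_s = NA_real_, end_s = NA_real_,
                             status = "unavailable",
                             detectability = NA_character_,
                             diagnostics = list()) {
  stopifnot(test %in% MGCE_TESTS, status %in% SEGMENT_STATUSES)
  if (status == "unavailable") {
    start_s <- NA_real_
    end_s <- NA_real_
  }
  if (!is.na(start_s) && !is.na(end_s) && end_s < start_s) {
    abort("segment interval must satisfy start_s <= end_s")
  }
  tibble(
    test = test,
    start_s = as.numeric(start_s),
    end_s = as.numeric(end_s),
    status = status,
    detectability = as.character(detectability),
    diagnostics = list(diagnostics)
  )
}

empty_segments <- function() {
  bind_rows(lapply(MGCE_TESTS, detected_segment))
}

#' Assemble a segmentation report
#'
#' The report is the end product of [segment_session()]: one detected
#' segment per test, optional item scores per scored domain, the total
#' MG-CE score when all eight domains are usable, and a fingerprint of the
#' configuration that produced it.
#'
#' @param session_id Session identifier.
#' @param segments A tibble of [detected_segment()] rows covering every
#'   test in [mgce_tests()] exactly once.
#' @param item_scores Named integer vector over [mgce_domains()]
#'   (values 0-4), or `NULL` when scoring has not been run.
#' @param config The configuration list used (fingerprinted into the
#'   report).
#' @return An object of class `mgce_report`.
#' @seealso [score_report()], [write_report()], [export_webvtt()]
#' @export
mgce_report <- function(session_id, segments, item_scores = NULL,
                        config = list()) {
  stopifnot(setequal(segments$test, MGCE_TESTS),
            !anyDuplicated(segments$test))
  segments <- segments[match(MGCE_TESTS, segments$test), ]
  ok <- is.na(segments$start_s) | is.na(segments$end_s) |
    segments$end_s >= segments$start_s
  if (!all(ok)) abort("report contains an inverted interval")
  total <- NULL
  if (!is.null(item_scores)) total <- total_score(item_scores)
  structure(
    list(
      session_id = session_id,
      segments = segments,
      item_scores = item_scores,
      total = total,
      config_fingerprint = config_fingerprint(config)
    ),
    class = "mgce_report"
  )
}

#' @export
print.mgce_report <- function(x, ...) {
  cat("<mgce_report> session", x$session_id, "\n")
  det <- sum(!is.na(x$segments$start_s))
  cat("  segments:", det, "of", nrow(x$segments), "located\n")
  if (!is.null(x$item_scores)) {
    tot <- x$total
    if (tot$complete) {
      cat("  total MG-CE score:", tot$total, "/ 24\n")
    } else {
      cat("  total MG-CE score: incomplete (partial",
          tot$partial_sum, "over", 8 - length(tot$unusable), "domains)\n")
    }
  }
  invisible(x)
}

#' Tidy a segmentation report
#'
#' Returns the per-test segment table; `glance()` returns a one-row summary.
#'
#' @param x An `mgce_report`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mgce_report
#' @export
tidy.mgce_report <- function(x, ...) {
  out <- x$segments
  out$duration_s <- out$end_s - out$start_s
  out$session_id <- x$session_id
  select(out, "session_id", "test", "start_s", "end_s", "duration_s",
         "status", "detectability", "diagnostics")
}

#' @rdname tidy.mgce_report
#' @method glance mgce_report
#' @export
glance.mgce_report <- function(x, ...) {
  tibble(
    session_id = x$session_id,
    n_located = sum(!is.na(x$segments$start_s)),
    n_successful = sum(x$segments$status == "successful"),
    n_uncertain = sum(x$segments$status == "uncertain"),
    n_unavailable = sum(x$segments$status == "unavailable"),
    total_score = if (!is.null(x$total) && x$total$complete)
      x$total$total else NA_integer_,
    complete = !is.null(x$total) && x$total$complete,
    config_fingerprint = x$config_fingerprint
  )
}

# Polynomial rolling hash over the canonical JSON of the configuration;
# enough to tag a report with the settings that produced it (not
# cryptographic). Exact in double arithmetic: h stays below 2^36.
config_fingerprint <- function(config) {
  if (length(config) > 0) config <- config[order(names(config))]
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", h)
}

ms <- function(x) ifelse(is.na(x), NA, round(x * 1000))

#' Write / read a segmentation report as JSON
#'
#' The JSON schema is versioned (`"schema": "mgce-report/1"`); all times are
#' serialized as integer milliseconds so that a write/read round trip
#' reproduces the report exactly.
#'
#' @param report An `mgce_report`.
#' @param path Output path.
#' @return `path` invisibly; `read_report()` returns the `mgce_report`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "mgce_report"))
  seg <- report$segments
  segments <- lapply(seq_len(nrow(seg)), function(i) {
    s <- list(
      test = seg$test[i],
      status = seg$status[i]
    )
    if (!is.na(seg$start_s[i])) {
      s$start_ms <- ms(seg$start_s[i])
      s$end_ms <- ms(seg$end_s[i])
    }
    if (!is.na(seg$detectability[i])) s$detectability <- seg$detectability[i]
    d <- seg$diagnostics[[i]]
    if (length(d) > 0) s$diagnostics <- d
    s
  })
  out <- list(
    schema = "mgce-report/1",
    session_id = report$session_id,
    config_fingerprint = report$config_fingerprint,
    segments = segments
  )
  if (!is.null(report$item_scores)) {
    out$item_scores <- as.list(report$item_scores)
    out$total <- report$total
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(raw$schema, "mgce-report/1")) {
    abort(paste0("unsupported report schema: ", raw$schema %||% "<none>"))
  }
  segments <- bind_rows(lapply(raw$segments, function(s) {
    detected_segment(
      test = s$test,
      start_s = if (is.null(s$start_ms)) NA_real_ else s$start_ms / 1000,
      end_s = if (is.null(s$end_ms)) NA_real_ else s$end_ms / 1000,
      status = s$status,
      detectability = s$detectability %||% NA_character_,
      diagnostics = lapply(s$diagnostics %||% list(), as.numeric)
    )
  }))
  scores <- NULL
  if (!is.null(raw$item_scores)) {
    scores <- unlist(raw$item_scores)
    scores <- setNames(as.integer(scores), names(raw$item_scores))
  }
  rep <- mgce_report(raw$session_id, segments, item_scores = scores)
  rep$config_fingerprint <- raw$config_fingerprint
  rep
}

vtt_time <- function(t) {
  h <- floor(t / 3600)
  m <- floor((t - 3600 * h) / 60)
  s <- t - 3600 * h - 60 * m
  sprintf("%02d:%02d:%06.3f", h, m, s)
}

#' Export report segments as WebVTT cues
#'
#' Writes one cue per located segment (test id and status as the cue text),
#' suitable for overlaying on the session video in any WebVTT-aware player.
#'
#' @param report An `mgce_report`.
#' @param path Output `.vtt` path.
#' @return `path`, invisibly.
#' @export
export_webvtt <- function(report, path) {
  stopifnot(inherits(report, "mgce_report"))
  seg <- filter(report$segments, !is.na(.data$start_s))
  seg <- arrange(seg, .data$start_s)
  lines <- "WEBVTT"
  for (i in seq_len(nrow(seg))) {
    lines <- c(
      lines, "",
      paste0(vtt_time(seg$start_s[i]), " --> ", vtt_time(seg$end_s[i])),
      paste0(toupper(seg$test[i]), " [", seg$status[i], "]")
    )
  }
  writeLines(lines, path)
  invisible(path)
}
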