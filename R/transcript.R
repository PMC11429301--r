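#' Build a transcript tibble
#'
#' A transcript is an ordered, word-level record of the session audio: one row
#' per recognized word, with start/end timestamps in seconds from session
#' start, a speaker label, and the recognizer's confidence. All downstream
#' keyword search operates on this table.
#'
#' @param text Character vector of word tokens.
#' @param start_s,end_s Numeric vectors, seconds from session start.
#' @param speaker Character vector; one of `"doctor"`, `"patient"`,
#'   `"unknown"` (recycled if length 1).
#' @param confidence Numeric in `[0, 1]` (recycled if length 1).
#' @param session_id Session identifier stored as an attribute.
#' @return A tibble of class `mgce_transcript` with columns `text`,
#'   `start_s`, `end_s`, `speaker`, `confidence`, sorted by `start_s`.
#' @examples
#' transcript(c("look", "up"), c(1.0, 1.4), c(1.3, 1.7), "doctor")
#' @export
transcript <- function(text = character(), start_s = numeric(),
                       end_s = numeric(), speaker = "unknown",
                       confidence = 1, session_id = "session") {
  tr <- tibble(
    text = as.character(text),
    start_s = as.numeric(start_s),
    end_s = as.numeric(end_s),
    speaker = rep_len(as.character(speaker), length(text)),
    confidence = rep_len(as.numeric(confidence), length(text))
  )
  tr <- dplyr::arrange(tr, .data$start_s)
  attr(tr, "session_id") <- session_id
  class(tr) <- c("mgce_transcript", class(tr))
  validate_transcript(tr)
}

validate_transcript <- function(tr) {
  stopifnot(all(c("text", "start_s", "end_s", "speaker", "confidence")
                %in% names(tr)))
  if (nrow(tr) == 0) return(tr)
  if (any(is.na(tr$start_s)) || any(tr$start_s < 0)) {
    abort("transcript timestamps must be non-negative and non-missing")
  }
  if (any(tr$end_s < tr$start_s)) {
    abort("transcript has a word with end_s < start_s")
  }
  if (is.unsorted(tr$start_s)) {
    abort("transcript words must be sorted by start_s")
  }
  bad <- !tr$speaker %in% SPEAKERS
  if (any(bad)) {
    abort(paste0("unknown speaker label: ", tr$speaker[which(bad)[1]]))
  }
  if (any(tr$confidence < 0 | tr$confidence > 1)) {
    abort("word confidence must lie in [0, 1]")
  }
  tr
}

session_id <- function(x) attr(x, "session_id") %||% "session"

restore_transcript <- function(tr, template) {
  attr(tr, "session_id") <- session_id(template)
  if (!inherits(tr, "mgce_transcript")) {
    class(tr) <- c("mgce_transcript", class(tr))
  }
  tr
}

#' Read a transcript from JSON
#'
#' Reads a word-level transcript in the speech-to-text export layout:
#' `{"unit": "ms", "session_id": ..., "words": [{"text", "start", "end",
#' "speaker", "confidence"}, ...]}`. The `unit` field declares whether word
#' timestamps are in milliseconds (`"ms"`, the usual recognizer output) or
#' seconds (`"s"`); times are converted to seconds on load. Speaker channel
#' labels (e.g. `"A"`/`"B"`) are mapped to `doctor`/`patient` via
#' `examiner_channel`; any other label becomes `unknown`. Words are sorted
#' by start time.
#'
#' @param path Path to the JSON file.
#' @param examiner_channel Speaker label in the file that denotes the
#'   examiner (default `"A"`); the remaining two-party label becomes
#'   `patient`.
#' @return An [transcript()] tibble.
#' @export
read_transcript <- function(path, examiner_channel = "A") {
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) abort(paste0("malformed transcript JSON: ",
                                     conditionMessage(e)))
  )
  unit <- raw$unit %||% "ms"
  if (!unit %in% c("ms", "s")) abort(paste0("unknown time unit: ", unit))
  scale <- if (unit == "ms") 1e-3 else 1
  words <- raw$words
  if (is.null(words) || length(words) == 0 ||
      (is.data.frame(words) && nrow(words) == 0)) {
    return(transcript(session_id = raw$session_id %||% "session"))
  }
  words <- as_tibble(words)
  needed <- c("text", "start", "end")
  missing <- setdiff(needed, names(words))
  if (length(missing) > 0) {
    abort(paste0("transcript words lack field(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(words$start < 0 | words$end < 0, na.rm = TRUE)) {
    bad <- which(words$start < 0 | words$end < 0)[1]
    abort(paste0("negative timestamp in word record ", bad,
                 " (text: ", words$text[bad], ")"))
  }
  raw_speaker <- if ("speaker" %in% names(words)) {
    as.character(words$speaker)
  } else {
    rep("unknown", nrow(words))
  }
  channels <- unique(raw_speaker)
  other <- setdiff(channels, examiner_channel)
  speaker <- dplyr::case_when(
    raw_speaker %in% SPEAKERS ~ raw_speaker,
    raw_speaker == examiner_channel ~ "doctor",
    length(other) == 1 & raw_speaker %in% other ~ "patient",
    .default = "unknown"
  )
  transcript(
    text = words$text,
    start_s = words$start * scale,
    end_s = words$end * scale,
    speaker = speaker,
    confidence = if ("confidence" %in% names(words)) words$confidence else 1,
    session_id = raw$session_id %||% "session"
  )
}

#' Write a transcript to JSON
#'
#' Serializes in the layout read back by [read_transcript()]. Times are
#' written as integer milliseconds so that a write/read round trip is exact.
#'
#' @param tr A transcript tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(tr, path) {
  validate_transcript(tr)
  out <- list(
    unit = "ms",
    session_id = session_id(tr),
    words = lapply(seq_len(nrow(tr)), function(i) {
      list(
        text = tr$text[i],
        start = round(tr$start_s[i] * 1000),
        end = round(tr$end_s[i] * 1000),
        speaker = tr$speaker[i],
        confidence = tr$confidence[i]
      )
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
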