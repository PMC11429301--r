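#' Build a gaze stream tibble
#'
#' A gaze stream is the frame-by-frame output of a gaze-direction classifier
#' applied to the patient's eye region: one row per video frame with a label
#' in `up`/`left`/`right`/`neutral`/`no_value` and the classifier confidence.
#' `no_value` means no accepted classification for the frame (no face found,
#' or confidence below the acceptance threshold).
#'
#' @param t_s Numeric vector of frame times (seconds), strictly increasing.
#' @param label Character vector of gaze labels.
#' @param confidence Numeric in `[0, 1]` (recycled).
#' @param fps Nominal frame rate (frames per second, > 0), stored as an
#'   attribute.
#' @return A tibble of class `mgce_gaze` with columns `t_s`, `label`,
#'   `confidence`.
#' @export
gaze_stream <- function(t_s, label, confidence = 1, fps = NULL) {
  n <- length(t_s)
  if (is.null(fps)) {
    fps <- if (n >= 2) 1 / median(diff(t_s)) else 30
  }
  g <- tibble(
    t_s = as.numeric(t_s),
    label = as.character(label),
    confidence = rep_len(as.numeric(confidence), n)
  )
  attr(g, "fps") <- fps
  class(g) <- c("mgce_gaze", class(g))
  validate_gaze(g)
}

validate_gaze <- function(g) {
  if (nrow(g) == 0) abort("gaze stream is empty")
  if (any(diff(g$t_s) <= 0)) abort("gaze frame times must strictly increase")
  bad <- !g$label %in% GAZE_LABELS
  if (any(bad)) abort(paste0("unknown gaze label: ", g$label[which(bad)[1]]))
  if (any(g$confidence < 0 | g$confidence > 1)) {
    abort("gaze confidence must lie in [0, 1]")
  }
  fps <- stream_fps(g)
  if (!is.numeric(fps) || fps <= 0) abort("fps must be > 0")
  g
}

#' @rdname gaze_stream
#' @param x A stream tibble.
#' @export
stream_fps <- function(x) attr(x, "fps")

#' Build a pose stream tibble
#'
#' A pose stream records, per video frame, the normalized image coordinates
#' and visibility of a set of body landmarks (BlazePose numbering: `x`
#' rightward, `y` downward, both in `[0, 1]` of the image; visibility in
#' `[0, 1]`). Layout is wide: columns `x_<id>`, `y_<id>`, `v_<id>` per
#' landmark id, plus `t_s` and `present` (whether a body was detected at
#' all).
#'
#' @param frames A data frame with columns `t_s`, `present`, and landmark
#'   triplets `x_<id>`, `y_<id>`, `v_<id>`.
#' @param fps Nominal frame rate, stored as an attribute.
#' @return A tibble of class `mgce_pose`.
#' @export
pose_stream <- function(frames, fps = NULL) {
  p <- as_tibble(frames)
  if (is.null(fps)) {
    fps <- if (nrow(p) >= 2) 1 / median(diff(p$t_s)) else 30
  }
  attr(p, "fps") <- fps
  class(p) <- c("mgce_pose", setdiff(class(p), "mgce_pose"))
  validate_pose(p)
}

validate_pose <- function(p) {
  stopifnot(all(c("t_s", "present") %in% names(p)))
  if (nrow(p) == 0) abort("pose stream is empty")
  if (any(diff(p$t_s) <= 0)) abort("pose frame times must strictly increase")
  vcols <- grep("^v_", names(p), value = TRUE)
  for (vc in vcols) {
    v <- p[[vc]]
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      abort(paste0("landmark visibility out of [0, 1] in column ", vc))
    }
  }
  xy <- grep("^[xy]_", names(p), value = TRUE)
  pres <- as.logical(p$present)
  for (cc in xy) {
    if (any(pres & !is.finite(p[[cc]]) & !is.na(p[[cc]]))) {
      abort(paste0("non-finite coordinate in column ", cc))
    }
  }
  p
}

#' Read a gaze or pose stream from CSV
#'
#' Gaze CSV layout: `t_s,label,confidence`. Pose CSV layout: `t_s,present`
#' followed by `x_<id>,y_<id>,v_<id>` triplets, one per landmark. Streams
#' with missing columns or non-increasing frame times are rejected.
#'
#' @param path CSV path.
#' @param kind `"gaze"` or `"pose"`.
#' @param fps Frame rate override; inferred from the median frame spacing
#'   when `NULL`.
#' @return A [gaze_stream()] or [pose_stream()] tibble.
#' @export
read_stream <- function(path, kind = c("gaze", "pose"), fps = NULL) {
  kind <- match.arg(kind)
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (kind == "gaze") {
    missing <- setdiff(c("t_s", "label", "confidence"), names(d))
    if (length(missing) > 0) {
      abort(paste0("gaze CSV lacks column(s): ",
                   paste(missing, collapse = ", ")))
    }
    gaze_stream(d$t_s, d$label, d$confidence, fps = fps)
  } else {
    missing <- setdiff(c("t_s", "present"), names(d))
    if (length(missing) > 0) {
      abort(paste0("pose CSV lacks column(s): ",
                   paste(missing, collapse = ", ")))
    }
    d$present <- as.logical(d$present)
    pose_stream(d, fps = fps)
  }
}

#' Write a gaze or pose stream to CSV
#'
#' Inverse of [read_stream()]; frame times are written at millisecond
#' precision so a write/read round trip is exact.
#'
#' @param stream A gaze or pose stream tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path) {
  out <- as_tibble(stream)
  out$t_s <- round(out$t_s, 3)
  if ("present" %in% names(out)) out$present <- as.integer(out$present)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
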