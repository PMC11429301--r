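#' Bound the ocular phase from the transcript
#'
#' The three ocular tests (ptosis, diplopia right, diplopia left) always
#' open the MG-CE. Keywords that start ocular exercises (e.g. "look up")
#' trigger the phase start; keywords of the following test (cheek puff)
#' mark its end. Fallbacks: the phase starts at the questionnaire end when
#' no ocular keyword is found, and runs for `fallback_len_s` when no cheek
#' keyword is found.
#'
#' @param tr A cleaned transcript.
#' @param dictionary Keyword dictionary.
#' @param adl_end End of the MG-ADL questionnaire (seconds).
#' @param fallback_len_s Phase length used when no closing keyword exists.
#' @return Numeric `c(start_s, end_s)`.
#' @export
ocular_phase_bounds <- function(tr, dictionary, adl_end,
                                fallback_len_s = 360) {
  if (nrow(tr) == 0 || !any(tr$start_s >= adl_end)) {
    abort("no transcript content after the questionnaire: unusable recording")
  }
  ocular_ids <- c("ptosis", "diplopia_right", "diplopia_left")
  starts <- find_keywords(tr, dictionary, ocular_ids, roles = "explanation",
                          window = c(adl_end, Inf))
  start <- if (nrow(starts) > 0) starts$t_s[1] else adl_end
  ends <- find_keywords(tr, dictionary, "cheek_puff", roles = "explanation",
                        window = c(start + 1e-9, Inf))
  end <- if (nrow(ends) > 0) ends$t_s[1] else start + fallback_len_s
  c(start, end)
}

#' Sliding-window gaze-class density
#'
#' For every frame time `t`, the density of a gaze class is the fraction of
#' frames labeled with that class inside the window
#' `[t - window_s/2, t + window_s/2]` (truncated at the stream edges). By
#' default the denominator counts all frames in the window, `no_value`
#' included, so periods of poor visibility get low density; set
#' `denominator = "classified"` to count only accepted frames.
#'
#' @param stream A [gaze_stream()] tibble.
#' @param label Gaze class: `"up"`, `"left"`, or `"right"` (any class
#'   accepted).
#' @param window_s Window length in seconds (default 5).
#' @param denominator `"all"` or `"classified"`.
#' @return A tibble with columns `t_s`, `density`; attributes `label` and
#'   `window_s`.
#' @export
gaze_density <- function(stream, label, window_s = 5,
                         denominator = c("all", "classified")) {
  denominator <- match.arg(denominator)
  if (nrow(stream) == 0) abort("gaze stream is empty")
  t <- stream$t_s
  half <- window_s / 2
  # frames j with t[j] in [t_i - half, t_i + half]:
  # count(<= b) - count(< a), exact on the stream's own sample times
  hi <- findInterval(t + half, t)
  lo <- findInterval(t - half, t, left.open = TRUE)
  cum_lab <- c(0, cumsum(stream$label == label))
  n_lab <- cum_lab[hi + 1] - cum_lab[lo + 1]
  n_all <- if (denominator == "all") {
    hi - lo
  } else {
    cum_cls <- c(0, cumsum(stream$label != "no_value"))
    cum_cls[hi + 1] - cum_cls[lo + 1]
  }
  d <- ifelse(n_all > 0, n_lab / n_all, 0)
  curve <- tibble(t_s = t, density = d)
  attr(curve, "label") <- label
  attr(curve, "window_s") <- window_s
  curve
}

#' Longest segment above a relative density threshold
#'
#' Finds the longest contiguous run of samples whose density strictly
#' exceeds `rel_threshold` times the curve's maximum density. Ties are
#' broken toward the earliest run; a flat-zero curve yields no segment. The
#' returned interval is half-open: its end is the first sample time after
#' the run (or the last sample plus one frame period at the stream edge).
#'
#' @param curve A density curve from [gaze_density()].
#' @param rel_threshold Fraction of the maximum density (default 0.6).
#' @return A list with `start_s`, `end_s`, `duration_s`, or `NULL` when no
#'   sample exceeds the threshold.
#' @export
longest_dense_segment <- function(curve, rel_threshold = 0.6) {
  d <- curve$density
  t <- curve$t_s
  mx <- max(d)
  if (mx <= 0) return(NULL)
  mask <- d > rel_threshold * mx
  if (!any(mask)) return(NULL)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  dt <- if (length(t) >= 2) median(diff(t)) else 1
  run_start <- t[starts[runs]]
  run_end <- ifelse(ends[runs] < length(t), t[ends[runs] + 1L],
                    t[ends[runs]] + dt)
  dur <- run_end - run_start
  best <- which(dur == max(dur))[1]  # earliest among ties
  list(start_s = run_start[best], end_s = run_end[best],
       duration_s = dur[best])
}

#' Detectability class of an ocular segment
#'
#' Segments shorter than 10 s are undetectable (`"none"`), segments of 10 to
#' 45 s inclusive are partially detectable (`"partial"`), and only segments
#' exceeding 45 s are fully detected (`"full"`).
#'
#' @param segment A segment list from [longest_dense_segment()], a numeric
#'   duration in seconds, or `NULL`.
#' @param partial_min_s,full_min_s Class boundaries (seconds).
#' @return `"none"`, `"partial"`, or `"full"`.
#' @export
classify_detectability <- function(segment, partial_min_s = 10,
                                   full_min_s = 45) {
  if (is.null(segment)) return("none")
  dur <- if (is.list(segment)) segment$duration_s else as.numeric(segment)
  if (dur < partial_min_s) "none" else if (dur <= full_min_s) "partial" else "full"
}

#' Segment the three ocular tests from the gaze stream
#'
#' Within the NLP-derived ocular phase, each test is located as the longest
#' dense segment of its own gaze class: ptosis from `up`, diplopia right
#' from `right`, diplopia left from `left`. Left/right assignment is always
#' by gaze class, never by expected order, since examiners vary the diplopia
#' order. Detectability maps to status: `full` is `successful`, `partial`
#' is `uncertain`, `none` is `unavailable`.
#'
#' @param stream A [gaze_stream()] tibble.
#' @param phase_bounds Numeric `c(start_s, end_s)` from
#'   [ocular_phase_bounds()].
#' @inheritParams gaze_density
#' @inheritParams longest_dense_segment
#' @inheritParams classify_detectability
#' @return A tibble of [detected_segment()] rows for `ptosis`,
#'   `diplopia_right`, `diplopia_left`.
#' @export
segment_ocular <- function(stream, phase_bounds, window_s = 5,
                           rel_threshold = 0.6, denominator = "all",
                           partial_min_s = 10, full_min_s = 45) {
  tests <- c(ptosis = "up", diplopia_right = "right", diplopia_left = "left")
  inphase <- stream[stream$t_s >= phase_bounds[1] &
                      stream$t_s < phase_bounds[2], ]
  purrr::map_dfr(names(tests), function(test) {
    if (nrow(inphase) == 0) {
      return(detected_segment(test, status = "unavailable",
                              detectability = "none"))
    }
    curve <- gaze_density(inphase, tests[[test]], window_s = window_s,
                          denominator = denominator)
    seg <- longest_dense_segment(curve, rel_threshold = rel_threshold)
    det <- classify_detectability(seg, partial_min_s, full_min_s)
    diag <- list(max_density = max(curve$density))
    if (det == "none") {
      detected_segment(test, status = "unavailable", detectability = "none",
                       diagnostics = diag)
    } else {
      diag$segment_duration_s <- seg$duration_s
      detected_segment(
        test, seg$start_s, seg$end_s,
        status = if (det == "full") "successful" else "uncertain",
        detectability = det, diagnostics = diag
      )
    }
  })
}

#' Render a synthetic eye-region image
#'
#' Stand-in for real eye-region crops: a bright elliptical sclera on a dark
#' background with a dark pupil disk whose offset encodes the gaze
#' direction (`up` shifts the pupil toward the top of the image, `left`
#' and `right` shift it horizontally, `neutral` is centered). Used to
#' train and exercise the toy gaze classifier; it is synthetic by design
#' and makes no claim about real eye appearance.
#'
#' @param label Gaze label: `"up"`, `"left"`, `"right"`, `"neutral"`.
#' @param width,height Image size in pixels.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param jitter_px Uniform jitter applied to the pupil center.
#' @return A numeric matrix (`height` rows by `width` columns) in `[0, 1]`.
#' @export
render_eye_region <- function(label, width = 24, height = 16,
                              noise_sd = 0.05, jitter_px = 1) {
  stopifnot(label %in% c("up", "left", "right", "neutral"))
  cx <- width / 2
  cy <- height / 2
  off <- switch(label,
                up = c(0, -height / 4),
                left = c(-width / 4, 0),
                right = c(width / 4, 0),
                neutral = c(0, 0))
  px <- cx + off[1] + runif(1, -jitter_px, jitter_px)
  py <- cy + off[2] + runif(1, -jitter_px, jitter_px)
  xs <- matrix(rep(seq_len(width), each = height), nrow = height)
  ys <- matrix(rep(seq_len(height), times = width), nrow = height)
  sclera <- ((xs - cx) / (width / 2))^2 + ((ys - cy) / (height / 2))^2 <= 1
  pupil <- (xs - px)^2 + (ys - py)^2 <= (height / 5)^2
  img <- 0.1 + 0.8 * sclera - 0.7 * pupil * sclera
  img <- img + matrix(rnorm(width * height, sd = noise_sd), nrow = height)
  pmin(pmax(img, 0), 1)
}

# Pupil-offset features: intensity-weighted centroid of the dark pixels
# inside the image, normalized to [-1, 1] around the image center.
eye_features <- function(images) {
  feats <- t(vapply(images, function(img) {
    h <- nrow(img)
    w <- ncol(img)
    dark <- pmax(0.6 - img, 0)
    tot <- sum(dark)
    if (tot == 0) return(c(0, 0))
    xs <- matrix(rep(seq_len(w), each = h), nrow = h)
    ys <- matrix(rep(seq_len(h), times = w), nrow = h)
    c((sum(dark * xs) / tot - (w + 1) / 2) / (w / 2),
      (sum(dark * ys) / tot - (h + 1) / 2) / (h / 2))
  }, numeric(2)))
  colnames(feats) <- c("cx", "cy")
  feats
}

#' Train the toy gaze classifier
#'
#' A desk-scale stand-in for the production frame classifier, honoring the
#' same contract: given an eye-region observation it returns a gaze label
#' and a confidence, and frames whose confidence does not exceed the
#' acceptance threshold are recorded as `no_value`. Features are the
#' pupil-offset centroid of the dark pixels; the class model is linear
#' discriminant analysis.
#'
#' @param train_images List of image matrices (see [render_eye_region()]).
#' @param labels Character vector of gaze labels, same length.
#' @return An object of class `mgce_gaze_classifier`.
#' @export
toy_gaze_classifier <- function(train_images, labels) {
  labels <- as.character(labels)
  stopifnot(length(train_images) == length(labels))
  if (length(unique(labels)) < 2) {
    abort("training set must contain at least 2 gaze classes")
  }
  feats <- eye_features(train_images)
  fit <- MASS::lda(feats, grouping = factor(labels))
  structure(list(fit = fit), class = "mgce_gaze_classifier")
}

#' @export
print.mgce_gaze_classifier <- function(x, ...) {
  cat("<mgce_gaze_classifier> lda on pupil-offset features; classes:",
      paste(levels(x$fit$lev), collapse = ", "), "\n")
  invisible(x)
}

#' Classify eye-region images into a gaze stream
#'
#' Applies the classifier to each image; frames whose posterior confidence
#' is not greater than `threshold` (default 0.95) are recorded as
#' `no_value`.
#'
#' @param images List of image matrices.
#' @param classifier An `mgce_gaze_classifier`.
#' @param t_s Frame times (seconds); defaults to frame index / `fps`.
#' @param fps Frame rate.
#' @param threshold Acceptance threshold on the classifier confidence.
#' @return A [gaze_stream()] tibble.
#' @export
classify_gaze <- function(images, classifier, t_s = NULL, fps = 30,
                          threshold = 0.95) {
  stopifnot(inherits(classifier, "mgce_gaze_classifier"))
  feats <- eye_features(images)
  pred <- predict(classifier$fit, feats)
  conf <- apply(pred$posterior, 1, max)
  label <- as.character(pred$class)
  label[conf <= threshold] <- "no_value"
  if (is.null(t_s)) t_s <- (seq_along(images) - 1) / fps
  gaze_stream(t_s, label, confidence = conf, fps = fps)
}
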