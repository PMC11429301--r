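PTOSIS_CATEGORIES <- c(no_ptosis = 0L, lid_above_pupil = 1L,
                       lid_at_pupil = 2L, lid_below_pupil = 3L)
CHEEK_CATEGORIES <- c(normal_seal = 0L, transverse_pucker = 1L,
                      opposes_lips_air_escapes = 2L, cannot_oppose = 3L)
TONGUE_CATEGORIES <- c(full_convex = 0L, partial_convex = 1L,
                       moves_no_deform = 2L, unable = 3L)
STS_CATEGORIES <- c(no_difficulty = 0L, slow_extra_effort = 1L,
                    uses_arms = 2L, unable = 3L)

#' Score one MG-CE item
#'
#' Maps a per-domain measurement to the categorical MG-CE item score 0
#' (normal) to 3 (severe). A score of 4 flags an examination that was
#' unusable: it is returned whenever the segment is `unavailable` or the
#' measurement is absent (`NULL`/`NA`). Bilateral domains (diplopia, arm
#' strength) must be given the more severe side's measurement.
#'
#' Domain measurements and cutoffs:
#' \describe{
#'   \item{ptosis}{category `no_ptosis`/`lid_above_pupil`/`lid_at_pupil`/
#'     `lid_below_pupil` -> 0/1/2/3.}
#'   \item{diplopia}{onset of double vision in seconds of sustained gaze:
#'     none during the full hold (`Inf`) -> 0; onset in (10, 60] s -> 1;
#'     in [1, 10] s -> 2; immediate (< 1 s) -> 3. Onsets in the unstated
#'     (60, 61] band score 0 (milder side of the gap).}
#'   \item{count_to_50}{count at first dysarthria: none (`Inf`) or at
#'     exactly 50 -> 0; 30-49 -> 1; 10-29 -> 2; 1-9 -> 3.}
#'   \item{arm_strength}{drift time in seconds: > 120 -> 0; 90-120 -> 1;
#'     10 to < 90 -> 2; < 10 -> 3.}
#'   \item{single_breath_count}{highest count reached: > 30 -> 0;
#'     25-30 -> 1 (the unstated count of exactly 30 is folded into this
#'     band); 20-24 -> 2; < 20 -> 3.}
#'   \item{sit_to_stand}{category `no_difficulty`/`slow_extra_effort`/
#'     `uses_arms`/`unable` -> 0/1/2/3.}
#'   \item{cheek_puff, tongue_to_cheek}{categories per their rubric rows.}
#' }
#'
#' @param domain One of [mgce_domains()].
#' @param measurement The domain's measurement (see Details), or `NULL`.
#' @param segment_status Status of the segment the measurement came from.
#' @return Integer item score in 0..4.
#' @examples
#' score_item("single_breath_count", 27)   # 1
#' score_item("arm_strength", 100)         # 1
#' score_item("ptosis", "lid_at_pupil")    # 2
#' @export
score_item <- function(domain, measurement,
                       segment_status = "successful") {
  stopifnot(domain %in% MGCE_DOMAINS)
  if (segment_status == "unavailable" || is.null(measurement) ||
      (length(measurement) == 1 && is.na(measurement))) {
    return(4L)
  }
  from_categories <- function(cats) {
    if (!measurement %in% names(cats)) {
      abort(paste0("unknown ", domain, " category: ", measurement))
    }
    unname(cats[[measurement]])
  }
  switch(domain,
    ptosis = from_categories(PTOSIS_CATEGORIES),
    cheek_puff = from_categories(CHEEK_CATEGORIES),
    tongue_to_cheek = from_categories(TONGUE_CATEGORIES),
    sit_to_stand = from_categories(STS_CATEGORIES),
    diplopia = {
      o <- as.numeric(measurement)
      if (o < 0) abort("diplopia onset must be non-negative")
      if (o < 1) 3L else if (o <= 10) 2L else if (o <= 60) 1L else 0L
    },
    count_to_50 = {
      c_ <- as.numeric(measurement)
      if (is.finite(c_) && (c_ < 1 || c_ > 50)) {
        abort("dysarthria onset count must be in 1..50 or Inf (none)")
      }
      if (!is.finite(c_) || c_ == 50) 0L
      else if (c_ >= 30) 1L else if (c_ >= 10) 2L else 3L
    },
    arm_strength = {
      d <- as.numeric(measurement)
      if (d < 0) abort("drift time must be non-negative")
      if (d > 120) 0L else if (d >= 90) 1L else if (d >= 10) 2L else 3L
    },
    single_breath_count = {
      n <- as.numeric(measurement)
      if (n < 0) abort("single breath count must be non-negative")
      if (n > 30) 0L else if (n >= 25) 1L else if (n >= 20) 2L else 3L
    }
  )
}

#' Total MG-CE score
#'
#' Sum of the eight item scores, defined only when every domain is usable
#' (no item scored 4). Otherwise the result is flagged incomplete and
#' carries the partial sum over the usable domains plus the list of
#' unusable ones.
#'
#' @param item_scores Named integer vector covering exactly the eight
#'   domains of [mgce_domains()], values 0-4.
#' @return A list with `complete`, `total` (0-24 or `NA`), `partial_sum`,
#'   `unusable` (character).
#' @export
total_score <- function(item_scores) {
  if (length(item_scores) != 8 || !setequal(names(item_scores), MGCE_DOMAINS)) {
    abort("item_scores must name exactly the eight MG-CE domains")
  }
  item_scores <- item_scores[MGCE_DOMAINS]
  if (any(item_scores < 0 | item_scores > 4)) {
    abort("item scores must lie in 0..4")
  }
  unusable <- names(item_scores)[item_scores == 4]
  usable <- item_scores[item_scores < 4]
  list(
    complete = length(unusable) == 0,
    total = if (length(unusable) == 0) sum(usable) else NA_integer_,
    partial_sum = sum(usable),
    unusable = unusable
  )
}

# map each scored domain to the segments it depends on
DOMAIN_TESTS <- list(
  ptosis = "ptosis",
  diplopia = c("diplopia_right", "diplopia_left"),
  cheek_puff = "cheek_puff",
  tongue_to_cheek = "tongue_to_cheek",
  count_to_50 = "count_to_50",
  arm_strength = "arm_extension",
  single_breath_count = "single_breath_count",
  sit_to_stand = "sit_to_stand"
)

#' Apply the rubric to a segmentation report
#'
#' Combines a report with externally measured rubric inputs into item
#' scores and the total. Bilateral measurements may be given per side
#' (named or unnamed vectors); the more severe side is scored (smaller
#' diplopia onset, smaller drift time). Domains whose segments are all
#' `unavailable`, or whose measurement is missing, score 4.
#'
#' @param report An `mgce_report` from [segment_session()].
#' @param measurements Named list with any of: `ptosis_category`,
#'   `diplopia_onset_s`, `cheek_category`, `tongue_category`,
#'   `dysarthria_onset_count`, `drift_time_s`, `sbc_count`,
#'   `sts_category`.
#' @return The report with `item_scores` and `total` filled in.
#' @export
score_report <- function(report, measurements = list()) {
  stopifnot(inherits(report, "mgce_report"))
  seg <- report$segments
  status_of <- function(domain) {
    st <- seg$status[seg$test %in% DOMAIN_TESTS[[domain]]]
    if (all(st == "unavailable")) "unavailable"
    else if (any(st == "uncertain")) "uncertain" else "successful"
  }
  worst_side <- function(x) if (is.null(x)) NULL else min(x)
  meas <- list(
    ptosis = measurements$ptosis_category,
    diplopia = worst_side(measurements$diplopia_onset_s),
    cheek_puff = measurements$cheek_category,
    tongue_to_cheek = measurements$tongue_category,
    count_to_50 = measurements$dysarthria_onset_count,
    arm_strength = worst_side(measurements$drift_time_s),
    single_breath_count = measurements$sbc_count,
    sit_to_stand = measurements$sts_category
  )
  scores <- vapply(MGCE_DOMAINS, function(d) {
    score_item(d, meas[[d]], status_of(d))
  }, integer(1))
  report$item_scores <- scores
  report$total <- total_score(scores)
  report
}
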