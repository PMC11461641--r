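## Metabolism-contractility mismatch classifier.
##
## A segment is mismatched when high late-enhancement transmurality (scar)
## coincides with high normalised FDG uptake (metabolic signal) in the same
## segment; an animal with at least `min_segments` mismatched segments on the
## day-3 scan is assigned to the Mismatch group.

#' Mismatch classification thresholds
#'
#' @param transmurality_min segment transmurality threshold, percent
#'   (inclusive; default 75).
#' @param uptake_min normalised-uptake threshold, percent (inclusive;
#'   default 75).
#' @param min_segments minimum number of mismatched segments for the animal
#'   to be assigned Mismatch (default 3).
#' @return object of class `mismatch_thresholds`.
#' @export
mismatch_thresholds <- function(transmurality_min = 75, uptake_min = 75,
                                min_segments = 3L) {
  check_number(transmurality_min, "transmurality_min", 0, 100)
  check_number(uptake_min, "uptake_min", 0, 100)
  check_number(min_segments, "min_segments", 1, 17)
  structure(list(transmurality_min = transmurality_min,
                 uptake_min = uptake_min,
                 min_segments = as.integer(min_segments)),
            class = "mismatch_thresholds")
}

#' @export
print.mismatch_thresholds <- function(x, ...) {
  cat(sprintf("<mismatch_thresholds> transmurality >= %g%%, uptake >= %g%%, >= %d segments\n",
              x$transmurality_min, x$uptake_min, x$min_segments))
  invisible(x)
}

#' Segment-level mismatch rule
#'
#' TRUE iff transmurality and normalised uptake both reach their thresholds
#' (both comparisons inclusive). Vectorised over segments.
#'
#' @param transmurality,uptake_norm percents in \[0, 100\].
#' @param th a [mismatch_thresholds()].
#' @return logical vector.
#' @export
#' @examples
#' classify_segment(75, 75)          # TRUE: boundary is inclusive
#' classify_segment(74.9, 100)       # FALSE
classify_segment <- function(transmurality, uptake_norm,
                             th = mismatch_thresholds()) {
  stopifnot(inherits(th, "mismatch_thresholds"))
  if (!is.numeric(transmurality) || !is.numeric(uptake_norm) ||
      length(transmurality) != length(uptake_norm) ||
      anyNA(transmurality) || anyNA(uptake_norm)) {
    stop_input("'transmurality' and 'uptake_norm' must be equal-length numeric vectors")
  }
  if (any(transmurality < 0 | transmurality > 100) ||
      any(uptake_norm < 0 | uptake_norm > 100)) {
    stop_input("percent inputs must lie in [0, 100]")
  }
  transmurality >= th$transmurality_min & uptake_norm >= th$uptake_min
}

#' Animal-level Match/Mismatch assignment
#'
#' Applies [classify_segment()] to all 17 segments of a day-3 profile and
#' assigns the animal to the Mismatch group when at least `th$min_segments`
#' segments are mismatched.
#'
#' @param profile a [segment_profile()].
#' @param th a [mismatch_thresholds()].
#' @return object of class `mismatch_result` with fields `animal_id`,
#'   `segment_mask` (length-17 logical), `n_mismatched` and `group`.
#' @export
classify_animal <- function(profile, th = mismatch_thresholds()) {
  stopifnot(inherits(profile, "segment_profile"))
  mask <- classify_segment(profile$transmurality, profile$uptake_norm, th)
  n <- sum(mask)
  structure(list(animal_id = profile$animal_id,
                 segment_mask = mask,
                 n_mismatched = as.integer(n),
                 group = if (n >= th$min_segments) "Mismatch" else "Match",
                 thresholds = th),
            class = "mismatch_result")
}

#' @export
print.mismatch_result <- function(x, ...) {
  cat(sprintf("<mismatch_result> animal %s: %d mismatched segment%s -> %s\n",
              x$animal_id, x$n_mismatched,
              if (x$n_mismatched == 1) "" else "s", x$group))
  if (x$n_mismatched > 0) {
    cat("  segments:", paste(which(x$segment_mask), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Cohort-level group assignment and mismatch prevalence
#'
#' Classifies every animal's day-3 profile and reports the Mismatch
#' prevalence, rounded to the nearest integer percent and unrounded.
#' Profiles from other timepoints are dropped with a warning (animals lacking
#' a day-3 profile are excluded, not imputed).
#'
#' @param profiles list of [segment_profile()]s.
#' @param th a [mismatch_thresholds()].
#' @return object of class `cohort_assignment`: list with `table`
#'   (data.frame `animal_id`, `n_mismatched`, `group`), `n_total`,
#'   `n_mismatch`, `prevalence` (unrounded percent) and
#'   `prevalence_rounded`.
#' @export
cohort_assign <- function(profiles, th = mismatch_thresholds()) {
  stopifnot(is.list(profiles), length(profiles) > 0L)
  ok <- vapply(profiles, inherits, logical(1), "segment_profile")
  if (!all(ok)) stop_input("'profiles' must be a list of segment_profile objects")
  tp <- vapply(profiles, `[[`, character(1), "timepoint")
  if (any(tp != "day3")) {
    dropped <- unique(vapply(profiles[tp != "day3"], `[[`, character(1), "animal_id"))
    warning(sprintf("dropping %d non-day3 profile(s); animals without a day-3 profile are excluded: %s",
                    sum(tp != "day3"), paste(dropped, collapse = ", ")),
            call. = FALSE)
    profiles <- profiles[tp == "day3"]
    if (length(profiles) == 0L) stop_input("no day-3 profiles to classify")
  }
  ids <- vapply(profiles, `[[`, character(1), "animal_id")
  if (anyDuplicated(ids)) {
    stop_input("duplicate animal ids in day-3 profiles: ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  res <- lapply(profiles, classify_animal, th = th)
  tab <- data.frame(
    animal_id = ids,
    n_mismatched = vapply(res, `[[`, integer(1), "n_mismatched"),
    group = vapply(res, `[[`, character(1), "group"),
    stringsAsFactors = FALSE)
  n_mis <- sum(tab$group == "Mismatch")
  prev <- 100 * n_mis / nrow(tab)
  structure(list(table = tab, n_total = nrow(tab), n_mismatch = n_mis,
                 prevalence = prev, prevalence_rounded = round(prev),
                 thresholds = th),
            class = "cohort_assignment")
}

#' @export
print.cohort_assignment <- function(x, ...) {
  cat(sprintf("<cohort_assignment> %d animals: %d Mismatch (%d%%, unrounded %.2f%%)\n",
              x$n_total, x$n_mismatch, x$prevalence_rounded, x$prevalence))
  invisible(x)
}

#' Angiographic grade shares by group
#'
#' Per-group share (percent) of animals at a given TIMI flow or myocardial
#' blush grade, as reported for post-reperfusion angiography.
#'
#' @param animals data.frame with a `group` column and the grade column.
#' @param column grade column name (e.g. `"timi_flow"`).
#' @param grade grade value whose share is reported.
#' @return data.frame with `group`, `n`, `n_at_grade`, `share` (percent,
#'   unrounded) and `share_rounded`.
#' @export
angiographic_summary <- function(animals, column = "timi_flow", grade = 2L) {
  stopifnot(is.data.frame(animals), "group" %in% names(animals),
            column %in% names(animals))
  groups <- sort(unique(animals$group))
  out <- do.call(rbind, lapply(groups, function(g) {
    sub <- animals[animals$group == g, ]
    k <- sum(sub[[column]] == grade)
    data.frame(group = g, n = nrow(sub), n_at_grade = k,
               share = 100 * k / nrow(sub),
               share_rounded = round(100 * k / nrow(sub)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
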