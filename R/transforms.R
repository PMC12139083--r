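#' Double a VAS score onto the ordinal 0..20 grid
#'
#' Visual analogue scale scores are recorded on 0--10 in steps of 0.5; an
#' ordinal model needs integer categories. Multiplying by two maps the grid
#' bijectively onto the integers 0..20. Off-grid values are an error -- no
#' silent rounding.
#'
#' @param raw Numeric vector in \[0, 10\], multiples of 0.5 (tolerance 1e-9).
#'   `NA` passes through.
#' @returns Integer vector in 0..20.
#' @examples
#' vas_to_ordinal(c(0, 7.5, 10))
#' @export
vas_to_ordinal <- function(raw) {
  ok <- is.na(raw) | (raw >= 0 & raw <= 10 & abs(raw * 2 - round(raw * 2)) <= 1e-9)
  if (!all(ok)) {
    abort(paste0("VAS value off the 0.5 grid on [0, 10]: ",
                 paste(head(raw[!ok], 3), collapse = ", ")))
  }
  as.integer(round(raw * 2))
}

#' Change from within-period baseline
#'
#' For each subject x period, subtracts the occasion-1 (baseline) value of
#' `outcome` from the values at occasions 2..4 and stores them as a new
#' outcome `"<outcome>_change"`. Baseline rows are not carried into the new
#' outcome. A missing baseline makes that period's three change values
#' missing; the number of such periods is reported via a warning and the
#' `"n_missing_baseline"` attribute.
#'
#' @param data A `long_trial`.
#' @param outcome Name of the outcome to difference.
#' @returns The input with the `"<outcome>_change"` records appended.
#' @export
change_from_baseline <- function(data, outcome) {
  data <- as_long_trial(data)
  sub <- data[data$outcome == outcome, ]
  if (nrow(sub) == 0) abort(paste0("outcome not present: ", outcome))

  base <- sub[sub$time == 1L, c("subject_id", "period", "value")]
  names(base)[3] <- ".baseline"
  post <- sub[sub$time != 1L, ]
  post <- dplyr::left_join(post, base, by = c("subject_id", "period"))

  miss_key <- unique(paste(post$subject_id, post$period)[is.na(post$.baseline)])
  if (length(miss_key) > 0) {
    warn(sprintf("%d subject-period(s) lack a baseline for '%s'; changes set to missing",
                 length(miss_key), outcome))
  }
  post$value <- post$value - post$.baseline
  post$.baseline <- NULL
  post$outcome <- paste0(outcome, "_change")

  out <- dplyr::bind_rows(data, post)
  out <- as_long_trial(out)
  attr(out, "n_missing_baseline") <- length(miss_key)
  out
}

#' Dichotomize a relative reduction from baseline
#'
#' Classifies a value against its baseline as `"responder"` when the
#' relative reduction `(baseline - value) / baseline` clears
#' `threshold_fraction`. The blister-count rule ("reduction of more than
#' 40%") is strict (`strict = TRUE`, the default at 0.4); the VAS rule
#' ("decreases by at least 30%") uses `strict = FALSE` with
#' `threshold_fraction = 0.3`.
#'
#' @param baseline Positive baseline value(s).
#' @param value Non-negative value(s) to classify.
#' @param threshold_fraction Reduction fraction in (0, 1); default 0.4.
#' @param strict If `TRUE` (default) a responder needs reduction strictly
#'   greater than the threshold; if `FALSE`, greater or equal.
#' @returns Character vector `"responder"` / `"non_responder"` (`NA` where
#'   `value` is missing).
#' @examples
#' dichotomize_reduction(10, c(5, 6))
#' @export
dichotomize_reduction <- function(baseline, value, threshold_fraction = 0.4,
                                  strict = TRUE) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    abort("`threshold_fraction` must lie in (0, 1)")
  }
  if (any(!is.na(baseline) & baseline <= 0)) {
    abort("`baseline` must be > 0: relative reduction is undefined at 0")
  }
  reduction <- (baseline - value) / baseline
  hit <- if (strict) reduction > threshold_fraction else reduction >= threshold_fraction
  ifelse(is.na(reduction), NA_character_,
         ifelse(hit, "responder", "non_responder"))
}

#' Categorize a change from baseline as improvement / stable / worsening
#'
#' With lower scores better (pain, pruritus), a drop of at least `threshold`
#' is an improvement and a rise of at least `threshold` a worsening;
#' anything in between is stable. Equality at exactly +/- `threshold` goes
#' to the directional category so the three categories partition all pairs.
#'
#' @param baseline,value Numeric vectors.
#' @param threshold Positive threshold in outcome units.
#' @returns Character vector `"improvement"` / `"stable"` / `"worsening"`.
#' @examples
#' categorize_change(6, c(3, 6, 9), threshold = 2)
#' @export
categorize_change <- function(baseline, value, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    abort("`threshold` must be a single positive number")
  }
  d <- value - baseline
  ifelse(is.na(d), NA_character_,
         ifelse(d <= -threshold, "improvement",
                ifelse(d >= threshold, "worsening", "stable")))
}

#' Standardize a value by a baseline-period mean
#'
#' Ratio standardization against the average of a reference baseline period:
#' `value / baseline mean`. The baseline standard deviation is not used in
#' the ratio; it is the natural scale for a pairwise-comparison threshold
#' and is carried alongside as the `"baseline_sd"` attribute.
#'
#' @param value Numeric vector.
#' @param baseline_mean Positive baseline mean.
#' @param baseline_sd Optional non-negative baseline standard deviation,
#'   attached to the result for use as a comparison threshold.
#' @returns Numeric vector of ratios, with attribute `"baseline_sd"`.
#' @export
standardize_by_baseline <- function(value, baseline_mean, baseline_sd = NULL) {
  if (!is.numeric(baseline_mean) || length(baseline_mean) != 1 ||
      is.na(baseline_mean) || baseline_mean <= 0) {
    abort("`baseline_mean` must be a single positive number")
  }
  if (!is.null(baseline_sd) && (baseline_sd < 0 || is.na(baseline_sd))) {
    abort("`baseline_sd` must be >= 0")
  }
  out <- value / baseline_mean
  attr(out, "baseline_sd") <- baseline_sd
  out
}
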