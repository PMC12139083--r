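#' Rank-based relative treatment effects
#'
#' Pools all observations of one outcome, assigns mid-ranks, and expresses
#' each design cell's tendency as a relative effect
#' `p_hat = (mean mid-rank in cell - 1/2) / N`, where `N` is the total
#' number of pooled observations. `p_hat > 0.5` means the cell's values tend
#' to exceed those of a randomly chosen observation from the pooled data.
#' The size-weighted average of `p_hat` over all cells is exactly 0.5.
#'
#' Only subjects with a complete profile on the outcome are used
#' (complete-case analysis; missing-data machinery is out of scope).
#'
#' @param data A `long_trial`.
#' @param outcome Outcome name to analyze.
#' @param cells Character vector of columns whose interaction defines the
#'   design cells (default `c("treatment", "time")`).
#' @returns A tibble with one row per cell: the cell labels, `n`, mean
#'   mid-rank and `p_hat`; total `N` in attribute `"N"`.
#' @references Brunner, E., Domhof, S., Langer, F. (2002). Nonparametric
#'   Analysis of Longitudinal Data in Factorial Experiments. Wiley.
#' @export
relative_effects <- function(data, outcome, cells = c("treatment", "time")) {
  data <- as_long_trial(data)
  sub <- data[data$outcome == outcome, ]
  if (nrow(sub) == 0) abort(paste0("outcome not present: ", outcome))
  missing_cols <- setdiff(cells, names(sub))
  if (length(missing_cols) > 0) {
    abort(paste0("cell column(s) not in data: ",
                 paste(missing_cols, collapse = ", ")))
  }
  complete <- tapply(!is.na(sub$value), sub$subject_id, all)
  sub <- sub[complete[sub$subject_id], ]
  if (nrow(sub) == 0) abort("no complete-case subjects")

  cell_id <- interaction(sub[cells], drop = FALSE, sep = ":", lex.order = TRUE)
  if (nlevels(cell_id) < 2) abort("need at least 2 design cells")
  empty <- setdiff(levels(cell_id), unique(as.character(cell_id)))
  if (length(empty) > 0) {
    abort(paste0("empty design cell(s): ", paste(empty, collapse = ", ")))
  }
  N <- nrow(sub)
  r <- rank(sub$value, ties.method = "average")
  out <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(sub, .rank = r),
                    dplyr::across(dplyr::all_of(cells))),
    n = dplyr::n(), mean_rank = mean(.data$.rank), .groups = "drop")
  out$p_hat <- (out$mean_rank - 0.5) / N
  out <- dplyr::arrange(out, dplyr::across(dplyr::all_of(cells)))
  attr(out, "N") <- N
  out
}

# projection matrices for the 2 (treatment) x 4 (time) cell layout,
# cells ordered treatment-major (active t1..t4, placebo t1..t4)
ats_projection <- function(contrast) {
  cen <- function(d) diag(d) - matrix(1 / d, d, d)
  avg <- function(d) matrix(1 / d, d, d)
  switch(contrast,
    treatment = kronecker(cen(2), avg(4)),
    time = kronecker(avg(2), cen(4)),
    treatment_x_time = kronecker(cen(2), cen(4)),
    abort("unknown contrast"))
}

#' ANOVA-type statistic for the cross-over factorial layout
#'
#' Tests treatment, time, or treatment-by-time hypotheses about the
#' rank-based relative effects of the 2 x 4 (treatment x time) cell layout,
#' into which the 2x2x4 cross-over maps: every complete subject contributes
#' exactly one observation to each cell (the active cells from one period,
#' the placebo cells from the other). The statistic is the quadratic form of
#' the cell relative effects in the contrast's projection matrix, normalized
#' by the estimated covariance of the subject-level rank vectors; smooth
#' small-sample behaviour comes from a Box-type approximation with an
#' F(f, f0) reference distribution, with both degrees of freedom estimated
#' from the data (sequence groups act as independent strata for covariance
#' estimation).
#'
#' @param data A `long_trial`.
#' @param outcome Outcome name to analyze.
#' @param contrast `"treatment"` (default), `"treatment_x_time"` or
#'   `"time"`; alternatively a numeric contrast matrix with 8 columns in
#'   treatment-major cell order (active times 1..4, placebo times 1..4).
#' @returns An `ats_result`: `statistic`, numerator df `f`, denominator df
#'   `f0`, `p_value`, the contrast label and the cell relative effects.
#' @references Brunner, E., Domhof, S., Langer, F. (2002). Nonparametric
#'   Analysis of Longitudinal Data in Factorial Experiments. Wiley.
#' @export
ats_test <- function(data, outcome,
                     contrast = c("treatment", "treatment_x_time", "time")) {
  data <- as_long_trial(data)
  if (is.character(contrast)) {
    contrast <- match.arg(contrast)
    TT <- ats_projection(contrast)
    label <- contrast
  } else {
    C <- as.matrix(contrast)
    if (ncol(C) != 8) abort("a custom contrast matrix needs 8 columns")
    if (qr(C)$rank < nrow(C)) {
      abort("contrast matrix is rank-deficient (duplicated or dependent rows)")
    }
    CC <- C %*% t(C)
    TT <- t(C) %*% solve(CC, C)
    label <- "custom"
  }

  sub <- data[data$outcome == outcome, ]
  if (nrow(sub) == 0) abort(paste0("outcome not present: ", outcome))
  complete <- tapply(!is.na(sub$value), sub$subject_id, all) &
    tapply(rep(1, nrow(sub)), sub$subject_id, length) == 8
  sub <- sub[complete[sub$subject_id], ]
  subjects <- unique(sub$subject_id)
  n <- length(subjects)
  seq_lab <- sub$sequence[match(subjects, sub$subject_id)]
  if (any(table(factor(seq_lab, levels = c("AB", "BA"))) < 2)) {
    abort("need at least 2 complete subjects per sequence group")
  }

  N_tot <- nrow(sub)
  r <- rank(sub$value, ties.method = "average")
  cell <- (as.integer(sub$treatment == "placebo")) * 4L + sub$time
  Y <- matrix(NA_real_, n, 8)
  Y[cbind(match(sub$subject_id, subjects), cell)] <- (r - 0.5) / N_tot
  p_hat <- colMeans(Y)

  # V-hat = Cov(p_hat), pooled over sequence strata; Satterthwaite-type
  # denominator df from the per-stratum trace contributions
  tv <- 0; num0 <- 0; den0 <- 0
  for (g in c("AB", "BA")) {
    Yg <- Y[seq_lab == g, , drop = FALSE]
    ng <- nrow(Yg)
    Sg <- cov(Yg)
    cg <- ng / n^2
    tg <- sum(diag(TT %*% Sg))
    tv <- tv + cg * tg
    den0 <- den0 + (cg * tg)^2 / (ng - 1)
  }
  V <- Reduce(`+`, lapply(c("AB", "BA"), function(g) {
    Yg <- Y[seq_lab == g, , drop = FALSE]
    (nrow(Yg) / n^2) * cov(Yg)
  }))
  TV <- TT %*% V
  stat <- as.numeric(t(p_hat) %*% TT %*% p_hat) / tv
  f <- sum(diag(TV))^2 / sum(TV * t(TV))
  f0 <- tv^2 / den0
  p <- pf(stat, f, f0, lower.tail = FALSE)

  re <- tibble::tibble(
    treatment = rep(c("active", "placebo"), each = 4),
    time = rep(1:4, 2), p_hat = p_hat)
  structure(list(statistic = stat, f = f, f0 = f0, p_value = p,
                 contrast = label, relative_effects = re, n_subjects = n),
            class = "ats_result")
}

#' @export
print.ats_result <- function(x, ...) {
  cat(sprintf("ANOVA-type statistic (%s): %.4f\n", x$contrast, x$statistic))
  cat(sprintf("  F(%.2f, %.2f) reference, p = %.4g  [n = %d subjects]\n",
              x$f, x$f0, x$p_value, x$n_subjects))
  invisible(x)
}
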