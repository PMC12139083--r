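#' Tidy a GPC result
#'
#' @param x A `gpc_result`.
#' @param ... Unused.
#' @returns One-row tibble with counts, net benefit and p-value.
#' @method tidy gpc_result
#' @export
tidy.gpc_result <- function(x, ...) {
  tibble::tibble(variant = x$variant, wins = x$wins, losses = x$losses,
                 ties = x$ties, n_pairs = x$n_pairs,
                 net_benefit = x$net_benefit, p.value = x$p_value,
                 n_permutations = x$n_permutations)
}

#' @rdname tidy.gpc_result
#' @method glance gpc_result
#' @export
glance.gpc_result <- function(x, ...) tidy.gpc_result(x, ...)

#' Tidy an ANOVA-type statistic result
#'
#' @param x An `ats_result`.
#' @param ... Unused.
#' @returns One-row tibble with the statistic, both estimated degrees of
#'   freedom and the p-value.
#' @method tidy ats_result
#' @export
tidy.ats_result <- function(x, ...) {
  tibble::tibble(contrast = x$contrast, statistic = x$statistic,
                 df1 = x$f, df2 = x$f0, p.value = x$p_value)
}

#' @rdname tidy.ats_result
#' @method glance ats_result
#' @export
glance.ats_result <- function(x, ...) tidy.ats_result(x, ...)

#' Tidy an ordinal GEE fit
#'
#' @param x An `ordinal_gee` fit.
#' @param conf.level Level for Wald confidence intervals.
#' @param intercepts If `FALSE` (default) only the 12 regression slopes are
#'   returned; if `TRUE`, threshold intercepts too (degenerate ones carry
#'   infinite estimates and `NA` standard errors).
#' @param ... Unused.
#' @returns A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high`.
#' @method tidy ordinal_gee
#' @export
tidy.ordinal_gee <- function(x, conf.level = 0.95, intercepts = FALSE, ...) {
  terms <- names(x$coefficients)
  if (!intercepts) terms <- terms[!startsWith(terms, "cut_")]
  est <- x$coefficients[terms]
  se <- setNames(rep(NA_real_, length(terms)), terms)
  est_terms <- intersect(terms, x$estimable)
  se[est_terms] <- sqrt(diag(x$vcov))[est_terms]
  z <- est / se
  zq <- qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(term = terms, estimate = unname(est),
                 std.error = unname(se), statistic = unname(z),
                 p.value = unname(2 * pnorm(-abs(z))),
                 conf.low = unname(est - zq * se),
                 conf.high = unname(est + zq * se))
}

#' @rdname tidy.ordinal_gee
#' @method glance ordinal_gee
#' @export
glance.ordinal_gee <- function(x, ...) {
  tibble::tibble(n_clusters = x$n_clusters, n_iter = x$n_iter,
                 converged = x$converged,
                 working = x$working$structure, rho = x$working$rho,
                 n_degenerate_thresholds = length(x$degenerate_thresholds),
                 monotone_intercepts = x$monotone_intercepts,
                 score_norm = x$score_norm)
}

#' Tidy a rejection study
#'
#' @param x A `rejection_study`.
#' @param ... Unused.
#' @returns The per-method results tibble.
#' @method tidy rejection_study
#' @export
tidy.rejection_study <- function(x, ...) x$results

#' @rdname tidy.rejection_study
#' @method glance rejection_study
#' @export
glance.rejection_study <- function(x, ...) {
  tibble::tibble(n_sim = x$n_sim, alpha = x$alpha, seed = x$seed,
                 n_methods = nrow(x$results))
}
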