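#' Marginal distribution for zero-inflated ordinal VAS scores
#'
#' Builds a probability mass function over the doubled-scale categories
#' 0..20, as a mixture of a point mass at zero (many subjects report no
#' pain/pruritus at all) and a truncated negative-binomial shape over the
#' positive range.
#'
#' @param zero_inflation Extra mass placed at category 0, in \[0, 1).
#' @param location,dispersion Mean and size of the underlying negative
#'   binomial before truncation to 0..20.
#' @returns Numeric vector of length 21 summing to 1 (names `"0"`..`"20"`).
#' @export
vas_marginal_pmf <- function(zero_inflation = 0.35, location = 6,
                             dispersion = 3) {
  if (zero_inflation < 0 || zero_inflation >= 1) {
    abort("`zero_inflation` must lie in [0, 1)")
  }
  base <- stats::dnbinom(0:20, mu = location, size = dispersion)
  base <- base / sum(base)
  pmf <- (1 - zero_inflation) * base
  pmf[1] <- pmf[1] + zero_inflation
  names(pmf) <- 0:20
  pmf
}

#' Synthetic cross-over trial configuration
#'
#' Describes the 2-period, 2-sequence, 4-occasions-per-period trial that
#' [generate_trial()] emulates: marginal outcome distribution, within-subject
#' serial correlation, and between-subject heterogeneity. The defaults are
#' the package's standing emulation of a small rare-disease cross-over with
#' ordinal pain/pruritus scores: 8 subjects per sequence, 35% of scores at
#' zero, latent first-order autocorrelation 0.6 and a subject random
#' intercept of 0.8 latent standard deviations.
#'
#' @param n_per_sequence Subjects per sequence group (>= 2).
#' @param outcome_kind `"ordinal_vas"` (categories 0..20) or `"count"`
#'   (negative-binomial blister counts).
#' @param outcome_name Outcome label; defaults to `"vas"` or
#'   `"blister_count"` by kind.
#' @param pmf Marginal pmf over categories 0..20 (ordinal kind only).
#' @param count_mean,count_dispersion Negative-binomial mean and size
#'   (count kind only).
#' @param rho Latent AR(1) correlation across the 8 occasions, in \[0, 1).
#' @param subject_sd Latent random-intercept standard deviation (>= 0).
#' @param occasion_sd Length-8 (or scalar) latent residual standard
#'   deviations, one per occasion in period-then-time order.
#' @returns A `trial_config` list.
#' @seealso [generate_trial()]
#' @export
trial_config <- function(n_per_sequence = 8,
                         outcome_kind = c("ordinal_vas", "count"),
                         outcome_name = NULL,
                         pmf = vas_marginal_pmf(),
                         count_mean = 15, count_dispersion = 3,
                         rho = 0.6, subject_sd = 0.8, occasion_sd = 1) {
  outcome_kind <- match.arg(outcome_kind)
  if (n_per_sequence < 2) abort("`n_per_sequence` must be >= 2")
  if (rho < 0 || rho >= 1) abort("`rho` must lie in [0, 1)")
  if (subject_sd < 0) abort("`subject_sd` must be >= 0")
  occasion_sd <- rep_len(occasion_sd, 8)
  if (any(occasion_sd < 0)) abort("`occasion_sd` must be >= 0")
  if (outcome_kind == "ordinal_vas") {
    if (length(pmf) != 21 || any(pmf < 0) || abs(sum(pmf) - 1) > 1e-8) {
      abort("`pmf` must be 21 non-negative masses over 0..20 summing to 1")
    }
    if (any(pmf < 1e-12)) {
      warn("pmf has categories with (near-)zero mass; those categories are unreachable")
    }
  } else {
    if (count_mean <= 0 || count_dispersion <= 0) {
      abort("`count_mean` and `count_dispersion` must be > 0")
    }
  }
  if (is.null(outcome_name)) {
    outcome_name <- if (outcome_kind == "ordinal_vas") "vas" else "blister_count"
  }
  structure(list(n_per_sequence = n_per_sequence, outcome_kind = outcome_kind,
                 outcome_name = outcome_name, pmf = pmf,
                 count_mean = count_mean, count_dispersion = count_dispersion,
                 rho = rho, subject_sd = subject_sd, occasion_sd = occasion_sd),
            class = "trial_config")
}

#' Generate a synthetic cross-over trial
#'
#' Draws one complete trial under a [trial_config()]. A latent Gaussian
#' process (subject random intercept plus AR(1) residual over the 8
#' occasions, ordered period 1 times 1..4 then period 2 times 1..4) is
#' pushed through its own cdf and the marginal quantile function -- a
#' Gaussian copula -- so the requested marginal distribution holds exactly
#' at every occasion while within-subject correlation decays with occasion
#' lag. The generator contains no treatment effect; alternatives are built
#' by [inject_effect()].
#'
#' @param config A [trial_config()].
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @returns A [as_long_trial()] tibble with
#'   `2 * n_per_sequence * 8` records.
#' @examples
#' d <- generate_trial(trial_config(n_per_sequence = 4), seed = 1)
#' nrow(d)
#' @export
generate_trial <- function(config, seed = NULL) {
  stopifnot(inherits(config, "trial_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- 2L * config$n_per_sequence
  lat <- latent_panel(n, config$rho, config$subject_sd, config$occasion_sd)
  u <- pnorm(lat$z)
  if (config$outcome_kind == "ordinal_vas") {
    cum <- cumsum(config$pmf)
    vals <- matrix(findInterval(u, cum[-21], left.open = TRUE), nrow = n)
  } else {
    vals <- matrix(qnbinom(u, mu = config$count_mean,
                           size = config$count_dispersion), nrow = n)
  }
  ids <- sprintf("S%03d", seq_len(n))
  grid <- expand.grid(occ = 1:8, subject = seq_len(n))
  out <- tibble::tibble(
    subject_id = ids[grid$subject],
    sequence = rep(rep(c("AB", "BA"), each = config$n_per_sequence), each = 8),
    period = ((grid$occ - 1L) %/% 4L) + 1L,
    time = ((grid$occ - 1L) %% 4L) + 1L,
    outcome = config$outcome_name,
    value = as.numeric(t(vals))
  )
  as_long_trial(out)
}

# latent subject-intercept + AR(1) panel, standardized to unit total sd
latent_panel <- function(n, rho, subject_sd, occasion_sd) {
  b <- rnorm(n, 0, subject_sd)
  e <- matrix(0, n, 8)
  z <- matrix(rnorm(n * 8), n, 8)
  e[, 1] <- occasion_sd[1] * z[, 1]
  for (j in 2:8) {
    e[, j] <- rho * (occasion_sd[j] / occasion_sd[j - 1]) * e[, j - 1] +
      occasion_sd[j] * sqrt(1 - rho^2) * z[, j]
  }
  tot_sd <- sqrt(subject_sd^2 + occasion_sd^2)
  list(z = sweep(b + e, 2, tot_sd, "/"))
}

#' Remove treatment effects by permuting sequence labels
#'
#' Randomly reassigns the existing sequence labels across subjects, keeping
#' every subject's full outcome profile (all periods, times and outcomes)
#' intact and the sequence-group sizes unchanged; the treatment column is
#' recomputed from the new labels. Because only the label linking profile to
#' treatment order moves, any treatment association is destroyed while the
#' longitudinal structure survives -- this is the exact null used for
#' permutation inference and type-I-error studies.
#'
#' @param data A `long_trial`.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @returns A `long_trial` with permuted sequence labels.
#' @export
permute_null <- function(data, seed = NULL) {
  data <- as_long_trial(data)
  if (!is.null(seed)) set.seed(seed)
  subjects <- unique(data$subject_id)
  if (length(subjects) < 2) abort("need at least 2 subjects to permute")
  seq_of <- data$sequence[match(subjects, data$subject_id)]
  new_seq <- setNames(sample(seq_of), subjects)
  data$sequence <- unname(new_seq[data$subject_id])
  data$treatment <- expected_treatment(data$sequence, data$period)
  as_long_trial(data)
}

#' Artificial treatment effect specification
#'
#' Describes how [inject_effect()] modifies active-treatment observations:
#' `"ordinal_shift"` lowers ordinal categories by `magnitude` (floored at
#' 0), `"count_thinning"` keeps each counted event independently with
#' probability `magnitude`. Effects apply to active-treatment records at the
#' post-baseline occasions in `occasions`; placebo records and baselines are
#' never touched.
#'
#' @param mechanism `"ordinal_shift"` or `"count_thinning"`.
#' @param magnitude Shift in categories (>= 0) or retention probability in
#'   (0, 1\]. Defaults: 3 categories (1.5 VAS points) for the shift, 0.6 for
#'   thinning.
#' @param occasions Affected occasions, a subset of 2..4 (default all).
#' @param outcome Optional outcome name to restrict the effect to.
#' @returns An `effect_spec` list.
#' @export
effect_spec <- function(mechanism = c("ordinal_shift", "count_thinning"),
                        magnitude = NULL, occasions = 2:4, outcome = NULL) {
  mechanism <- match.arg(mechanism)
  if (is.null(magnitude)) {
    magnitude <- if (mechanism == "ordinal_shift") 3 else 0.6
  }
  if (mechanism == "ordinal_shift") {
    if (magnitude < 0) abort("shift `magnitude` must be >= 0")
  } else if (magnitude <= 0 || magnitude > 1) {
    abort("retention `magnitude` must lie in (0, 1]")
  }
  if (!all(occasions %in% 2:4)) abort("`occasions` must be a subset of 2..4")
  structure(list(mechanism = mechanism, magnitude = magnitude,
                 occasions = as.integer(occasions), outcome = outcome),
            class = "effect_spec")
}

#' Inject an artificial treatment effect
#'
#' Applies an [effect_spec()] to the active-treatment records of a trial,
#' leaving placebo records and within-period baselines untouched. A zero
#' shift or unit retention returns the input unchanged.
#'
#' @param data A `long_trial`.
#' @param effect An [effect_spec()].
#' @param seed Optional integer seed (used by the stochastic thinning
#'   mechanism); `NULL` uses the current RNG state.
#' @returns The modified `long_trial`.
#' @export
inject_effect <- function(data, effect, seed = NULL) {
  data <- as_long_trial(data)
  stopifnot(inherits(effect, "effect_spec"))
  if (effect$mechanism == "ordinal_shift" && effect$magnitude == 0) return(data)
  if (effect$mechanism == "count_thinning" && effect$magnitude == 1) return(data)
  if (!is.null(seed)) set.seed(seed)

  idx <- data$treatment == "active" & data$time %in% effect$occasions
  if (!is.null(effect$outcome)) idx <- idx & data$outcome == effect$outcome
  v <- data$value[idx]
  ok <- !is.na(v)
  if (any(abs(v[ok] - round(v[ok])) > 1e-9) || any(v[ok] < 0)) {
    abort(paste0("'", effect$mechanism,
                 "' needs non-negative integer-valued outcomes"))
  }
  if (effect$mechanism == "ordinal_shift") {
    v[ok] <- pmax(0, v[ok] - effect$magnitude)
  } else {
    v[ok] <- rbinom(sum(ok), size = as.integer(round(v[ok])),
                    prob = effect$magnitude)
  }
  data$value[idx] <- v
  data
}
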