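#' Prioritized comparison hierarchy for generalized pairwise comparisons
#'
#' An ordered list of endpoints on which pairs of observations are compared:
#' the first level that yields a win or a loss decides the pair; a pair is a
#' tie only if every level ties. Each entry names an outcome and occasion, a
#' direction, and a threshold of clinical relevance `tau` -- the minimum
#' difference (e.g. the natural baseline variability of a blister count)
#' before one value counts as better than another.
#'
#' @param ... One or more [priority()] entries, or a data frame with columns
#'   `outcome`, `time`, `direction`, `threshold`.
#' @returns A `priority_list` tibble.
#' @examples
#' priority_list(
#'   priority("vas", time = 3, direction = "lower_better", threshold = 2),
#'   priority("vas", time = 4, direction = "lower_better", threshold = 2)
#' )
#' @export
priority_list <- function(...) {
  entries <- list(...)
  if (length(entries) == 1 && is.data.frame(entries[[1]])) {
    pl <- tibble::as_tibble(entries[[1]])
  } else {
    pl <- dplyr::bind_rows(entries)
  }
  need <- c("outcome", "time", "direction", "threshold")
  if (nrow(pl) == 0) abort("a priority list must have at least one entry")
  if (!all(need %in% names(pl))) {
    abort("priority entries need outcome, time, direction, threshold")
  }
  if (!all(pl$direction %in% c("lower_better", "higher_better"))) {
    abort("direction must be \"lower_better\" or \"higher_better\"")
  }
  if (any(!is.finite(pl$threshold)) || any(pl$threshold < 0)) {
    abort("thresholds must be finite and >= 0")
  }
  if (anyDuplicated(pl[need])) abort("priority entries must be unique")
  class(pl) <- c("priority_list", class(tibble::tibble()))
  pl
}

#' @rdname priority_list
#' @param outcome Outcome name as it appears in the trial data.
#' @param time Assessment occasion (1..4) of the endpoint.
#' @param direction `"lower_better"` (pain, counts) or `"higher_better"`.
#' @param threshold Threshold of clinical relevance `tau >= 0` in outcome
#'   units; with `tau = 0` any nonzero difference decides the pair.
#' @export
priority <- function(outcome, time, direction = c("lower_better", "higher_better"),
                     threshold = 0) {
  direction <- match.arg(direction)
  tibble::tibble(outcome = outcome, time = as.integer(time),
                 direction = direction, threshold = threshold)
}

#' Classify a single active-vs-placebo pair
#'
#' With `direction = "lower_better"`, the active value wins when it
#' undercuts the placebo value by at least `tau` (strictly more than 0 when
#' `tau = 0`); the loss case is symmetric; anything else -- including a
#' missing value on either side -- is a tie.
#'
#' @param value_active,value_placebo Numeric values being compared.
#' @param direction `"lower_better"` or `"higher_better"`.
#' @param tau Threshold of clinical relevance, >= 0.
#' @returns `"win"`, `"loss"` or `"tie"` (vectorized).
#' @examples
#' compare_pair(3, 4, "lower_better", tau = 0) # win
#' compare_pair(3, 4, "lower_better", tau = 2) # tie
#' @export
compare_pair <- function(value_active, value_placebo,
                         direction = c("lower_better", "higher_better"),
                         tau = 0) {
  direction <- match.arg(direction)
  if (tau < 0) abort("`tau` must be >= 0")
  s <- pair_sign(value_active, value_placebo, direction, tau)
  c("loss", "tie", "win")[s + 2L]
}

# numeric pair classification: +1 win / 0 tie / -1 loss, NA-safe
pair_sign <- function(value_active, value_placebo, direction, tau) {
  d <- value_placebo - value_active
  if (direction == "higher_better") d <- -d
  s <- if (tau > 0) sign(d) * (abs(d) >= tau) else sign(d)
  s[is.na(s)] <- 0
  as.integer(s)
}

# Per-subject endpoint values by period for each priority level.
# Returns subjects, their sequence labels, optional stratum, and two
# n x L matrices of period-1 and period-2 values.
gpc_endpoints <- function(data, priorities, strata = NULL) {
  data <- as_long_trial(data)
  priorities <- priority_list(priorities)
  subjects <- unique(data$subject_id)
  n <- length(subjects)
  L <- nrow(priorities)
  P1 <- P2 <- matrix(NA_real_, n, L)
  for (l in seq_len(L)) {
    sel <- data$outcome == priorities$outcome[l] & data$time == priorities$time[l]
    if (!any(sel)) {
      abort(sprintf("priority endpoint absent from data: '%s' at time %d",
                    priorities$outcome[l], priorities$time[l]))
    }
    sub <- data[sel, ]
    i <- match(sub$subject_id, subjects)
    p1 <- sub$period == 1L
    P1[i[p1], l] <- sub$value[p1]
    P2[i[!p1], l] <- sub$value[!p1]
  }
  seq_lab <- data$sequence[match(subjects, data$subject_id)]
  stratum <- if (is.null(strata)) rep("(all)", n) else {
    if (!strata %in% names(data)) abort(paste0("stratum column not found: ", strata))
    as.character(data[[strata]][match(subjects, data$subject_id)])
  }
  list(subjects = subjects, seq_lab = seq_lab, stratum = stratum,
       P1 = P1, P2 = P2, priorities = priorities)
}

# Hierarchy-resolved pair classification matrix for a given sequence
# assignment. Rows index the subject supplying the active vector, columns
# the subject supplying the placebo vector.
gpc_pair_matrix <- function(ep, seq_lab) {
  is_ab <- seq_lab == "AB"
  n <- length(is_ab)
  res <- matrix(0L, n, n)
  undecided <- matrix(TRUE, n, n)
  for (l in seq_len(nrow(ep$priorities))) {
    act <- ifelse(is_ab, ep$P1[, l], ep$P2[, l])
    plc <- ifelse(is_ab, ep$P2[, l], ep$P1[, l])
    d <- matrix(plc, n, n, byrow = TRUE) - matrix(act, n, n)
    if (ep$priorities$direction[l] == "higher_better") d <- -d
    tau <- ep$priorities$threshold[l]
    s <- if (tau > 0) sign(d) * (abs(d) >= tau) else sign(d)
    s[is.na(s)] <- 0L
    res[undecided] <- s[undecided]
    undecided <- res == 0L
  }
  res
}

gpc_result <- function(wins, losses, ties, variant, priorities,
                       strata_summary = NULL) {
  n_pairs <- wins + losses + ties
  structure(list(
    wins = wins, losses = losses, ties = ties, n_pairs = n_pairs,
    net_benefit = if (n_pairs > 0) (wins - losses) / n_pairs else NA_real_,
    p_value = NA_real_, n_permutations = NA_integer_,
    variant = variant, priorities = priorities, strata = strata_summary
  ), class = "gpc_result")
}

#' Unmatched generalized pairwise comparisons
#'
#' Compares every active endpoint vector against every placebo endpoint
#' vector -- in a cross-over each subject contributes one of each, so a
#' trial with `n` subjects yields `n^2` pairs, including each subject's own
#' cross pair. Each pair is decided by the first priority level that is not
#' a tie. With `strata`, pairs are formed within stratum only and the
#' win/loss/tie counts are pooled by summation.
#'
#' @param data A `long_trial`.
#' @param priorities A [priority_list()].
#' @param strata Optional name of a subject-constant column in `data`
#'   defining pre-specified subgroups.
#' @returns A `gpc_result` (statistic only; see [gpc_permutation_test()]
#'   for inference): wins, losses, ties, `net_benefit = (wins - losses) /
#'   n_pairs`.
#' @references Buyse, M. (2010). Generalized pairwise comparisons of
#'   prioritized outcomes in the two-sample problem. Statistics in
#'   Medicine 29, 3245--3257.
#' @export
unmatched_gpc <- function(data, priorities, strata = NULL) {
  ep <- gpc_endpoints(data, priorities, strata)
  res <- gpc_pair_matrix(ep, ep$seq_lab)
  same <- outer(ep$stratum, ep$stratum, "==")
  wins <- sum(res == 1L & same)
  losses <- sum(res == -1L & same)
  ties <- sum(res == 0L & same)
  strata_summary <- NULL
  if (!is.null(strata)) {
    strata_summary <- dplyr::bind_rows(lapply(unique(ep$stratum), function(st) {
      m <- outer(ep$stratum == st, ep$stratum == st)
      tibble::tibble(stratum = st, wins = sum(res == 1L & m),
                     losses = sum(res == -1L & m), ties = sum(res == 0L & m))
    }))
  }
  gpc_result(wins, losses, ties, "unmatched", ep$priorities, strata_summary)
}

#' Matched (within-subject) generalized pairwise comparisons
#'
#' One comparison per subject: their own active endpoint vector against
#' their own placebo vector, so `n_pairs` equals the number of contributing
#' subjects. Subjects missing one arm entirely (no observed value at any
#' priority level) are excluded with a warning.
#'
#' @inheritParams unmatched_gpc
#' @returns A `gpc_result`.
#' @export
matched_gpc <- function(data, priorities) {
  ep <- gpc_endpoints(data, priorities)
  is_ab <- ep$seq_lab == "AB"
  act <- ifelse(matrix(is_ab, nrow = length(is_ab), ncol = ncol(ep$P1)), ep$P1, ep$P2)
  plc <- ifelse(matrix(is_ab, nrow = length(is_ab), ncol = ncol(ep$P1)), ep$P2, ep$P1)
  keep <- rowSums(!is.na(act)) > 0 & rowSums(!is.na(plc)) > 0
  if (any(!keep)) {
    warn(sprintf("%d subject(s) excluded from matched GPC: one arm fully missing",
                 sum(!keep)))
  }
  res <- diag(gpc_pair_matrix(ep, ep$seq_lab))[keep]
  gpc_result(sum(res == 1L), sum(res == -1L), sum(res == 0L),
             "matched", ep$priorities)
}

#' Permutation test for the GPC net benefit
#'
#' Two-sided permutation inference for the matched or unmatched net
#' benefit. The permutation law is the trial's re-randomization null (as in
#' [permute_null()]): sequence labels are shuffled across subjects while
#' every subject keeps their full outcome profile, and the net benefit is
#' recomputed under each reassignment. The p-value is
#' `(1 + #{|NB_perm| >= |NB_obs|}) / (n_perm + 1)`.
#'
#' @inheritParams unmatched_gpc
#' @param variant `"unmatched"` (default) or `"matched"`.
#' @param n_perm Number of permutations (>= 1), default 999.
#' @param seed Optional integer seed.
#' @returns A `gpc_result` with `p_value` and `n_permutations` filled in.
#' @export
gpc_permutation_test <- function(data, priorities,
                                 variant = c("unmatched", "matched"),
                                 n_perm = 999, seed = NULL, strata = NULL) {
  variant <- match.arg(variant)
  if (n_perm < 1) abort("`n_perm` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ep <- gpc_endpoints(data, priorities, strata)
  same <- outer(ep$stratum, ep$stratum, "==")

  nb_for <- function(seq_lab) {
    res <- gpc_pair_matrix(ep, seq_lab)
    if (variant == "matched") {
      r <- diag(res)
      (sum(r == 1L) - sum(r == -1L)) / length(r)
    } else {
      (sum(res == 1L & same) - sum(res == -1L & same)) / sum(same)
    }
  }

  obs <- if (variant == "matched") matched_gpc(data, ep$priorities)
         else unmatched_gpc(data, ep$priorities, strata)
  perm_nb <- vapply(seq_len(n_perm), function(i) {
    nb_for(sample(ep$seq_lab))  # same law as permute_null()
  }, numeric(1))
  obs$p_value <-
    (1 + sum(abs(perm_nb) >= abs(obs$net_benefit) - 1e-12)) / (n_perm + 1)
  obs$n_permutations <- as.integer(n_perm)
  obs
}

#' @export
print.gpc_result <- function(x, ...) {
  cat(sprintf("Generalized pairwise comparisons (%s)\n", x$variant))
  cat(sprintf("  pairs: %d  wins: %d  losses: %d  ties: %d\n",
              x$n_pairs, x$wins, x$losses, x$ties))
  cat(sprintf("  net benefit: %.4f\n", x$net_benefit))
  if (!is.na(x$p_value)) {
    cat(sprintf("  permutation p-value: %.4g (%d permutations)\n",
                x$p_value, x$n_permutations))
  }
  invisible(x)
}
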