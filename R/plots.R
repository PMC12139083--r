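#' Spaghetti plot of subject profiles
#'
#' One line per subject and period over the four assessment occasions,
#' faceted by treatment -- the standard first look at a cross-over trial.
#'
#' @param data A `long_trial`.
#' @param outcome Outcome to plot (default: first outcome present).
#' @returns A ggplot object.
#' @export
plot_profiles <- function(data, outcome = NULL) {
  data <- as_long_trial(data)
  outcome <- outcome %||% data$outcome[1]
  d <- data[data$outcome == outcome, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value,
                                  group = interaction(.data$subject_id, .data$period),
                                  colour = .data$sequence)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$treatment)) +
    ggplot2::labs(x = "occasion", y = outcome, colour = "sequence",
                  title = paste0("Subject profiles: ", outcome))
}

#' @rdname autoplot.rejection_study
#' @method autoplot gpc_result
#' @export
autoplot.gpc_result <- function(object, ...) {
  d <- tibble::tibble(
    outcome = factor(c("wins", "ties", "losses"),
                     levels = c("wins", "ties", "losses")),
    n = c(object$wins, object$ties, object$losses))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$outcome, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      y = "pairs",
      title = sprintf("GPC (%s): net benefit %.3f", object$variant,
                      object$net_benefit),
      subtitle = if (!is.na(object$p_value))
        sprintf("permutation p = %.3g", object$p_value) else NULL)
}

#' @rdname autoplot.rejection_study
#' @method autoplot ats_result
#' @export
autoplot.ats_result <- function(object, ...) {
  d <- object$relative_effects
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$p_hat,
                                  colour = .data$treatment,
                                  group = .data$treatment)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::labs(y = "relative effect", x = "occasion",
                  title = sprintf("Rank relative effects (ATS %s: p = %.3g)",
                                  object$contrast, object$p_value))
}

#' Plot methods for result objects
#'
#' `autoplot.rejection_study()` draws each method's rejection proportion
#' with its 95% Wilson interval and the nominal level; `autoplot.gpc_result()`
#' the win/tie/loss decomposition; `autoplot.ats_result()` the relative
#' effect profiles by treatment.
#'
#' @param object The result object.
#' @param ... Unused.
#' @returns A ggplot object.
#' @method autoplot rejection_study
#' @export
autoplot.rejection_study <- function(object, ...) {
  d <- object$results
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$proportion)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower, ymax = .data$upper)) +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(y = "rejection proportion",
                  title = sprintf("Rejection rates (%d replicates, alpha = %.2f)",
                                  object$n_sim, object$alpha))
}
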