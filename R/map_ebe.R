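#' Mixed-model specification for individual MAP / empirical-Bayes estimation
#'
#' Describes the subject-level conditional objective of a (possibly
#' non-linear) mixed-effects model: `neg2loglik(b, beta, data)` must return
#' the -2 log-likelihood of one subject's observations given fixed effects
#' `beta` and random effects `b`, and `Omega` is the positive-definite
#' inter-individual covariance of `b ~ N(0, Omega)`. Residual-variance
#' parameters, if any, travel inside `beta`.
#'
#' @param neg2loglik Function `(b, beta, data) -> -2 log-likelihood`.
#' @param q Random-effect dimension.
#' @param Omega q x q positive-definite covariance matrix.
#' @param predict Optional function `(beta, b, newdata) -> predictions`,
#'   used by [predict_individual()].
#' @param gradient Optional analytic gradient of `neg2loglik` in `b`.
#' @returns A `mixed_model_spec` list.
#' @seealso [gaussian_lmm_spec()], [poisson_glmm_spec()], [nb_glmm_spec()]
#' @export
mixed_model_spec <- function(neg2loglik, q, Omega, predict = NULL,
                             gradient = NULL) {
  Omega <- as.matrix(Omega)
  if (!isTRUE(all.equal(Omega, t(Omega))) ||
      any(eigen(Omega, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    abort("`Omega` must be symmetric positive-definite")
  }
  if (nrow(Omega) != q) abort("`Omega` must be q x q")
  structure(list(neg2loglik = neg2loglik, q = q, Omega = Omega,
                 predict = predict, gradient = gradient),
            class = "mixed_model_spec")
}

#' Maximum a posteriori estimate of a subject's random effects
#'
#' Minimizes the MAP objective
#' `l_i(beta, b, z_i) + b' Omega^{-1} b + log det(2 pi Omega)` -- i.e.
#' -2 times the log posterior kernel of `b` under the `N(0, Omega)` prior,
#' with `l_i` the conditional -2 log-likelihood -- by quasi-Newton search
#' with numerical (or supplied analytic) gradients. Multi-start: the prior
#' mode plus `n_start` draws from `N(0, Omega)`; the best objective wins,
#' ties broken toward the smallest `||b||`.
#'
#' With no subject data (`l_i` constant) the estimate is the prior mode 0;
#' as `Omega` shrinks toward 0 the estimate is pulled to 0 (full shrinkage).
#'
#' @param spec A [mixed_model_spec()].
#' @param data Subject-level data passed through to `neg2loglik`.
#' @param beta Fixed-effects (and residual) parameters.
#' @param start Starting value, default the prior mode `rep(0, q)`.
#' @param tol Convergence tolerance on the scaled gradient norm.
#' @param n_start Extra random starts (default 4).
#' @returns List with `b_hat`, `objective`, `gradient_norm`, `converged`
#'   and the optimizer report.
#' @export
map_estimate <- function(spec, data, beta, start = NULL, tol = 1e-8,
                         n_start = 4) {
  stopifnot(inherits(spec, "mixed_model_spec"))
  q <- spec$q
  Omega_inv <- solve(spec$Omega)
  logdet <- as.numeric(determinant(2 * pi * spec$Omega)$modulus)
  start <- start %||% rep(0, q)

  objective <- function(b) {
    val <- spec$neg2loglik(b, beta, data) + drop(t(b) %*% Omega_inv %*% b) + logdet
    if (!is.finite(val)) .Machine$double.xmax else val
  }
  gradient <- if (!is.null(spec$gradient)) {
    function(b) spec$gradient(b, beta, data) + 2 * drop(Omega_inv %*% b)
  } else {
    function(b) num_grad(objective, b)
  }
  if (!is.finite(spec$neg2loglik(start, beta, data))) {
    abort("objective is not finite at the starting value")
  }

  starts <- c(list(start),
              if (n_start > 0) {
                R <- chol(spec$Omega)
                lapply(seq_len(n_start),
                       function(i) drop(crossprod(R, rnorm(q))))
              })
  best <- NULL
  for (s in starts) {
    fit <- optim(s, objective, gradient, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    cand <- list(b_hat = fit$par, objective = fit$value,
                 counts = fit$counts, optim_convergence = fit$convergence)
    better <- is.null(best) ||
      cand$objective < best$objective - 1e-10 ||
      (abs(cand$objective - best$objective) <= 1e-10 &&
         sum(cand$b_hat^2) < sum(best$b_hat^2))
    if (better) best <- cand
  }
  # Newton polish: BFGS stops on relative objective change, which can leave
  # the argmin a few 1e-6 off; a couple of damped Newton steps on the
  # gradient tighten it
  b <- best$b_hat
  for (it in 1:10) {
    g <- gradient(b)
    if (sqrt(sum(g^2)) < 1e-10) break
    H <- matrix(0, q, q)
    h <- 1e-5 * (1 + abs(b))
    for (j in seq_len(q)) {
      e <- rep(0, q); e[j] <- h[j]
      H[, j] <- (gradient(b + e) - g) / h[j]
    }
    H <- (H + t(H)) / 2
    step_dir <- tryCatch(drop(solve(H, -g)), error = function(e) NULL)
    if (is.null(step_dir)) break
    stp <- 1
    repeat {
      cand <- b + stp * step_dir
      if (objective(cand) <= best$objective + 1e-12) break
      stp <- stp / 2
      if (stp < 1e-6) { cand <- b; break }
    }
    if (max(abs(cand - b)) < 1e-12) break
    b <- cand
    best$objective <- objective(b)
  }
  best$b_hat <- b

  g <- gradient(best$b_hat)
  gnorm <- sqrt(sum(g^2))
  best$gradient_norm <- gnorm
  best$converged <- gnorm < tol * (1 + abs(best$objective)) ||
    best$optim_convergence == 0
  best
}

# central-difference gradient
num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- rep(0, length(x)); e[j] <- h * max(1, abs(x[j]))
    (f(x + e) - f(x - e)) / (2 * e[j])
  }, numeric(1))
}

#' Predict individual outcomes from estimated random effects
#'
#' Evaluates the model's prediction function at the subject's estimated
#' random effects; with `b = 0` this is the population-typical prediction
#' (no longitudinal information used).
#'
#' @param spec A [mixed_model_spec()] with a `predict` component.
#' @param beta Fixed-effects parameters.
#' @param b Random-effects value, e.g. `map_estimate(...)$b_hat` or
#'   `rep(0, q)`.
#' @param newdata Design for the occasions to predict.
#' @returns Whatever the spec's `predict` returns (typically a tibble of
#'   model-implied means).
#' @export
predict_individual <- function(spec, beta, b, newdata) {
  stopifnot(inherits(spec, "mixed_model_spec"))
  if (is.null(spec$predict)) abort("this model spec has no predict function")
  if (length(b) != spec$q) abort("`b` must have length q")
  spec$predict(beta, b, newdata)
}

#' Built-in mixed-model specifications
#'
#' Ready-made [mixed_model_spec()]s for the models used with blister-count
#' and related outcomes. Subject data is a list with elements `y`
#' (observations), `X` (fixed-effects design) and `Z` (random-effects
#' design); `beta` carries the fixed effects, with the Gaussian residual
#' standard deviation (`sigma`) or negative-binomial size appended as the
#' last element where applicable.
#'
#' * `gaussian_lmm_spec()`: `y = X beta + Z b + e`, `e ~ N(0, sigma^2)`;
#'   `beta = c(coefficients, sigma)`.
#' * `poisson_glmm_spec()`: `y ~ Poisson(exp(X beta + Z b))`.
#' * `nb_glmm_spec()`: `y ~ NegBin(mu = exp(X beta + Z b), size)`;
#'   `beta = c(coefficients, size)`.
#'
#' @param Omega Random-effects covariance (q inferred from it).
#' @returns A `mixed_model_spec`.
#' @export
gaussian_lmm_spec <- function(Omega) {
  mixed_model_spec(
    neg2loglik = function(b, beta, data) {
      p <- ncol(data$X)
      sigma <- beta[p + 1]
      mu <- drop(data$X %*% beta[1:p] + data$Z %*% b)
      -2 * sum(stats::dnorm(data$y, mu, sigma, log = TRUE))
    },
    q = nrow(as.matrix(Omega)), Omega = Omega,
    predict = function(beta, b, newdata) {
      p <- ncol(newdata$X)
      tibble::tibble(mean = drop(newdata$X %*% beta[1:p] + newdata$Z %*% b))
    },
    gradient = function(b, beta, data) {
      p <- ncol(data$X)
      sigma <- beta[p + 1]
      r <- data$y - drop(data$X %*% beta[1:p] + data$Z %*% b)
      drop(-2 * crossprod(data$Z, r) / sigma^2)
    })
}

#' @rdname gaussian_lmm_spec
#' @export
poisson_glmm_spec <- function(Omega) {
  mixed_model_spec(
    neg2loglik = function(b, beta, data) {
      mu <- exp(drop(data$X %*% beta + data$Z %*% b))
      -2 * sum(stats::dpois(data$y, mu, log = TRUE))
    },
    q = nrow(as.matrix(Omega)), Omega = Omega,
    predict = function(beta, b, newdata) {
      tibble::tibble(mean = exp(drop(newdata$X %*% beta + newdata$Z %*% b)))
    },
    gradient = function(b, beta, data) {
      mu <- exp(drop(data$X %*% beta + data$Z %*% b))
      drop(-2 * crossprod(data$Z, data$y - mu))
    })
}

#' @rdname gaussian_lmm_spec
#' @export
nb_glmm_spec <- function(Omega) {
  mixed_model_spec(
    neg2loglik = function(b, beta, data) {
      p <- ncol(data$X)
      size <- beta[p + 1]
      mu <- exp(drop(data$X %*% beta[1:p] + data$Z %*% b))
      -2 * sum(stats::dnbinom(data$y, mu = mu, size = size, log = TRUE))
    },
    q = nrow(as.matrix(Omega)), Omega = Omega,
    predict = function(beta, b, newdata) {
      p <- ncol(newdata$X)
      tibble::tibble(mean = exp(drop(newdata$X %*% beta[1:p] + newdata$Z %*% b)))
    },
    gradient = function(b, beta, data) {
      p <- ncol(data$X)
      size <- beta[p + 1]
      mu <- exp(drop(data$X %*% beta[1:p] + data$Z %*% b))
      drop(-2 * crossprod(data$Z, (data$y - mu) * size / (size + mu)))
    })
}
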