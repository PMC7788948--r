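#' EM configuration
#'
#' Numerical settings for the per-(cell, gene) mixture fit.
#'
#' @param max_iter maximum EM iterations (default 100).
#' @param tol convergence threshold on the maximum absolute change of
#'   (lambda1, lambda2, lambda3, mu, sigma, p) between iterations
#'   (default 0.01). N is excluded, being integer-valued.
#' @param sigma_floor lower bound on the Normal standard deviation
#'   (default 0.1), guarding against point-mass collapse.
#' @param p_floor detection probability is clamped to
#'   \[p_floor, 1 - p_floor\] (default 0.01).
#' @param zero_tol values with `|x| <= zero_tol` count as zero for the
#'   point-mass component (default 1e-8).
#' @param component_eps tiny constant added to every unnormalized
#'   responsibility so degenerate rows normalize (default 1e-300).
#' @param weight_eps a component whose total responsibility falls below
#'   `weight_eps` keeps its previous parameters (default 1e-12).
#' @return list of class `em_config`.
#' @export
em_config <- function(max_iter = 100L, tol = 0.01, sigma_floor = 0.1,
                      p_floor = 0.01, zero_tol = 1e-8,
                      component_eps = 1e-300, weight_eps = 1e-12) {
  stopifnot(max_iter >= 1L, tol > 0, sigma_floor > 0, p_floor > 0,
            zero_tol > 0, component_eps > 0, weight_eps > 0)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 sigma_floor = sigma_floor, p_floor = p_floor,
                 zero_tol = zero_tol, component_eps = component_eps,
                 weight_eps = weight_eps),
            class = "em_config")
}

#' Mixture parameters
#'
#' Parameters of the three-component model for one (cell, gene):
#' a Normal component for high expression, a Binomial component for low
#' expression observed under a per-molecule detection probability, and a
#' point mass at zero for truly silent genes.
#'
#' @param lambda numeric length-3 mixture weights, summing to 1.
#' @param mu,sigma Normal mean and sd (expression units).
#' @param N Binomial size: total mRNA number, integer in 1..9.
#' @param p Binomial detection probability in (0, 1).
#' @return list of class `mixture_params`.
#' @export
mixture_params <- function(lambda, mu, sigma, N, p) {
  lambda <- as.numeric(lambda)
  if (length(lambda) != 3L) stop("lambda must have length 3")
  if (any(lambda < -1e-9) || abs(sum(lambda) - 1) > 1e-9) {
    stop("mixture weights must be nonnegative and sum to 1")
  }
  if (sigma <= 0) stop("sigma must be positive")
  N <- as.integer(N)
  if (N < 1L || N > 9L) stop("N must be an integer in 1..9")
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  structure(list(lambda = lambda, mu = mu, sigma = sigma, N = N, p = p),
            class = "mixture_params")
}

# Per-component densities at x (vectorized over x).
.component_density <- function(x, params, zero_tol) {
  k <- round(x)
  f1 <- stats::dnorm(x, params$mu, params$sigma)
  f2 <- ifelse(k >= 0 & k <= params$N,
               stats::dbinom(pmax(pmin(k, params$N), 0), params$N, params$p),
               0)
  f3 <- as.numeric(abs(x) <= zero_tol)
  cbind(f1, f2, f3, deparse.level = 0)
}

#' Mixture density
#'
#' Evaluates
#' `f(x) = lambda1 * Normal(x; mu, sigma) + lambda2 * Binomial(round(x); N, p) + lambda3 * 1{x = 0}`.
#' The Binomial term is evaluated at `round(x)` and contributes 0 outside
#' its support; the zero component is a point mass contributing only at
#' x = 0 (up to `zero_tol`).
#'
#' @param x nonnegative value(s) at which to evaluate the density.
#' @param params [mixture_params()].
#' @param zero_tol tolerance for the point mass (default 1e-8).
#' @return density value(s), same length as `x`.
#' @export
mixture_density <- function(x, params, zero_tol = 1e-8) {
  if (!inherits(params, "mixture_params")) {
    stop("params must be a mixture_params object")
  }
  f <- .component_density(x, params, zero_tol)
  as.numeric(f %*% params$lambda)
}

#' Initialize EM parameters
#'
#' mu0 and sigma0 are the mean and standard deviation of the neighbor
#' values (sigma floored); p0 = 0.1, the field's typical mRNA detection
#' rate; N0 = round(mean of nonzero values / p0) clamped to 1..9 (1 if
#' all values are zero); all three weights start at 1/3.
#'
#' @param values neighbor expression values for one gene (length >= 2).
#' @param cfg [em_config()].
#' @return [mixture_params()].
#' @export
em_init <- function(values, cfg = em_config()) {
  n <- length(values)
  if (n < 2L) stop("EM needs at least 2 values")
  mu0 <- mean(values)
  sigma0 <- max(stats::sd(values), cfg$sigma_floor)
  p0 <- 0.1
  nz <- values[values > 0]
  N0 <- if (length(nz) == 0L) 1L else
    as.integer(min(max(round(mean(nz) / p0), 1), 9))
  mixture_params(c(1, 1, 1) / 3, mu0, sigma0, N0, p0)
}

#' EM expectation step
#'
#' Computes the n x 3 responsibility matrix: entry (i, j) is proportional
#' to `lambda_j * f_j(x_i)` (with `component_eps` added to every
#' unnormalized entry), rows normalized to sum to 1.
#'
#' @param values neighbor values.
#' @param params current [mixture_params()].
#' @param cfg [em_config()].
#' @return n x 3 responsibility matrix, rows summing to 1.
#' @export
em_estep <- function(values, params, cfg = em_config()) {
  f <- .component_density(values, params, cfg$zero_tol)
  u <- sweep(f, 2L, params$lambda, "*") + cfg$component_eps
  u / rowSums(u)
}

#' EM maximization step
#'
#' For each component j the responsibility totals `P1 = sum(Pro[,j])`,
#' `P2 = sum(Pro[,j] * x)` and `P3 = sum(Pro[,j] * (x - Mean_j)^2)` give the
#' weight lambda_j = P1 / n, weighted mean Mean_j = P2 / P1 and weighted
#' sd Dev_j = sqrt(P3 / P1). The Normal component takes mu = Mean_1 and
#' sigma = max(Dev_1, sigma_floor). The Binomial component is updated by
#' method of moments on (Mean_2, Dev_2^2): p = 1 - Dev_2^2 / Mean_2
#' (clamped; unchanged if Mean_2 <= 0), N = round(Mean_2 / p) clamped to
#' 1..9, then p = Mean_2 / N (clamped) so the component mean survives the
#' rounding of N. A component with total responsibility below
#' `weight_eps` carries its previous parameters unchanged.
#'
#' @param values neighbor values.
#' @param resp responsibility matrix from [em_estep()].
#' @param prev previous [mixture_params()] (for carry-over).
#' @param cfg [em_config()].
#' @return updated [mixture_params()].
#' @export
em_mstep <- function(values, resp, prev, cfg = em_config()) {
  n <- length(values)
  P1 <- colSums(resp)
  lambda <- P1 / n

  mu <- prev$mu; sigma <- prev$sigma
  if (P1[1] >= cfg$weight_eps) {
    mean1 <- sum(resp[, 1] * values) / P1[1]
    dev1 <- sqrt(sum(resp[, 1] * (values - mean1)^2) / P1[1])
    mu <- mean1
    sigma <- max(dev1, cfg$sigma_floor)
  }

  N <- prev$N; p <- prev$p
  if (P1[2] >= cfg$weight_eps) {
    mean2 <- sum(resp[, 2] * values) / P1[2]
    var2 <- sum(resp[, 2] * (values - mean2)^2) / P1[2]
    if (mean2 > 0) {
      p <- min(max(1 - var2 / mean2, cfg$p_floor), 1 - cfg$p_floor)
    }
    N <- as.integer(min(max(round(mean2 / p), 1), 9))
    p <- min(max(mean2 / N, cfg$p_floor), 1 - cfg$p_floor)
  }

  mixture_params(lambda, mu, sigma, N, p)
}

#' Fit the three-component mixture by EM
#'
#' Alternates [em_estep()] and [em_mstep()] from [em_init()] until the
#' maximum absolute change over (lambda1, lambda2, lambda3, mu, sigma, p)
#' drops below `cfg$tol`, or `cfg$max_iter` iterations.
#'
#' @param values neighbor values for one gene (length >= 2).
#' @param cfg [em_config()].
#' @return list with `params` ([mixture_params()]), `iterations` and
#'   `converged`.
#' @export
fit_mixture <- function(values, cfg = em_config()) {
  params <- em_init(values, cfg)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(cfg$max_iter)) {
    resp <- em_estep(values, params, cfg)
    new <- em_mstep(values, resp, params, cfg)
    delta <- max(abs(c(new$lambda - params$lambda, new$mu - params$mu,
                       new$sigma - params$sigma, new$p - params$p)))
    params <- new
    if (delta < cfg$tol) { converged <- TRUE; break }
  }
  list(params = params, iterations = it, converged = converged)
}

.PROVENANCE_LEVELS <- c("kept_nonzero", "kept_high", "imputed_dropout",
                        "true_zero", "no_neighbors")

#' Decide whether to keep, impute, or zero an observed value
#'
#' Applies the argmax rule over the fitted mixture weights (ties broken
#' by smallest component index, favoring observed data):
#' \itemize{
#'   \item lambda1 highest (high expression): keep the observed value
#'     (`kept_high`).
#'   \item lambda2 highest (low expression, dropout-prone): replace with
#'     the Binomial mean `N * p` (`imputed_dropout`). In the default
#'     `zeros_only` mode only observed zeros are replaced; a nonzero
#'     observation passes through as `kept_nonzero`. `literal` mode
#'     replaces unconditionally.
#'   \item lambda3 highest (truly silent): an observed zero stays 0
#'     (`true_zero`); an observed nonzero passes through as
#'     `kept_nonzero` (the observation contradicts the zero-dominant
#'     model and is surfaced in run reports).
#' }
#'
#' @param x_obs observed value (>= 0).
#' @param params fitted [mixture_params()].
#' @param mode `"zeros_only"` (default) or `"literal"`.
#' @return list with `value` and `label` (one of kept_nonzero,
#'   kept_high, imputed_dropout, true_zero).
#' @export
decide_and_impute <- function(x_obs, params, mode = c("zeros_only", "literal")) {
  mode <- match.arg(mode)
  j <- which.max(params$lambda)  # first maximum: lowest component index
  if (j == 1L) {
    return(list(value = x_obs, label = "kept_high"))
  }
  if (j == 2L) {
    if (mode == "literal" || x_obs == 0) {
      return(list(value = params$N * params$p, label = "imputed_dropout"))
    }
    return(list(value = x_obs, label = "kept_nonzero"))
  }
  if (x_obs == 0) {
    return(list(value = 0, label = "true_zero"))
  }
  list(value = x_obs, label = "kept_nonzero")
}
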