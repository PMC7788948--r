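# Independent brute-force oracles. These deliberately use explicit loops
# and elementwise arithmetic, never the package's vectorized code paths.

# One EM iteration written directly from the component densities and the
# responsibility-total formulas P1 = sum(Pro[,j]), P2 = sum(Pro[,j]*x),
# Mean_j = P2/P1, lambda_j = P1/n, P3 = sum(Pro[,j]*(x-Mean_j)^2),
# Dev_j = sqrt(P3/P1).
oracle_em_iteration <- function(values, params, cfg) {
  n <- length(values)
  Pro <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    x <- values[i]
    f1 <- stats::dnorm(x, params$mu, params$sigma)
    k <- round(x)
    f2 <- if (k >= 0 && k <= params$N) stats::dbinom(k, params$N, params$p) else 0
    f3 <- if (abs(x) <= cfg$zero_tol) 1 else 0
    u <- c(params$lambda[1] * f1, params$lambda[2] * f2,
           params$lambda[3] * f3) + cfg$component_eps
    Pro[i, ] <- u / sum(u)
  }
  lambda <- numeric(3); mean_j <- numeric(3); dev_j <- numeric(3)
  for (j in 1:3) {
    P1 <- 0; for (i in seq_len(n)) P1 <- P1 + Pro[i, j]
    P2 <- 0; for (i in seq_len(n)) P2 <- P2 + Pro[i, j] * values[i]
    lambda[j] <- P1 / n
    mean_j[j] <- if (P1 >= cfg$weight_eps) P2 / P1 else NA_real_
    if (P1 >= cfg$weight_eps) {
      P3 <- 0
      for (i in seq_len(n)) P3 <- P3 + Pro[i, j] * (values[i] - mean_j[j])^2
      dev_j[j] <- sqrt(P3 / P1)
    } else dev_j[j] <- NA_real_
  }
  # Normal component
  mu <- if (is.na(mean_j[1])) params$mu else mean_j[1]
  sigma <- if (is.na(dev_j[1])) params$sigma else max(dev_j[1], cfg$sigma_floor)
  # Binomial component: method of moments, N clamped and p re-solved
  N <- params$N; p <- params$p
  if (!is.na(mean_j[2])) {
    var2 <- dev_j[2]^2
    if (mean_j[2] > 0) {
      p <- min(max(1 - var2 / mean_j[2], cfg$p_floor), 1 - cfg$p_floor)
    }
    N <- min(max(round(mean_j[2] / p), 1), 9)
    p <- min(max(mean_j[2] / N, cfg$p_floor), 1 - cfg$p_floor)
  }
  list(resp = Pro, lambda = lambda, mu = mu, sigma = sigma,
       N = as.integer(N), p = p)
}

# Pair-counting ARI by exhaustive enumeration of all C(n, 2) pairs.
oracle_ari_pairs <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  total <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / total
  max_idx <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_idx == expected) return(if (n11 == expected) 1 else 0)
  (n11 - expected) / (max_idx - expected)
}

# Eq.-style intra/inter distances as literal double loops over cells.
oracle_intra_inter <- function(m, labels) {
  sqd <- function(x, y) sum((x - y)^2)
  classes <- unique(labels)
  intra <- 0
  for (cl in classes) {
    idx <- which(labels == cl)
    s <- 0
    for (k in idx) for (l in idx) s <- s + sqd(m[, k], m[, l])
    intra <- intra + s / (length(idx)^2)
  }
  inter <- 0
  for (ci in classes) {
    for (cj in classes) {
      if (ci == cj) next
      ii <- which(labels == ci); jj <- which(labels == cj)
      s <- 0
      for (k in ii) for (l in jj) s <- s + sqd(m[, k], m[, l])
      inter <- inter + s / (length(ii) * length(jj))
    }
  }
  list(dis_intra = intra, dis_inter = inter, dis_ratio = intra / inter)
}

expect_params_equal <- function(fit, oracle, tol = 1e-9) {
  expect_equal(fit$lambda, oracle$lambda, tolerance = tol)
  expect_equal(fit$mu, oracle$mu, tolerance = tol)
  expect_equal(fit$sigma, oracle$sigma, tolerance = tol)
  expect_equal(fit$N, oracle$N)
  expect_equal(fit$p, oracle$p, tolerance = tol)
}
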