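test_that("mixture density matches its closed form, point mass and degenerate weights", {
  par <- mixture_params(c(1, 1, 1) / 3, mu = 5, sigma = 1, N = 5, p = 0.1)
  expect_equal(mixture_density(0, par),
               (stats::dnorm(0, 5, 1) + 0.9^5 + 1) / 3, tolerance = 1e-12)
  # away from zero the point mass contributes nothing
  expect_equal(mixture_density(3, par),
               (stats::dnorm(3, 5, 1) + stats::dbinom(3, 5, 0.1)) / 3,
               tolerance = 1e-12)
  # outside the binomial support only the normal term remains
  expect_equal(mixture_density(7, par), stats::dnorm(7, 5, 1) / 3,
               tolerance = 1e-12)
  pure <- mixture_params(c(1, 0, 0), mu = 2, sigma = 0.5, N = 3, p = 0.2)
  x <- c(0, 0.5, 1.7, 4)
  expect_equal(mixture_density(x, pure), stats::dnorm(x, 2, 0.5),
               tolerance = 1e-12)
  expect_error(mixture_params(c(0.5, 0.2, 0.2), 1, 1, 3, 0.5), "sum to 1")
})

test_that("initialization follows the stated rules including degenerate inputs", {
  cfg <- em_config()
  p0 <- em_init(c(0, 0, 0, 0), cfg)
  expect_equal(p0$mu, 0)
  expect_equal(p0$sigma, cfg$sigma_floor)
  expect_equal(p0$N, 1L)
  expect_equal(p0$p, 0.1)
  expect_equal(p0$lambda, rep(1, 3) / 3)

  p1 <- em_init(c(0, 0, 1, 1), cfg)
  expect_equal(p1$mu, 0.5)
  expect_equal(p1$N, 9L)  # round(1 / 0.1) = 10, clamped to 9

  p2 <- em_init(c(0, 2, 4), cfg)
  expect_equal(p2$mu, 2)
  expect_equal(p2$sigma, stats::sd(c(0, 2, 4)))
  expect_equal(p2$N, 9L)  # round(3 / 0.1) = 30 -> 9

  expect_error(em_init(5), "at least 2")
})

test_that("E-step rows normalize and concentrate where only one component lives", {
  cfg <- em_config()
  set.seed(14)
  for (r in 1:10) {
    v <- c(0, 0, rpois(6, 4))
    par <- em_init(v, cfg)
    resp <- em_estep(v, par, cfg)
    expect_equal(rowSums(resp), rep(1, length(v)), tolerance = 1e-12)
    expect_true(all(resp >= 0 & resp <= 1))
    # zero-component responsibility vanishes off the point mass
    expect_true(all(resp[v > cfg$zero_tol, 3] < 1e-100))
  }
  # x beyond the binomial support and off zero: all mass on the Normal
  par <- mixture_params(c(1, 1, 1) / 3, mu = 6, sigma = 2, N = 5, p = 0.2)
  resp <- em_estep(7, par, cfg)
  expect_gt(resp[1, 1], 1 - 1e-10)
  # x = 0 under a zero-heavy model: closed-form responsibility ratio
  par <- mixture_params(c(0.05, 0.05, 0.9), mu = 5, sigma = 1, N = 4, p = 0.3)
  resp <- em_estep(0, par, cfg)
  expected <- 0.9 / (0.05 * stats::dnorm(0, 5, 1) + 0.05 * 0.7^4 + 0.9)
  expect_equal(resp[1, 3], expected, tolerance = 1e-9)
})

test_that("M-step reproduces hand-derived updates and conserves weight", {
  cfg <- em_config()
  prev <- mixture_params(c(1, 1, 1) / 3, mu = 1, sigma = 1, N = 3, p = 0.1)

  # all responsibility on the Normal for constant values
  resp <- cbind(1, 0, 0)[rep(1, 3), ]
  up <- em_mstep(c(10, 10, 10), resp, prev, cfg)
  expect_equal(up$lambda, c(1, 0, 0))
  expect_equal(up$mu, 10)
  expect_equal(up$sigma, cfg$sigma_floor)

  # uniform responsibilities on (0, 3): every weighted mean is 1.5
  resp <- matrix(1 / 3, 2, 3)
  up <- em_mstep(c(0, 3), resp, prev, cfg)
  expect_equal(up$lambda, rep(1, 3) / 3)
  expect_equal(up$mu, 1.5)
  # binomial update: var 2.25 > mean 1.5 so p floors, N = round(1.5/p)
  # clamps to 9, then p = 1.5/9
  expect_equal(up$N, 9L)
  expect_equal(up$p, 1.5 / 9)

  set.seed(15)
  for (r in 1:10) {
    v <- rpois(8, 3)
    resp <- matrix(stats::runif(24), 8, 3)
    resp <- resp / rowSums(resp)
    up <- em_mstep(v, resp, prev, cfg)
    expect_equal(sum(up$lambda), 1, tolerance = 1e-12)
  }
})

test_that("one EM iteration agrees with the brute-force formula oracle", {
  cfg <- em_config()
  set.seed(16)
  for (r in 1:30) {
    n <- sample(3:8, 1)
    v <- ifelse(stats::runif(n) < 0.4, 0, rpois(n, sample(c(2, 10), 1)))
    par <- em_init(v, cfg)
    oracle <- oracle_em_iteration(v, par, cfg)
    resp <- em_estep(v, par, cfg)
    up <- em_mstep(v, resp, par, cfg)
    expect_equal(unname(resp), unname(oracle$resp), tolerance = 1e-12)
    expect_params_equal(up, oracle)
  }
})

test_that("full fits converge sensibly on archetypal value sets", {
  cfg <- em_config()
  # constants with no zeros: the point mass has no support
  f <- fit_mixture(rep(10, 12), cfg)
  expect_lte(f$params$lambda[3], 0.01)
  expect_true(f$converged)

  # clean Normal data: the Normal component dominates and mu is recovered
  set.seed(7)
  st <- sapply(1:50, function(i) {
    v <- stats::rnorm(20, 20, 2)
    fp <- fit_mixture(v, cfg)$params
    c(fp$mu, fp$lambda[1])
  })
  expect_true(abs(stats::median(st[1, ]) - 20) <= 2)
  expect_gte(stats::median(st[2, ]), 0.8)

  # half zeros, half conditioned binomial draws: zero mass is substantial
  set.seed(8)
  l3 <- sapply(1:50, function(i) {
    nz <- numeric(0)
    while (length(nz) < 10) {
      d <- stats::rbinom(20, 5, 0.5)
      nz <- c(nz, d[d > 0])
    }
    v <- c(rep(0, 10), nz[1:10])
    fit_mixture(v, cfg)$params$lambda[3]
  })
  expect_gte(stats::median(l3), 0.3)
})

test_that("weights stay on the simplex after every M step of a full fit", {
  cfg <- em_config()
  set.seed(17)
  v <- c(0, 0, 0, 1, 2, 0, 8, 9, 10, 0)
  par <- em_init(v, cfg)
  for (it in 1:20) {
    par <- em_mstep(v, em_estep(v, par, cfg), par, cfg)
    expect_equal(sum(par$lambda), 1, tolerance = 1e-12)
    expect_true(all(par$lambda >= -1e-12))
    expect_gte(par$sigma, cfg$sigma_floor)
    expect_true(par$N >= 1 && par$N <= 9)
    expect_true(par$p >= cfg$p_floor && par$p <= 1 - cfg$p_floor)
  }
})

test_that("the C++ batch fitter is exactly the R reference fit, per gene", {
  cfg <- em_config()
  set.seed(42)
  for (r in 1:40) {
    n <- sample(5:20, 1)
    v <- ifelse(stats::runif(n) < 0.5, 0, rpois(n, sample(c(1, 3, 15), 1)))
    ref <- fit_mixture(v, cfg)
    got <- sccimpute:::em_fit_batch_cpp(matrix(v, 1), unclass(cfg))
    expect_equal(unname(got[1, 1:3]), ref$params$lambda, tolerance = 1e-9)
    expect_equal(unname(got[1, "mu"]), ref$params$mu, tolerance = 1e-9)
    expect_equal(unname(got[1, "sigma"]), ref$params$sigma, tolerance = 1e-9)
    expect_equal(unname(got[1, "N"]), as.numeric(ref$params$N))
    expect_equal(unname(got[1, "p"]), ref$params$p, tolerance = 1e-9)
    expect_equal(unname(got[1, "iterations"]), as.numeric(ref$iterations))
  }
})

test_that("the argmax decision rule keeps, imputes, or zeroes as printed", {
  par <- mixture_params(c(0.1, 0.7, 0.2), mu = 5, sigma = 1, N = 5, p = 0.1)
  d <- decide_and_impute(0, par)
  expect_equal(d$value, 0.5)  # N * p
  expect_identical(d$label, "imputed_dropout")

  par <- mixture_params(c(0.7, 0.2, 0.1), mu = 5, sigma = 1, N = 5, p = 0.1)
  d <- decide_and_impute(4.2, par)
  expect_equal(d$value, 4.2)
  expect_identical(d$label, "kept_high")

  par <- mixture_params(c(0.1, 0.2, 0.7), mu = 5, sigma = 1, N = 5, p = 0.1)
  d <- decide_and_impute(0, par)
  expect_equal(d$value, 0)
  expect_identical(d$label, "true_zero")
  # an observed nonzero contradicting the zero-dominant model is kept
  d <- decide_and_impute(2, par)
  expect_equal(d$value, 2)
  expect_identical(d$label, "kept_nonzero")

  # zeros_only keeps nonzero values even when the binomial wins;
  # literal mode replaces them
  par <- mixture_params(c(0.1, 0.7, 0.2), mu = 5, sigma = 1, N = 4, p = 0.25)
  expect_identical(decide_and_impute(3, par, "zeros_only")$label, "kept_nonzero")
  lit <- decide_and_impute(3, par, "literal")
  expect_equal(lit$value, 1)
  expect_identical(lit$label, "imputed_dropout")

  # argmax ties resolve to the lowest component index
  par <- mixture_params(c(0.4, 0.4, 0.2), mu = 5, sigma = 1, N = 5, p = 0.1)
  expect_identical(decide_and_impute(0, par)$label, "kept_high")
})
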