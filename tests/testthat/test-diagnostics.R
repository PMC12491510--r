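test_that("psrf matches hand arithmetic and handles degenerate chains", {
  # identical chains: B = 0, psrf = sqrt((n-1)/n)
  expect_equal(psrf(list(c(1, 2, 3, 4), c(1, 2, 3, 4))), sqrt(3 / 4))
  for (n in c(5, 50, 500)) {
    x <- rnorm(n)
    expect_equal(psrf(list(x, x)), sqrt((n - 1) / n))
  }
  # distinct constant chains: W = 0, B > 0
  expect_identical(psrf(list(rep(0, 4), rep(1, 4))), Inf)
  # all draws identical
  expect_identical(psrf(list(rep(2, 4), rep(2, 4))), 1)
  expect_error(psrf(list(1:4)), "2 chains")

  # full two-chain formula on a worked example
  c1 <- c(0, 1, 2, 3); c2 <- c(2, 3, 4, 5)
  W <- (var(c1) + var(c2)) / 2
  B <- 4 * var(c(mean(c1), mean(c2)))
  expect_equal(psrf(list(c1, c2)), sqrt((3 / 4 * W + B / 4) / W))
})

test_that("effective sample size tracks the autocorrelation structure", {
  set.seed(123)
  n <- 10000
  # iid draws: ess near n
  x <- rnorm(n)
  ess <- effective_sample_size(x)
  expect_gt(ess, 0.8 * n)
  expect_lt(ess, 1.2 * n)

  # AR(1) with coefficient 0.5: ess -> n (1 - rho) / (1 + rho) = n / 3
  rho <- 0.5
  ar <- as.numeric(arima.sim(list(ar = rho), n = n))
  ess_ar <- effective_sample_size(ar)
  expect_lt(abs(ess_ar - n / 3), 0.2 * n / 3)

  # constant chain
  expect_identical(effective_sample_size(rep(1, 100)), 0)

  # never exceeds the documented inflation cap
  y <- rep(c(-1, 1), 500) + rnorm(1000, sd = 0.01)  # strongly anticorrelated
  expect_lte(effective_sample_size(y), 1.5 * 1000)

  # multi-chain pooling sums the chain sizes
  ess2 <- effective_sample_size(list(rnorm(5000), rnorm(5000)))
  expect_gt(ess2, 0.8 * 10000)
})

test_that("posterior summaries use pooled medians and interpolated quantiles", {
  mk_draws <- function(chains, names = "x") {
    structure(list(
      chains = lapply(chains, function(v) matrix(v, ncol = length(names),
                                                 dimnames = list(NULL, names))),
      par_names = names,
      config = mcmc_config(n_chains = length(chains), burn_in = 0,
                           n_iterations = length(chains[[1]])),
      dependence = FALSE
    ), class = "blcm_draws")
  }
  s <- summarize_draws(mk_draws(list(sample(1:100), sample(1:100))))
  expect_equal(s$estimate, 50.5)
  # pooled draws hold each of 1..100 twice; the type-7 quantile index is
  # h = (200 - 1) * 0.025 + 1 = 5.975, and the 5th and 6th order statistics
  # are both 3, so the interpolated 2.5% quantile is exactly 3
  expect_equal(s$lower95, 3)

  s2 <- summarize_draws(mk_draws(list(rep(3, 50), rep(3, 50))))
  expect_equal(c(s2$estimate, s2$lower95, s2$upper95), c(3, 3, 3))

  # location equivariance: shifting draws shifts all three outputs
  set.seed(5)
  base <- list(rnorm(200), rnorm(200))
  s0 <- summarize_draws(mk_draws(base))
  s1 <- summarize_draws(mk_draws(lapply(base, `+`, 10)))
  expect_equal(s1$estimate, s0$estimate + 10)
  expect_equal(s1$lower95, s0$lower95 + 10)
  expect_equal(s1$upper95, s0$upper95 + 10)
})

test_that("model selection follows the interval-includes-zero rule", {
  mk_sum <- function(lo_p, hi_p, lo_n, hi_n) {
    s <- data.frame(
      parameter = c("se1", "cov_dpos", "cov_dneg"),
      estimate = c(0.9, mean(c(lo_p, hi_p)), mean(c(lo_n, hi_n))),
      lower95 = c(0.8, lo_p, lo_n),
      upper95 = c(1.0, hi_p, hi_n),
      ess = 2000, psrf = 1
    )
    class(s) <- c("blcm_summary", "data.frame")
    s
  }
  expect_identical(select_model(mk_sum(-0.02, 0.03, -0.01, 0.04)), "independence")
  expect_identical(select_model(mk_sum(0.01, 0.05, -0.01, 0.04)), "dependence")
  expect_identical(select_model(mk_sum(-0.02, 0.03, 0.005, 0.05)), "dependence")
  # endpoint convention: a closed interval touching 0 counts as including 0
  expect_identical(select_model(mk_sum(0, 0.05, -0.01, 0.01)), "independence")
  expect_error(select_model(mk_sum(0, 0.05, -0.01, 0.01)[1:2, ]), "cov_dneg")
})

test_that("convergence report applies the study thresholds", {
  s <- data.frame(parameter = c("se1", "sp1"), estimate = c(0.9, 0.8),
                  lower95 = 0, upper95 = 1,
                  ess = c(2000, 800), psrf = c(1.01, 1.2))
  rep <- convergence_report(s)
  expect_false(attr(rep, "converged"))
  expect_identical(attr(rep, "failing"), "sp1")
  expect_true(attr(convergence_report(s, psrf_max = 1.5, ess_min = 500),
                   "converged"))
})

test_that("summary of a conjugate-limit run matches closed-form quantiles", {
  x <- 40; n <- 120
  d <- study_data(list(population_counts("A", x, 0, 0, n - x)))
  pr <- minimally_informative_priors(1, allow_single = TRUE)
  fit <- gibbs_independence(d, pr, quick_mcmc(seed = 30, burn_in = 100,
                                              n_iterations = 2500),
                            fixed = list(se1 = 1, sp1 = 1, se2 = 1, sp2 = 1),
                            allow_single = TRUE)
  s <- summarize_draws(fit)
  row <- s[s$parameter == "prev1", ]
  a <- 1 + x; b <- 1 + n - x
  expect_equal(row$estimate, qbeta(0.5, a, b), tolerance = 0.01)
  expect_equal(row$lower95, qbeta(0.025, a, b), tolerance = 0.015)
  expect_equal(row$upper95, qbeta(0.975, a, b), tolerance = 0.015)
  expect_lt(row$psrf, 1.05)
})
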