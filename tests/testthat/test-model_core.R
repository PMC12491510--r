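test_that("covariance bounds match the feasibility arithmetic", {
  expect_equal(covariance_bounds(1, 1), list(lower = 0, upper = 0))
  expect_equal(covariance_bounds(0.5, 0.5), list(lower = -0.25, upper = 0.25))
  b <- covariance_bounds(0.905, 0.730)
  expect_equal(b$upper, 0.730 - 0.905 * 0.730)
  expect_equal(b$lower, max(-(1 - 0.905) * (1 - 0.730), -0.905 * 0.730))
  # zero is always feasible
  set.seed(2)
  for (i in 1:20) {
    bi <- covariance_bounds(runif(1), runif(1))
    expect_lte(bi$lower, 0)
    expect_gte(bi$upper, 0)
  }
})

test_that("cell probabilities follow the mixture formula and normalise", {
  # perfect tests concentrate on the concordant cells
  p <- model_parameters(test_accuracy(1, 1), test_accuracy(1, 1),
                        prevalence = c(0.3))
  expect_equal(unname(cell_probabilities(p, 1)), c(0.3, 0, 0, 0.7))

  # study point estimates against independent hand arithmetic
  p2 <- model_parameters(test_accuracy(0.905, 0.822), test_accuracy(0.730, 0.726),
                         prevalence = c(0.518, 0.817))
  cells <- cell_probabilities(p2, 1)
  expect_equal(unname(cells[1]),
               0.518 * 0.905 * 0.730 + 0.482 * (1 - 0.822) * (1 - 0.726))
  expect_equal(unname(cells),
               oracle_cells(0.905, 0.822, 0.730, 0.726, 0.518))

  # property: non-negative, sums to 1, with and without dependence
  set.seed(7)
  for (i in 1:50) {
    pars <- random_params(K = 2, dependence = i %% 2 == 0)
    for (k in 1:2) {
      cells <- cell_probabilities(pars, k)
      expect_true(all(cells >= 0))
      expect_equal(sum(cells), 1, tolerance = 1e-12)
      expect_equal(unname(cells), oracle_cells(
        pars$test1$se, pars$test1$sp, pars$test2$se, pars$test2$sp,
        pars$prevalence[k],
        if (is.null(pars$dependence)) 0 else pars$dependence$cov_dpos,
        if (is.null(pars$dependence)) 0 else pars$dependence$cov_dneg
      ))
    }
  }
})

test_that("zero covariances reproduce the independence model exactly", {
  set.seed(9)
  for (i in 1:10) {
    se1 <- runif(1); sp1 <- runif(1); se2 <- runif(1); sp2 <- runif(1)
    prev <- runif(2)
    ind <- model_parameters(test_accuracy(se1, sp1), test_accuracy(se2, sp2), prev)
    dep <- model_parameters(test_accuracy(se1, sp1), test_accuracy(se2, sp2),
                            prev, dependence = dependence_terms(0, 0))
    for (k in 1:2) {
      expect_identical(cell_probabilities(ind, k), cell_probabilities(dep, k))
    }
  }
})

test_that("covariances outside their bounds are rejected by name", {
  expect_error(
    model_parameters(test_accuracy(0.9, 0.8), test_accuracy(0.7, 0.7),
                     prevalence = 0.5,
                     dependence = dependence_terms(cov_dpos = 0.5)),
    "cov_dpos"
  )
  expect_error(
    model_parameters(test_accuracy(0.9, 0.8), test_accuracy(0.7, 0.7),
                     prevalence = 0.5,
                     dependence = dependence_terms(cov_dneg = -0.9)),
    "cov_dneg"
  )
})

test_that("log-likelihood agrees with brute-force cell computation", {
  # single-cell data: kernel is n * log q
  p <- model_parameters(test_accuracy(0.9, 0.8), test_accuracy(0.7, 0.75),
                        prevalence = 0.4)
  d1 <- study_data(list(population_counts("A", 17, 0, 0, 1)))
  q <- cell_probabilities(p, 1)
  expect_equal(log_likelihood(p, d1),
               17 * log(q[["p11"]]) + 1 * log(q[["p00"]]))

  # random small instances vs dmultinom and the oracle cells
  set.seed(21)
  for (i in 1:10) {
    pars <- random_params(K = 2, dependence = i %% 2 == 0)
    cnt <- matrix(rpois(8, 10) + 1, 2, 4)
    d <- study_data(list(
      population_counts("A", cnt[1, 1], cnt[1, 2], cnt[1, 3], cnt[1, 4]),
      population_counts("B", cnt[2, 1], cnt[2, 2], cnt[2, 3], cnt[2, 4])
    ))
    cells <- lapply(1:2, function(k) oracle_cells(
      pars$test1$se, pars$test1$sp, pars$test2$se, pars$test2$sp,
      pars$prevalence[k],
      if (is.null(pars$dependence)) 0 else pars$dependence$cov_dpos,
      if (is.null(pars$dependence)) 0 else pars$dependence$cov_dneg
    ))
    brute_kernel <- sum(cnt[1, ] * log(cells[[1]])) + sum(cnt[2, ] * log(cells[[2]]))
    expect_equal(log_likelihood(pars, d), brute_kernel, tolerance = 1e-10)
    with_coef <- dmultinom(cnt[1, ], prob = cells[[1]], log = TRUE) +
      dmultinom(cnt[2, ], prob = cells[[2]], log = TRUE)
    expect_equal(log_likelihood(pars, d, kernel = FALSE), with_coef,
                 tolerance = 1e-10)
  }

  # impossible cell with positive count gives -Inf, not an error
  perfect <- model_parameters(test_accuracy(1, 1), test_accuracy(1, 1), c(0.5, 0.5))
  expect_identical(log_likelihood(perfect, tiny_study()), -Inf)
})

test_that("predictive values evaluate the closed formulas and are monotone", {
  expect_equal(ppv(0.905, 0.822, 0.518),
               0.518 * 0.905 / (0.518 * 0.905 + (1 - 0.518) * (1 - 0.822)))
  expect_equal(npv(0.905, 0.822, 0.817),
               (1 - 0.817) * 0.822 / (0.817 * (1 - 0.905) + (1 - 0.817) * 0.822))
  expect_equal(ppv(0.6, 1, 0.2), 1)  # perfect specificity: no false positives

  prevs <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(vapply(prevs, function(p) ppv(0.9, 0.8, p), 1)) > 0))
  expect_true(all(diff(vapply(prevs, function(p) npv(0.9, 0.8, p), 1)) < 0))
  ses <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(vapply(ses, function(s) ppv(s, 0.8, 0.3), 1)) > 0))
  sps <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(vapply(sps, function(s) ppv(0.9, s, 0.3), 1)) > 0))

  expect_error(ppv(0.5, 1, 0), "undefined")
  expect_error(npv(1, 0.5, 1), "undefined")
  expect_error(ppv(1.2, 0.5, 0.5), "must lie in")
})
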