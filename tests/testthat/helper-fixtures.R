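# Shared fixtures for the test suite. Everything is generated in code.

# A small, fixed two-population dataset (hand-picked counts, no special
# structure) for IO and likelihood tests.
tiny_study <- function() {
  study_data(list(
    population_counts("A", n11 = 12, n10 = 5, n01 = 7, n00 = 26),
    population_counts("B", n11 = 20, n10 = 3, n01 = 6, n00 = 13)
  ))
}

# Short MCMC protocol for unit tests that only need a functioning chain.
quick_mcmc <- function(seed = 1, burn_in = 200, n_iterations = 500,
                       n_chains = 2) {
  mcmc_config(n_chains = n_chains, burn_in = burn_in,
              n_iterations = n_iterations, seed = seed)
}

# Independent arithmetic for the marginal cell probabilities, written
# directly from the mixture formula (used as an oracle against
# cell_probabilities and log_likelihood).
oracle_cells <- function(se1, sp1, se2, sp2, prev, cp = 0, cn = 0) {
  cells <- numeric(4)
  i <- 0
  for (t1 in c(1, 0)) for (t2 in if (t1 == 1) c(1, 0) else c(1, 0)) {
    i <- i + 1
    gam <- if (t1 == t2) 1 else -1
    a <- se1^t1 * (1 - se1)^(1 - t1) * se2^t2 * (1 - se2)^(1 - t2) + gam * cp
    b <- (1 - sp1)^t1 * sp1^(1 - t1) * (1 - sp2)^t2 * sp2^(1 - t2) + gam * cn
    cells[i] <- prev * a + (1 - prev) * b
  }
  cells  # order (1,1), (1,0), (0,1), (0,0)
}

# Random valid model parameters, optionally with covariances drawn inside
# their feasibility bounds.
random_params <- function(K = 2, dependence = FALSE) {
  se1 <- runif(1); sp1 <- runif(1); se2 <- runif(1); sp2 <- runif(1)
  dep <- NULL
  if (dependence) {
    bp <- covariance_bounds(se1, se2)
    bn <- covariance_bounds(sp1, sp2)
    dep <- dependence_terms(runif(1, bp$lower, bp$upper),
                            runif(1, bn$lower, bn$upper))
  }
  model_parameters(test_accuracy(se1, sp1), test_accuracy(se2, sp2),
                   prevalence = runif(K), dependence = dep)
}
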