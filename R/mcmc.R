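# Posterior samplers for the Hui-Walter latent class model.
#
# Conditional independence: data-augmentation Gibbs. Each iteration draws the
# latent true-positive count in every observed cell from its binomial full
# conditional, then prevalence and the four accuracy parameters from beta
# full conditionals (prior shape + augmented successes/failures).
#
# Conditional dependence: the same augmentation, with the two within-class
# covariance terms updated by random-walk Metropolis on their feasibility
# interval, and the accuracy parameters updated by Metropolis-Hastings using
# the independence beta full conditional as proposal. The acceptance ratio
# carries (i) the covariance correction to the within-class cell
# probabilities and (ii) the normalisation of the conditional-uniform
# covariance prior, whose feasibility interval moves with the accuracies.
# When both covariances are zero the ratio is exactly 1, so the sampler
# reduces bit-identically to the Gibbs sampler.
#
# Both samplers append a sweep of univariate slice updates on the
# observed-data (marginal) posterior after the augmentation moves; this
# leaves the target invariant and removes the heavy autocorrelation the
# augmentation alone would carry at large sample sizes.

#' MCMC configuration
#'
#' Defaults follow the study protocol: two independent chains, burn-in 5000,
#' 10,000 retained iterations per chain.
#'
#' @param n_chains Number of independent chains (>= 2 for the Gelman-Rubin
#'   diagnostic).
#' @param burn_in Discarded initial iterations per chain.
#' @param n_iterations Post-burn-in iterations per chain.
#' @param seed Integer seed; chain c is seeded with `seed + c`.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param enforce_identifiability Resolve latent-class label switching by
#'   relabelling states in the mirror mode (both tests with se + sp < 1).
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2, burn_in = 5000, n_iterations = 10000,
                        seed = 1, thin = 1, enforce_identifiability = TRUE) {
  if (n_chains < 1 || n_iterations < 1 || burn_in < 0 || thin < 1) {
    stop("invalid MCMC configuration: chain/iteration counts must be positive",
         call. = FALSE)
  }
  structure(list(n_chains = as.integer(n_chains), burn_in = as.integer(burn_in),
                 n_iterations = as.integer(n_iterations), seed = as.integer(seed),
                 thin = as.integer(thin),
                 enforce_identifiability = isTRUE(enforce_identifiability)),
            class = "mcmc_config")
}

# x * log(y) with the convention 0 * log(0) = 0; -Inf when y = 0 and x > 0.
xlogy <- function(x, y) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log(y[pos])
  sum(out)
}

# Relabel one state vector if it sits in the mirror mode. Swapping the class
# labels maps se_i -> 1 - sp_i, sp_i -> 1 - se_i, prev -> 1 - prev and
# exchanges the covariance terms; this is the transformation that leaves the
# likelihood invariant (the naive complement se -> 1 - se does not).
relabel_if_mirrored <- function(state, K, dependence) {
  if (state["se1"] + state["sp1"] < 1 && state["se2"] + state["sp2"] < 1) {
    state[c("se1", "sp1", "se2", "sp2")] <-
      1 - state[c("sp1", "se1", "sp2", "se2")]
    pk <- paste0("prev", seq_len(K))
    state[pk] <- 1 - state[pk]
    if (dependence) {
      state[c("cov_dpos", "cov_dneg")] <- state[c("cov_dneg", "cov_dpos")]
    }
    attr(state, "relabeled") <- TRUE
  } else {
    attr(state, "relabeled") <- FALSE
  }
  state
}

#' Resolve label switching in a parameter state
#'
#' Latent class models are invariant under swapping the class labels, which
#' maps `(se, sp, prev)` to `(1 - se, 1 - sp, 1 - prev)` and exchanges the
#' two covariance terms. When a state has `se + sp < 1` for both tests it is
#' relabelled into the conventional mode (`se + sp >= 1`); otherwise it is
#' returned unchanged. The operation is an involution on mirrored pairs.
#'
#' @param state Named numeric vector with entries `se1`, `sp1`, `se2`, `sp2`,
#'   `prev1`...`prevK` and optionally `cov_dpos`, `cov_dneg`.
#' @return The (possibly relabelled) state, with attribute `relabeled`.
#' @export
enforce_identifiability <- function(state) {
  needed <- c("se1", "sp1", "se2", "sp2")
  if (!all(needed %in% names(state))) {
    stop("state must name se1, sp1, se2, sp2", call. = FALSE)
  }
  K <- sum(grepl("^prev[0-9]+$", names(state)))
  dep <- all(c("cov_dpos", "cov_dneg") %in% names(state))
  relabel_if_mirrored(state, K, dep)
}

# Shared sampler engine. `dependence` activates the covariance terms;
# `proposal_sd = 0` switches them off entirely (the model degenerates to
# conditional independence with two constant zero covariance columns).
run_sampler <- function(data, priors, config, dependence, proposal_sd,
                        fixed = list(), allow_single = FALSE) {
  stopifnot(inherits(data, "study_data"), inherits(priors, "prior_set"),
            inherits(config, "mcmc_config"))
  K <- n_populations(data)
  if (length(priors$prevalence) != K) {
    stop("prior set has ", length(priors$prevalence),
         " prevalence priors but data has ", K, " populations", call. = FALSE)
  }
  if (K < 2 && !allow_single && length(fixed) == 0) {
    stop("a single population is not identifiable under the base model; ",
         "fix parameters, use informative priors, or set allow_single = TRUE",
         call. = FALSE)
  }
  N <- as.matrix(data$counts[, c("n11", "n10", "n01", "n00")])
  storage.mode(N) <- "double"
  n_k <- rowSums(N)
  if (any(n_k == 0)) stop("empty population in data", call. = FALSE)

  slots <- prior_slots(priors)
  pr_a <- vapply(slots, `[[`, numeric(1), "alpha")
  pr_b <- vapply(slots, `[[`, numeric(1), "beta")

  dep_active <- dependence && proposal_sd > 0
  par_names <- c("se1", "sp1", "se2", "sp2", paste0("prev", seq_len(K)))
  if (dependence) par_names <- c(par_names, "cov_dpos", "cov_dneg")
  P <- length(par_names)

  # cell layout: (1,1), (1,0), (0,1), (0,0)
  t1_pos <- c(1L, 2L)  # cells where test 1 is positive
  t2_pos <- c(1L, 3L)

  n_keep <- config$n_iterations %/% config$thin
  total_iter <- config$burn_in + config$n_iterations

  chains <- vector("list", config$n_chains)
  acc <- vector("list", config$n_chains)
  relabels <- integer(config$n_chains)

  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch)
    # overdispersed starting values drawn from the priors
    init <- stats::rbeta(4 + K, pr_a, pr_b)
    names(init) <- names(slots)
    se1 <- init[["se1"]]; sp1 <- init[["sp1"]]
    se2 <- init[["se2"]]; sp2 <- init[["sp2"]]
    prev <- init[4 + seq_len(K)]
    for (nm in names(fixed)) {
      assign(nm, fixed[[nm]])
    }
    cp <- 0; cn <- 0

    draws <- matrix(NA_real_, n_keep, P, dimnames = list(NULL, par_names))
    n_prop <- c(se1 = 0, sp1 = 0, se2 = 0, sp2 = 0, cov_dpos = 0, cov_dneg = 0)
    n_acc <- n_prop
    n_relab <- 0L
    kept <- 0L

    for (iter in seq_len(total_iter)) {
      a <- class_cell_probs(se1, se2, cp)
      b <- class_cell_probs(1 - sp1, 1 - sp2, cn)

      # latent true-positive count per population x cell
      pa <- outer(prev, a)                     # K x 4
      pb <- outer(1 - prev, b)
      den <- pa + pb
      W <- ifelse(den > 0, pa / den, 0)
      Y <- matrix(stats::rbinom(K * 4L, as.integer(N), W), K, 4L)

      # prevalence: beta full conditional, exact under both models
      ypos_k <- rowSums(Y)
      if (is.null(fixed$prev)) {
        prev <- stats::rbeta(K, pr_a[4 + seq_len(K)] + ypos_k,
                             pr_b[4 + seq_len(K)] + n_k - ypos_k)
      }

      ypos <- colSums(Y)          # within-class cell counts, latent positives
      mneg <- colSums(N - Y)      # latent negatives

      # accuracy updates; for the dependence model these are MH steps with
      # the independence full conditional as proposal
      upd <- function(cur, s, f, alpha, beta, which_class, slot) {
        prop <- stats::rbeta(1, alpha + s, beta + f)
        if (!dep_active) return(prop)
        if (which_class == "pos") {
          p_old <- class_cell_probs(se1, se2, cp)
          if (slot == 1) p_new <- class_cell_probs(prop, se2, cp)
          else           p_new <- class_cell_probs(se1, prop, cp)
          cnt <- ypos
          bd_new <- covariance_bounds(if (slot == 1) prop else se1,
                                      if (slot == 1) se2 else prop)
          cv <- cp
          bd_old <- covariance_bounds(se1, se2)
        } else {
          p_old <- class_cell_probs(1 - sp1, 1 - sp2, cn)
          if (slot == 1) p_new <- class_cell_probs(1 - prop, 1 - sp2, cn)
          else           p_new <- class_cell_probs(1 - sp1, 1 - prop, cn)
          cnt <- mneg
          bd_new <- covariance_bounds(if (slot == 1) prop else sp1,
                                      if (slot == 1) sp2 else prop)
          cv <- cn
          bd_old <- covariance_bounds(sp1, sp2)
        }
        if (cv < bd_new$lower || cv > bd_new$upper) return(cur)  # infeasible
        # independence kernel that the proposal already accounts for
        marg_old <- if (which_class == "pos") {
          if (slot == 1) c(cur, cur, 1 - cur, 1 - cur) else c(cur, 1 - cur, cur, 1 - cur)
        } else {
          if (slot == 1) c(1 - cur, 1 - cur, cur, cur) else c(1 - cur, cur, 1 - cur, cur)
        }
        marg_new <- if (which_class == "pos") {
          if (slot == 1) c(prop, prop, 1 - prop, 1 - prop) else c(prop, 1 - prop, prop, 1 - prop)
        } else {
          if (slot == 1) c(1 - prop, 1 - prop, prop, prop) else c(1 - prop, prop, 1 - prop, prop)
        }
        logr <- xlogy(cnt, p_new) - xlogy(cnt, p_old) -
          (xlogy(cnt, marg_new) - xlogy(cnt, marg_old)) +
          log(bd_old$upper - bd_old$lower) - log(bd_new$upper - bd_new$lower)
        if (is.nan(logr) || logr == -Inf) return(cur)
        if (logr >= 0) prop
        else if (log(stats::runif(1)) < logr) prop
        else cur
      }

      if (is.null(fixed$se1)) {
        s <- sum(ypos[t1_pos]); f <- sum(ypos[-t1_pos])
        new <- upd(se1, s, f, pr_a[["se1"]], pr_b[["se1"]], "pos", 1)
        if (dep_active) { n_prop["se1"] <- n_prop["se1"] + 1
                          n_acc["se1"] <- n_acc["se1"] + (new != se1) }
        se1 <- new
      }
      if (is.null(fixed$sp1)) {
        s <- sum(mneg[-t1_pos]); f <- sum(mneg[t1_pos])
        new <- upd(sp1, s, f, pr_a[["sp1"]], pr_b[["sp1"]], "neg", 1)
        if (dep_active) { n_prop["sp1"] <- n_prop["sp1"] + 1
                          n_acc["sp1"] <- n_acc["sp1"] + (new != sp1) }
        sp1 <- new
      }
      if (is.null(fixed$se2)) {
        s <- sum(ypos[t2_pos]); f <- sum(ypos[-t2_pos])
        new <- upd(se2, s, f, pr_a[["se2"]], pr_b[["se2"]], "pos", 2)
        if (dep_active) { n_prop["se2"] <- n_prop["se2"] + 1
                          n_acc["se2"] <- n_acc["se2"] + (new != se2) }
        se2 <- new
      }
      if (is.null(fixed$sp2)) {
        s <- sum(mneg[-t2_pos]); f <- sum(mneg[t2_pos])
        new <- upd(sp2, s, f, pr_a[["sp2"]], pr_b[["sp2"]], "neg", 2)
        if (dep_active) { n_prop["sp2"] <- n_prop["sp2"] + 1
                          n_acc["sp2"] <- n_acc["sp2"] + (new != sp2) }
        sp2 <- new
      }

      if (dep_active) {
        # Covariance updates: a reflected Gaussian random walk, mixed (10%
        # of proposals) with an independence draw uniform over the current
        # feasibility interval so the chain can traverse the weakly
        # identified covariance ridge. Both kernels are symmetric, so the
        # acceptance ratio is the within-class likelihood ratio.
        upd_cov <- function(cur, p1, p2, cnt, nm) {
          bd <- covariance_bounds(p1, p2)
          if (bd$upper - bd$lower <= 1e-10) return(0)
          n_prop[nm] <<- n_prop[nm] + 1
          prop <- if (stats::runif(1) < 0.1) {
            stats::runif(1, bd$lower, bd$upper)
          } else {
            reflect_into(cur + stats::rnorm(1, 0, proposal_sd),
                         bd$lower, bd$upper)
          }
          logr <- xlogy(cnt, class_cell_probs(p1, p2, prop)) -
                  xlogy(cnt, class_cell_probs(p1, p2, cur))
          if (!is.nan(logr) &&
              (logr >= 0 || log(stats::runif(1)) < logr)) {
            n_acc[nm] <<- n_acc[nm] + 1
            prop
          } else cur
        }
        cp <- upd_cov(cp, se1, se2, ypos, "cov_dpos")
        cn <- upd_cov(cn, 1 - sp1, 1 - sp2, mneg, "cov_dneg")
      }

      # Marginal slice sweep on the observed-data posterior (see
      # slice_update). Targets include the beta prior; in the dependence
      # model also the conditional-uniform covariance prior normalisation
      # and feasibility of the current covariances.
      obs_ll <- function(v_se1, v_sp1, v_se2, v_sp2, v_prev, v_cp, v_cn) {
        aa <- class_cell_probs(v_se1, v_se2, v_cp)
        bb <- class_cell_probs(1 - v_sp1, 1 - v_sp2, v_cn)
        cells <- outer(v_prev, aa) + outer(1 - v_prev, bb)
        if (any(cells <= 0 & N > 0)) return(-Inf)
        pos <- N > 0
        sum(N[pos] * log(cells[pos]))
      }
      cov_prior_term <- function(p1, p2, cv) {
        bd <- covariance_bounds(p1, p2)
        if (cv < bd$lower || cv > bd$upper) return(-Inf)
        wd <- bd$upper - bd$lower
        if (wd <= 1e-10) 0 else -log(wd)
      }
      for (sweep in 1:2) {
      if (is.null(fixed$se1)) {
        se1 <- slice_update(se1, function(x) {
          lp <- obs_ll(x, sp1, se2, sp2, prev, cp, cn) +
            stats::dbeta(x, pr_a[["se1"]], pr_b[["se1"]], log = TRUE)
          if (dep_active) lp <- lp + cov_prior_term(x, se2, cp)
          lp
        }, 0, 1)
      }
      if (is.null(fixed$sp1)) {
        sp1 <- slice_update(sp1, function(x) {
          lp <- obs_ll(se1, x, se2, sp2, prev, cp, cn) +
            stats::dbeta(x, pr_a[["sp1"]], pr_b[["sp1"]], log = TRUE)
          if (dep_active) lp <- lp + cov_prior_term(x, sp2, cn)
          lp
        }, 0, 1)
      }
      if (is.null(fixed$se2)) {
        se2 <- slice_update(se2, function(x) {
          lp <- obs_ll(se1, sp1, x, sp2, prev, cp, cn) +
            stats::dbeta(x, pr_a[["se2"]], pr_b[["se2"]], log = TRUE)
          if (dep_active) lp <- lp + cov_prior_term(se1, x, cp)
          lp
        }, 0, 1)
      }
      if (is.null(fixed$sp2)) {
        sp2 <- slice_update(sp2, function(x) {
          lp <- obs_ll(se1, sp1, se2, x, prev, cp, cn) +
            stats::dbeta(x, pr_a[["sp2"]], pr_b[["sp2"]], log = TRUE)
          if (dep_active) lp <- lp + cov_prior_term(sp1, x, cn)
          lp
        }, 0, 1)
      }
      if (is.null(fixed$prev)) {
        for (k in seq_len(K)) {
          prev[k] <- slice_update(prev[k], function(x) {
            pv <- prev; pv[k] <- x
            obs_ll(se1, sp1, se2, sp2, pv, cp, cn) +
              stats::dbeta(x, pr_a[[4 + k]], pr_b[[4 + k]], log = TRUE)
          }, 0, 1)
        }
      }
      if (dep_active) {
        bd <- covariance_bounds(se1, se2)
        if (bd$upper - bd$lower > 1e-10) {
          cp <- slice_update(cp, function(x)
            obs_ll(se1, sp1, se2, sp2, prev, x, cn),
            bd$lower, bd$upper, w = 0.05)
        }
        bd <- covariance_bounds(sp1, sp2)
        if (bd$upper - bd$lower > 1e-10) {
          cn <- slice_update(cn, function(x)
            obs_ll(se1, sp1, se2, sp2, prev, cp, x),
            bd$lower, bd$upper, w = 0.05)
        }
      }
      }

      if (config$enforce_identifiability &&
          se1 + sp1 < 1 && se2 + sp2 < 1) {
        # class-label swap: se <-> 1 - sp (likelihood-invariant relabeling)
        tmp1 <- se1; se1 <- 1 - sp1; sp1 <- 1 - tmp1
        tmp2 <- se2; se2 <- 1 - sp2; sp2 <- 1 - tmp2
        prev <- 1 - prev
        tmp <- cp; cp <- cn; cn <- tmp
        n_relab <- n_relab + 1L
      }

      if (iter > config$burn_in &&
          (iter - config$burn_in) %% config$thin == 0) {
        kept <- kept + 1L
        state <- c(se1, sp1, se2, sp2, prev)
        if (dependence) state <- c(state, cp, cn)
        draws[kept, ] <- state
      }
    }

    chains[[ch]] <- draws
    rates <- ifelse(n_prop > 0, n_acc / n_prop, NA_real_)
    acc[[ch]] <- rates
    relabels[ch] <- n_relab
  }

  if (dep_active) {
    r <- unlist(lapply(acc, function(x) x[c("cov_dpos", "cov_dneg")]))
    r <- r[is.finite(r)]
    if (length(r) && (any(r < 0.1) || any(r > 0.6))) {
      warning("Metropolis acceptance rate outside [0.1, 0.6] for a covariance ",
              "term; consider tuning proposal_sd", call. = FALSE)
    }
  }

  structure(list(
    chains = chains,
    par_names = par_names,
    config = config,
    dependence = dependence,
    proposal_sd = if (dependence) proposal_sd else NULL,
    acceptance = acc,
    relabel_count = relabels,
    population_ids = data$counts$population,
    test_names = data$test_names
  ), class = "blcm_draws")
}

# One univariate slice-sampling update (stepping-out and shrinkage, fixed
# width, bounded support). Used on the observed-data posterior after the
# augmentation sweep: the latent-count Gibbs moves alone carry a high
# missing-information fraction (both tests are imperfect, so each
# individual's class is uncertain), which inflates autocorrelation as the
# sample grows; slice moves on the marginal posterior restore near-iid
# mixing while leaving the target distribution unchanged.
slice_update <- function(x0, logf, lower, upper, w = 0.1, m = 50L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) return(x0)
  logy <- f0 - stats::rexp(1)
  u <- stats::runif(1)
  L <- x0 - w * u
  R <- L + w
  J <- floor(m * stats::runif(1))
  Kk <- m - 1 - J
  while (J > 0 && L > lower && logf(L) > logy) { L <- L - w; J <- J - 1 }
  while (Kk > 0 && R < upper && logf(R) > logy) { R <- R + w; Kk <- Kk - 1 }
  L <- max(L, lower)
  R <- min(R, upper)
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) >= logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

# Fold a real number into [lower, upper] by reflection at the boundaries.
reflect_into <- function(x, lower, upper) {
  width <- upper - lower
  if (width <= 0) return(lower)
  while (x < lower || x > upper) {
    if (x < lower) x <- 2 * lower - x
    if (x > upper) x <- 2 * upper - x
  }
  x
}

#' Gibbs sampler for the conditional-independence model
#'
#' Data-augmentation Gibbs sampling of the Hui-Walter model: latent
#' true-positive counts per observed cell from binomial full conditionals,
#' then prevalence and accuracy parameters from conjugate beta full
#' conditionals. Identical inputs (including the seed) give bit-identical
#' draws.
#'
#' @param data A [study_data()] object.
#' @param priors A [prior_set()] with one prevalence prior per population.
#' @param config An [mcmc_config()].
#' @param fixed Named list of parameters to hold fixed (e.g.
#'   `list(se1 = 1, sp1 = 1)`), mainly for validation studies.
#' @param allow_single Permit a single population (requires informative
#'   priors or fixed parameters to be meaningful).
#' @return A `blcm_draws` object: per-chain draw matrices with columns
#'   `se1, sp1, se2, sp2, prev1..prevK`, plus configuration and bookkeeping.
#' @export
gibbs_independence <- function(data, priors, config = mcmc_config(),
                               fixed = list(), allow_single = FALSE) {
  run_sampler(data, priors, config, dependence = FALSE, proposal_sd = 0,
              fixed = fixed, allow_single = allow_single)
}

#' Metropolis-within-Gibbs sampler for the conditional-dependence model
#'
#' Extends [gibbs_independence()] with within-class covariance terms between
#' the two tests. Covariances get uniform priors over their feasibility
#' interval (which moves with the accuracies) and are updated by a reflected
#' Gaussian random walk; accuracy parameters are updated by
#' Metropolis-Hastings with the independence beta full conditional as
#' proposal, so the sampler targets the exact posterior. `proposal_sd = 0`
#' disables the covariance terms: the accuracy and prevalence draws are then
#' bit-identical to [gibbs_independence()] under the same configuration, and
#' both covariance columns are constant zero.
#'
#' @inheritParams gibbs_independence
#' @param proposal_sd Random-walk proposal standard deviation for the
#'   covariance terms (default 0.05). An acceptance rate outside
#'   `[0.1, 0.6]` triggers a tuning warning.
#' @return A `blcm_draws` object with additional columns `cov_dpos`,
#'   `cov_dneg` and per-chain Metropolis acceptance rates.
#' @export
mwg_dependence <- function(data, priors, config = mcmc_config(),
                           proposal_sd = 0.05, fixed = list(),
                           allow_single = FALSE) {
  run_sampler(data, priors, config, dependence = TRUE,
              proposal_sd = proposal_sd, fixed = fixed,
              allow_single = allow_single)
}

#' @export
print.blcm_draws <- function(x, ...) {
  cat("Hui-Walter BLCM posterior draws (",
      if (x$dependence) "conditional dependence" else "conditional independence",
      ")\n", sep = "")
  cat(length(x$chains), "chain(s) x", nrow(x$chains[[1]]), "retained draws;",
      "parameters:", paste(x$par_names, collapse = ", "), "\n")
  invisible(x)
}

#' Pool retained draws across chains
#' @param x A `blcm_draws` object.
#' @param ... Unused.
#' @return Matrix of pooled draws (rows = chain-major draws).
#' @export
as.matrix.blcm_draws <- function(x, ...) {
  do.call(rbind, x$chains)
}

#' Export draws in long format
#'
#' Writes a plain CSV with columns `chain, iteration, parameter, value`, one
#' row per retained draw, so external diagnostic tools can consume the
#' chains.
#'
#' @param draws A `blcm_draws` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(draws, path) {
  stopifnot(inherits(draws, "blcm_draws"))
  long <- do.call(rbind, lapply(seq_along(draws$chains), function(ch) {
    m <- draws$chains[[ch]]
    data.frame(
      chain = ch,
      iteration = rep(seq_len(nrow(m)), times = ncol(m)),
      parameter = rep(colnames(m), each = nrow(m)),
      value = as.vector(m),
      stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
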