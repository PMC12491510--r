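# Beta priors for the probability parameters of the latent class model.

#' Beta prior for a probability parameter
#'
#' @param alpha,beta Positive shape parameters.
#' @param label Optional parameter name (used in printing and reports).
#' @return An object of class `beta_prior`.
#' @examples
#' beta_prior(1, 1, "se1")  # uniform on [0, 1]
#' @export
beta_prior <- function(alpha, beta, label = "") {
  if (!is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0) {
    stop("beta prior shapes must be positive and finite", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, label = as.character(label)),
            class = "beta_prior")
}

#' @export
print.beta_prior <- function(x, ...) {
  cat(sprintf("Beta(%g, %g)%s\n", x$alpha, x$beta,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Prior set for the two-test, K-population latent class model
#'
#' Holds one beta prior for each probability parameter: sensitivity and
#' specificity of each test, and one prevalence per population. Covariance
#' (conditional dependence) terms, when active in the model, receive uniform
#' priors over their feasibility interval and are not parameterised here.
#'
#' @param se1,sp1,se2,sp2 [beta_prior()] objects for test accuracies.
#' @param prevalence List of [beta_prior()] objects, one per population.
#' @return An object of class `prior_set`.
#' @export
prior_set <- function(se1, sp1, se2, sp2, prevalence) {
  all_bp <- c(list(se1, sp1, se2, sp2), prevalence)
  ok <- vapply(all_bp, inherits, logical(1), what = "beta_prior")
  if (!all(ok)) stop("all priors must be beta_prior objects", call. = FALSE)
  structure(list(se1 = se1, sp1 = sp1, se2 = se2, sp2 = sp2,
                 prevalence = prevalence),
            class = "prior_set")
}

#' @export
print.prior_set <- function(x, ...) {
  for (nm in c("se1", "sp1", "se2", "sp2")) {
    cat(sprintf("%5s: Beta(%g, %g)\n", nm, x[[nm]]$alpha, x[[nm]]$beta))
  }
  for (k in seq_along(x$prevalence)) {
    cat(sprintf("prev%d: Beta(%g, %g)\n", k,
                x$prevalence[[k]]$alpha, x$prevalence[[k]]$beta))
  }
  invisible(x)
}

# Flat list of the priors in canonical slot order: se1, sp1, se2, sp2, prev_1..K.
prior_slots <- function(priors) {
  c(list(se1 = priors$se1, sp1 = priors$sp1, se2 = priors$se2, sp2 = priors$sp2),
    stats::setNames(priors$prevalence,
                    paste0("prev", seq_along(priors$prevalence))))
}

#' Minimally informative prior set
#'
#' Returns Beta(1, 1) (uniform) priors for all sensitivity, specificity and
#' prevalence parameters. With two populations this is the study's set of
#' six minimally informative priors. A single population leaves the base
#' model unidentifiable under flat priors, so `n_populations < 2` errors
#' unless explicitly overridden (e.g. when informative priors will replace
#' some slots downstream, or parameters are fixed).
#'
#' @param n_populations Number of populations (>= 2 unless overridden).
#' @param allow_single Set `TRUE` to permit one population.
#' @return A [prior_set()].
#' @examples
#' minimally_informative_priors(2)
#' @export
minimally_informative_priors <- function(n_populations, allow_single = FALSE) {
  if (n_populations < 2 && !allow_single) {
    stop("fewer than 2 populations leaves the model unidentifiable under ",
         "flat priors; pass allow_single = TRUE to override", call. = FALSE)
  }
  prior_set(
    se1 = beta_prior(1, 1, "se1"), sp1 = beta_prior(1, 1, "sp1"),
    se2 = beta_prior(1, 1, "se2"), sp2 = beta_prior(1, 1, "sp2"),
    prevalence = lapply(seq_len(n_populations), function(k)
      beta_prior(1, 1, paste0("prev", k)))
  )
}

#' Elicit a beta prior from a mode and a percentile constraint
#'
#' Finds the beta distribution with the requested interior mode whose
#' cumulative probability at `percentile_value` equals `percentile`. Shapes
#' are constrained to `alpha, beta >= 1` so the mode is interior and unique;
#' the mode relation `beta = 1 + (alpha - 1) (1 - mode) / mode` reduces the
#' search to one dimension, solved by root finding on the beta CDF. Use a
#' `percentile > 0.5` for an upper bound (`percentile_value > mode`) and a
#' `percentile < 0.5` for a lower bound (`percentile_value < mode`).
#'
#' Not every constraint pair is achievable: a beta with both shapes at least
#' 1 never has heavier tails than the uniform, so e.g. requesting 5% of the
#' mass above 0.975 with mode 0.5 is infeasible and errors.
#'
#' @param mode Prior mode, in (0, 1).
#' @param percentile_value The parameter value at which the CDF constraint
#'   applies, in (0, 1).
#' @param percentile The target cumulative probability at `percentile_value`
#'   (default 0.95).
#' @param label Optional parameter name.
#' @return A [beta_prior()] satisfying both constraints to within 1e-6.
#' @examples
#' # "most likely 0.5, 95% sure below 0.8"
#' elicit_beta(mode = 0.5, percentile_value = 0.8, percentile = 0.95)
#' @export
elicit_beta <- function(mode, percentile_value, percentile = 0.95, label = "") {
  if (mode <= 0 || mode >= 1) stop("mode must lie strictly in (0, 1)", call. = FALSE)
  if (percentile_value <= 0 || percentile_value >= 1) {
    stop("percentile_value must lie strictly in (0, 1)", call. = FALSE)
  }
  if (percentile <= 0 || percentile >= 1) {
    stop("percentile must lie strictly in (0, 1)", call. = FALSE)
  }
  upper_tail <- percentile >= 0.5
  if (upper_tail && percentile_value <= mode) {
    stop("for an upper percentile, percentile_value must exceed the mode",
         call. = FALSE)
  }
  if (!upper_tail && percentile_value >= mode) {
    stop("for a lower percentile, percentile_value must lie below the mode",
         call. = FALSE)
  }
  beta_of <- function(a) 1 + (a - 1) * (1 - mode) / mode
  f <- function(a) stats::pbeta(percentile_value, a, beta_of(a)) - percentile
  # Bracket a root on alpha in [1, a_max]; the CDF at the constraint point is
  # continuous in alpha along the fixed-mode ridge.
  a_lo <- 1
  a_hi <- 2
  f_lo <- f(a_lo)
  found <- FALSE
  while (a_hi <= 1e7) {
    if (f_lo * f(a_hi) <= 0) { found <- TRUE; break }
    a_hi <- a_hi * 4
  }
  if (!found) {
    stop("no beta distribution with shapes >= 1 has mode ", mode,
         " and cumulative probability ", percentile, " at ", percentile_value,
         call. = FALSE)
  }
  root <- stats::uniroot(f, c(a_lo, a_hi), tol = 1e-10)$root
  alpha <- root
  beta <- beta_of(alpha)
  fitted_mode <- (alpha - 1) / (alpha + beta - 2)
  if (alpha + beta > 2 && abs(fitted_mode - mode) > 1e-6) {
    stop("internal elicitation failure: mode constraint not met", call. = FALSE)
  }
  if (abs(stats::pbeta(percentile_value, alpha, beta) - percentile) > 1e-6) {
    stop("no beta distribution with shapes >= 1 has mode ", mode,
         " and cumulative probability ", percentile, " at ", percentile_value,
         call. = FALSE)
  }
  beta_prior(alpha, beta, label)
}

#' One-at-a-time prior replacement grid for sensitivity analysis
#'
#' Builds the model configurations of a leave-one-prior-out sensitivity
#' analysis: the i-th returned prior set equals `base` except that its i-th
#' slot (order: se1, sp1, se2, sp2, then prevalences) is replaced by
#' `replacement`. With two populations this yields six configurations, one
#' per prior.
#'
#' @param base A [prior_set()].
#' @param replacement A [beta_prior()] to substitute into each slot in turn.
#' @return A list of [prior_set()] objects, one per slot of `base`, named by
#'   the replaced slot.
#' @export
sensitivity_grid <- function(base, replacement) {
  stopifnot(inherits(base, "prior_set"), inherits(replacement, "beta_prior"))
  slots <- names(prior_slots(base))
  K <- length(base$prevalence)
  out <- lapply(seq_along(slots), function(i) {
    nm <- slots[i]
    b <- base
    repl <- beta_prior(replacement$alpha, replacement$beta, nm)
    if (grepl("^prev", nm)) {
      k <- as.integer(sub("^prev", "", nm))
      b$prevalence[[k]] <- repl
    } else {
      b[[nm]] <- repl
    }
    b
  })
  stats::setNames(out, slots)
}
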