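# Hui-Walter probability model: within-class cell probabilities with optional
# covariance (conditional dependence) terms, multinomial likelihood, and
# predictive values.

#' Diagnostic accuracy of one test
#'
#' @param se,sp Sensitivity and specificity, in `[0, 1]`. Shared across
#'   populations (the Hui-Walter assumption).
#' @return An object of class `test_accuracy`.
#' @export
test_accuracy <- function(se, sp) {
  if (se < 0 || se > 1 || sp < 0 || sp > 1) {
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  }
  structure(list(se = se, sp = sp), class = "test_accuracy")
}

#' Feasibility bounds of a within-class covariance term
#'
#' For two conditionally dependent binary tests whose within-class marginal
#' positive probabilities are `a` and `b`, the covariance between their
#' results is constrained so all four within-class cell probabilities stay in
#' `[0, 1]`:
#' lower = `max(-(1-a)(1-b), -ab)`, upper = `min(a, b) - ab`.
#' Zero is always feasible, so the interval always contains the
#' conditional-independence model.
#'
#' @param a,b Within-class positive probabilities in `[0, 1]` (sensitivities
#'   among the latent positives; one-minus-specificities among negatives).
#' @return List with `lower` and `upper`.
#' @examples
#' covariance_bounds(0.905, 0.730)
#' @export
covariance_bounds <- function(a, b) {
  if (any(c(a, b) < 0) || any(c(a, b) > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  list(lower = max(-(1 - a) * (1 - b), -a * b),
       upper = min(a, b) - a * b)
}

#' Within-class covariance (conditional dependence) terms
#'
#' `cov_dpos` is the covariance of the two tests' results among latent
#' positives, `cov_dneg` among latent negatives. Feasibility against given
#' accuracies is checked by [model_parameters()].
#'
#' @param cov_dpos,cov_dneg Real covariance terms.
#' @return An object of class `dependence_terms`.
#' @export
dependence_terms <- function(cov_dpos = 0, cov_dneg = 0) {
  structure(list(cov_dpos = cov_dpos, cov_dneg = cov_dneg),
            class = "dependence_terms")
}

#' Full parameter set of the latent class model
#'
#' @param test1,test2 [test_accuracy()] objects (test 1 = EDTB slot, test 2 =
#'   OLBI slot by convention).
#' @param prevalence Numeric vector of per-population prevalences in `[0, 1]`.
#' @param dependence Optional [dependence_terms()]; `NULL` means conditional
#'   independence.
#' @return An object of class `model_parameters`.
#' @examples
#' model_parameters(test_accuracy(0.905, 0.822), test_accuracy(0.730, 0.726),
#'                  prevalence = c(0.518, 0.817))
#' @export
model_parameters <- function(test1, test2, prevalence, dependence = NULL) {
  stopifnot(inherits(test1, "test_accuracy"), inherits(test2, "test_accuracy"))
  if (any(prevalence < 0) || any(prevalence > 1)) {
    stop("prevalences must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(dependence)) {
    stopifnot(inherits(dependence, "dependence_terms"))
    bp <- covariance_bounds(test1$se, test2$se)
    if (dependence$cov_dpos < bp$lower - 1e-12 ||
        dependence$cov_dpos > bp$upper + 1e-12) {
      stop(sprintf(
        "cov_dpos = %g violates its feasibility bounds [%g, %g] given se1, se2",
        dependence$cov_dpos, bp$lower, bp$upper), call. = FALSE)
    }
    bn <- covariance_bounds(test1$sp, test2$sp)
    if (dependence$cov_dneg < bn$lower - 1e-12 ||
        dependence$cov_dneg > bn$upper + 1e-12) {
      stop(sprintf(
        "cov_dneg = %g violates its feasibility bounds [%g, %g] given sp1, sp2",
        dependence$cov_dneg, bn$lower, bn$upper), call. = FALSE)
    }
  }
  structure(list(test1 = test1, test2 = test2,
                 prevalence = as.numeric(prevalence),
                 dependence = dependence),
            class = "model_parameters")
}

# Within-class joint cell probabilities over outcomes (1,1),(1,0),(0,1),(0,0)
# for marginal positive probabilities p1, p2 and covariance cv. The sign of
# the covariance contribution is +1 on concordant cells, -1 on discordant.
class_cell_probs <- function(p1, p2, cv = 0) {
  c(p1 * p2 + cv,
    p1 * (1 - p2) - cv,
    (1 - p1) * p2 - cv,
    (1 - p1) * (1 - p2) + cv)
}

#' Marginal cell probabilities of the observed 2x2 table
#'
#' Mixture of the within-class joint distributions of the two test results,
#' weighted by the population's prevalence:
#' `P(t1, t2) = P_k * a(t1, t2) + (1 - P_k) * b(t1, t2)`, where `a` is built
#' from the sensitivities plus `cov_dpos` and `b` from the specificities plus
#' `cov_dneg` (covariances add on concordant outcomes, subtract on
#' discordant ones).
#'
#' @param params A [model_parameters()] object.
#' @param population Population index (into `params$prevalence`).
#' @return Named numeric vector `p11, p10, p01, p00`; non-negative, summing
#'   to 1.
#' @examples
#' p <- model_parameters(test_accuracy(0.905, 0.822), test_accuracy(0.730, 0.726),
#'                       prevalence = c(0.518, 0.817))
#' cell_probabilities(p, 1)
#' @export
cell_probabilities <- function(params, population = 1) {
  stopifnot(inherits(params, "model_parameters"))
  if (population < 1 || population > length(params$prevalence)) {
    stop("population index out of range", call. = FALSE)
  }
  cp <- if (is.null(params$dependence)) 0 else params$dependence$cov_dpos
  cn <- if (is.null(params$dependence)) 0 else params$dependence$cov_dneg
  pk <- params$prevalence[population]
  a <- class_cell_probs(params$test1$se, params$test2$se, cp)
  b <- class_cell_probs(1 - params$test1$sp, 1 - params$test2$sp, cn)
  out <- pk * a + (1 - pk) * b
  # clamp away floating-point dust; true negatives are prevented by the bounds
  out[out < 0 & out > -1e-12] <- 0
  stats::setNames(out, c("p11", "p10", "p01", "p00"))
}

#' Multinomial log-likelihood of study data
#'
#' Sum over populations of the multinomial log-probability of the observed
#' 2x2 cells under [cell_probabilities()]. By default only the kernel
#' `sum n_c log p_c` is returned (the multinomial coefficient does not depend
#' on the parameters); set `kernel = FALSE` to include it. A zero cell
#' probability paired with a positive count yields `-Inf`, not an error.
#'
#' @param params A [model_parameters()] object.
#' @param data A [study_data()] object with as many populations as
#'   `params$prevalence`.
#' @param kernel Drop the multinomial coefficient (default `TRUE`).
#' @return Scalar log-likelihood (possibly `-Inf`).
#' @export
log_likelihood <- function(params, data, kernel = TRUE) {
  stopifnot(inherits(data, "study_data"))
  K <- n_populations(data)
  if (length(params$prevalence) != K) {
    stop("params have ", length(params$prevalence), " prevalences but data has ",
         K, " populations", call. = FALSE)
  }
  total <- 0
  for (k in seq_len(K)) {
    n <- as.numeric(data$counts[k, c("n11", "n10", "n01", "n00")])
    p <- cell_probabilities(params, k)
    if (any(p == 0 & n > 0)) return(-Inf)
    nz <- n > 0
    total <- total + sum(n[nz] * log(p[nz]))
    if (!kernel) {
      total <- total + lgamma(sum(n) + 1) - sum(lgamma(n + 1))
    }
  }
  total
}

#' Positive predictive value
#'
#' `PPV = P * Se / (P * Se + (1 - P)(1 - Sp))`: the probability that an
#' individual testing positive is truly positive, at prevalence `prev`.
#'
#' @param se,sp Test sensitivity and specificity in `[0, 1]`.
#' @param prev Prevalence in `[0, 1]`.
#' @return PPV in `[0, 1]`.
#' @examples
#' ppv(se = 0.905, sp = 0.822, prev = 0.518)  # 0.845 (Belgian population)
#' @export
ppv <- function(se, sp, prev) {
  check_probs(se = se, sp = sp, prev = prev)
  den <- prev * se + (1 - prev) * (1 - sp)
  if (den <= 0) {
    stop("PPV undefined: probability of a positive result is 0", call. = FALSE)
  }
  prev * se / den
}

#' Negative predictive value
#'
#' `NPV = (1 - P) * Sp / (P (1 - Se) + (1 - P) Sp)`: the probability that an
#' individual testing negative is truly negative, at prevalence `prev`.
#'
#' @inheritParams ppv
#' @return NPV in `[0, 1]`.
#' @examples
#' npv(se = 0.905, sp = 0.822, prev = 0.817)  # 0.66 (Swiss population)
#' @export
npv <- function(se, sp, prev) {
  check_probs(se = se, sp = sp, prev = prev)
  den <- prev * (1 - se) + (1 - prev) * sp
  if (den <= 0) {
    stop("NPV undefined: probability of a negative result is 0", call. = FALSE)
  }
  (1 - prev) * sp / den
}

check_probs <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.finite(v) || v < 0 || v > 1) {
      stop("'", nm, "' must lie in [0, 1]", call. = FALSE)
    }
  }
  invisible(TRUE)
}
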