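# Convergence diagnostics and posterior summarisation.

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic two-stage psrf without the sampling-variability degrees-of-freedom
#' correction: `sqrt(((n - 1)/n * W + B/n) / W)` with `W` the mean
#' within-chain variance and `B` the between-chain variance (`n` times the
#' variance of the chain means). Values near 1 indicate the chains have
#' mixed; the study's rule flags parameters with psrf >= 1.05.
#'
#' Degenerate cases: identical constant chains give 1 by convention;
#' constant but distinct chains give `Inf`.
#'
#' @param chains List of numeric vectors (one per chain, equal length >= 2),
#'   or a matrix with one column per chain.
#' @return Scalar psrf.
#' @examples
#' psrf(list(c(1, 2, 3, 4), c(1, 2, 3, 4)))  # sqrt(3/4)
#' @export
psrf <- function(chains) {
  if (is.matrix(chains)) chains <- asplit(chains, 2)
  m <- length(chains)
  if (m < 2) stop("psrf needs at least 2 chains", call. = FALSE)
  n <- unique(lengths(chains))
  if (length(n) != 1 || n < 2) {
    stop("chains must share a common length >= 2", call. = FALSE)
  }
  W <- mean(vapply(chains, stats::var, numeric(1)))
  B <- n * stats::var(vapply(chains, mean, numeric(1)))
  if (W == 0) {
    return(if (B == 0) 1 else Inf)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Sample autocorrelation of one chain at lags 0..lag_max (demeaned,
# normalised by lag-0 covariance). Returns zeros for constant chains.
sample_autocorr <- function(x, lag_max) {
  n <- length(x)
  x <- x - mean(x)
  c0 <- sum(x^2) / n
  if (c0 == 0) return(rep(0, lag_max + 1))
  vapply(0:lag_max, function(l) {
    sum(x[seq_len(n - l)] * x[seq_len(n - l) + l]) / n / c0
  }, numeric(1))
}

#' Effective sample size
#'
#' `ESS = N / (1 + 2 * sum(rho_t))`, with the autocorrelation sum truncated
#' by the initial monotone positive sequence rule (consecutive lag-pair sums
#' are kept while positive and enforced non-increasing). With several chains
#' the autocorrelations are computed per chain (each demeaned by its own
#' mean) and averaged, and `N` is the total retained draw count. The result
#' is capped at 1.5 x N (slightly anticorrelated chains can exceed N) and is
#' 0 for constant chains.
#'
#' @param chains Numeric vector (one chain), list of numeric vectors, or
#'   matrix with one column per chain.
#' @return Scalar effective sample size.
#' @export
effective_sample_size <- function(chains) {
  if (is.numeric(chains) && !is.matrix(chains)) chains <- list(chains)
  if (is.matrix(chains)) chains <- asplit(chains, 2)
  n <- unique(lengths(chains))
  if (length(n) != 1) stop("chains must share a common length", call. = FALSE)
  if (n < 10) stop("need at least 10 draws per chain", call. = FALSE)
  N <- n * length(chains)
  if (all(vapply(chains, function(x) stats::var(x) == 0, logical(1)))) {
    return(0)
  }
  # adaptively extend the lag window until the truncation rule fires
  lag_max <- min(n - 1, 128L)
  repeat {
    rho <- Reduce(`+`, lapply(chains, sample_autocorr, lag_max = lag_max)) /
      length(chains)
    # paired sums Gamma_m = rho_{2m} + rho_{2m+1}
    n_pairs <- (lag_max + 1) %/% 2
    gam <- rho[2 * seq_len(n_pairs) - 1] + rho[2 * seq_len(n_pairs)]
    neg <- which(gam <= 0)
    if (length(neg) > 0 || lag_max >= n - 1) {
      M <- if (length(neg)) neg[1] - 1 else n_pairs
      break
    }
    lag_max <- min(n - 1, lag_max * 4L)
  }
  if (M >= 1) gam_kept <- cummin(gam[seq_len(M)]) else gam_kept <- numeric(0)
  tau <- max(2 * sum(gam_kept) - 1, .Machine$double.eps)
  min(N / tau, 1.5 * N)
}

#' Posterior summary of latent class model draws
#'
#' Pooled-chain posterior median and equal-tailed 95% credible interval per
#' parameter (quantiles by linear interpolation of order statistics), with
#' the Gelman-Rubin statistic and effective sample size alongside — the
#' layout of a standard BLCM results table.
#'
#' @param draws A `blcm_draws` object.
#' @param prob Credible mass of the equal-tailed interval (default 0.95).
#' @return A data.frame of class `blcm_summary` with columns `parameter`,
#'   `estimate` (median), `lower95`, `upper95`, `ess`, `psrf`.
#' @export
summarize_draws <- function(draws, prob = 0.95) {
  stopifnot(inherits(draws, "blcm_draws"))
  pooled <- as.matrix(draws)
  if (nrow(pooled) == 0) stop("no retained draws", call. = FALSE)
  alpha <- (1 - prob) / 2
  multi <- length(draws$chains) >= 2
  rows <- lapply(draws$par_names, function(p) {
    per_chain <- lapply(draws$chains, function(m) m[, p])
    x <- pooled[, p]
    q <- stats::quantile(x, c(alpha, 0.5, 1 - alpha), names = FALSE, type = 7)
    data.frame(
      parameter = p,
      estimate = q[2], lower95 = q[1], upper95 = q[3],
      ess = effective_sample_size(per_chain),
      psrf = if (multi) psrf(per_chain) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("blcm_summary", "data.frame")
  out
}

#' @export
print.blcm_summary <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Select between the independence and dependence models
#'
#' The study's rule: fit the conditional-dependence model and keep the
#' dependence terms only if warranted — the conditional-independence model
#' is selected when the 95% credible intervals of both within-class
#' covariance terms contain 0 (closed intervals, endpoints inclusive);
#' otherwise the dependence model is selected.
#'
#' @param summary_dep A `blcm_summary` of a dependence-model fit (must
#'   contain rows `cov_dpos` and `cov_dneg`).
#' @return `"independence"` or `"dependence"`.
#' @export
select_model <- function(summary_dep) {
  stopifnot(inherits(summary_dep, "data.frame"))
  need <- c("cov_dpos", "cov_dneg")
  if (!all(need %in% summary_dep$parameter)) {
    stop("summary lacks covariance parameters cov_dpos / cov_dneg", call. = FALSE)
  }
  rows <- summary_dep[summary_dep$parameter %in% need, ]
  includes0 <- rows$lower95 <= 0 & rows$upper95 >= 0
  if (all(includes0)) "independence" else "dependence"
}

#' Convergence report against the study thresholds
#'
#' @param summary A `blcm_summary`.
#' @param psrf_max Maximum acceptable Gelman-Rubin statistic (default 1.05).
#' @param ess_min Minimum acceptable effective sample size (default 1000).
#' @return A data.frame with per-parameter psrf, ess and a `converged` flag;
#'   attribute `converged` gives the overall verdict and `failing` the
#'   offending parameter names.
#' @export
convergence_report <- function(summary, psrf_max = 1.05, ess_min = 1000) {
  stopifnot(inherits(summary, "data.frame"))
  ok <- (is.na(summary$psrf) | summary$psrf < psrf_max) & summary$ess > ess_min
  out <- data.frame(parameter = summary$parameter, psrf = summary$psrf,
                    ess = summary$ess, converged = ok,
                    stringsAsFactors = FALSE)
  attr(out, "converged") <- all(ok)
  attr(out, "failing") <- summary$parameter[!ok]
  out
}

#' Export autocorrelation series for plotting
#'
#' @param draws A `blcm_draws` object.
#' @param lag_max Largest lag to report.
#' @return Long data.frame with columns `chain`, `parameter`, `lag`, `acf`.
#' @export
autocorrelation_table <- function(draws, lag_max = 50) {
  stopifnot(inherits(draws, "blcm_draws"))
  do.call(rbind, lapply(seq_along(draws$chains), function(ch) {
    m <- draws$chains[[ch]]
    do.call(rbind, lapply(colnames(m), function(p) {
      data.frame(chain = ch, parameter = p, lag = 0:lag_max,
                 acf = sample_autocorr(m[, p], lag_max),
                 stringsAsFactors = FALSE)
    }))
  }))
}
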