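# End-to-end study pipeline: fit both model variants, select by the
# covariance credible intervals, summarise, compute predictive values, and
# write a machine-readable results bundle.

#' Configuration of a full study run
#'
#' Exactly one of `data` (observed counts) or `scenario` (a synthetic
#' [scenario_spec()]) must be supplied.
#'
#' @param data A [study_data()] object, or a path to a counts CSV/JSON file.
#' @param scenario A [scenario_spec()] to simulate instead of observed data.
#' @param priors A [prior_set()]; default: minimally informative (uniform)
#'   priors for all six parameters of a two-population study.
#' @param mcmc An [mcmc_config()]; defaults follow the study protocol.
#' @param pv_test Which test (1 or 2) the headline predictive values are
#'   computed for (default 1, the clinician-rated instrument).
#' @param psrf_max,ess_min Convergence thresholds (defaults 1.05 and 1000).
#' @param proposal_sd Random-walk proposal sd for the dependence fit.
#' @param fit_dependence Also fit the conditional-dependence model and apply
#'   the selection rule (default `TRUE`); when `FALSE` the independence
#'   model is selected outright.
#' @return An object of class `run_config`.
#' @export
run_config <- function(data = NULL, scenario = NULL,
                       priors = NULL, mcmc = mcmc_config(),
                       pv_test = 1, psrf_max = 1.05, ess_min = 1000,
                       proposal_sd = 0.05, fit_dependence = TRUE) {
  if (is.null(data) == is.null(scenario)) {
    stop("supply exactly one of 'data' or 'scenario'", call. = FALSE)
  }
  if (!is.null(data) && is.character(data)) data <- read_counts(data)
  if (!is.null(data)) stopifnot(inherits(data, "study_data"))
  if (!is.null(scenario)) stopifnot(inherits(scenario, "scenario_spec"))
  if (!pv_test %in% c(1, 2)) stop("pv_test must be 1 or 2", call. = FALSE)
  structure(list(data = data, scenario = scenario, priors = priors,
                 mcmc = mcmc, pv_test = as.integer(pv_test),
                 psrf_max = psrf_max, ess_min = ess_min,
                 proposal_sd = proposal_sd,
                 fit_dependence = isTRUE(fit_dependence)),
            class = "run_config")
}

#' Run the full latent class analysis pipeline
#'
#' Resolves the input data (simulating it if a scenario is configured), fits
#' the conditional-dependence and conditional-independence models, applies
#' the credible-interval selection rule for the covariance terms, summarises
#' the selected fit, checks convergence against the configured thresholds,
#' and computes per-population predictive values for the designated test
#' from the posterior point estimates.
#'
#' @param config A [run_config()].
#' @return A list of class `blcm_report`: `data`, `selected` ("independence"
#'   or "dependence"), `summary` (selected model), `summary_independence`,
#'   `summary_dependence`, `draws` (selected model), `predictive_values`
#'   (data.frame), `convergence` (see [convergence_report()]) and
#'   `converged` flag.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  data <- if (!is.null(config$data)) config$data
          else simulate_study(config$scenario)$data
  K <- n_populations(data)
  priors <- if (!is.null(config$priors)) config$priors
            else minimally_informative_priors(K)
  if (length(priors$prevalence) != K) {
    stop("prior set does not match the number of populations", call. = FALSE)
  }

  fit_ind <- gibbs_independence(data, priors, config$mcmc)
  sum_ind <- summarize_draws(fit_ind)
  if (config$fit_dependence) {
    fit_dep <- mwg_dependence(data, priors, config$mcmc,
                              proposal_sd = config$proposal_sd)
    sum_dep <- summarize_draws(fit_dep)
    selected <- select_model(sum_dep)
  } else {
    fit_dep <- NULL
    sum_dep <- NULL
    selected <- "independence"
  }

  fit_sel <- if (selected == "independence") fit_ind else fit_dep
  sum_sel <- if (selected == "independence") sum_ind else sum_dep

  conv <- convergence_report(sum_sel, config$psrf_max, config$ess_min)

  est <- stats::setNames(sum_sel$estimate, sum_sel$parameter)
  se <- est[[paste0("se", config$pv_test)]]
  sp <- est[[paste0("sp", config$pv_test)]]
  pv <- do.call(rbind, lapply(seq_len(K), function(k) {
    prev <- est[[paste0("prev", k)]]
    data.frame(population = data$counts$population[k],
               test = data$test_names[config$pv_test],
               prevalence = prev,
               ppv = ppv(se, sp, prev),
               npv = npv(se, sp, prev),
               stringsAsFactors = FALSE)
  }))

  structure(list(
    data = data,
    selected = selected,
    summary = sum_sel,
    summary_independence = sum_ind,
    summary_dependence = sum_dep,
    draws = fit_sel,
    predictive_values = pv,
    convergence = conv,
    converged = attr(conv, "converged"),
    failing = attr(conv, "failing"),
    config = config
  ), class = "blcm_report")
}

#' @export
print.blcm_report <- function(x, ...) {
  cat("Hui-Walter BLCM study report\n")
  cat("Selected model:", x$selected, "\n\n")
  print(x$summary)
  cat("\nPredictive values (", x$predictive_values$test[1], "):\n", sep = "")
  print(x$predictive_values, row.names = FALSE)
  cat("\nConverged:", x$converged,
      if (!x$converged) paste0(" (failing: ",
                               paste(x$failing, collapse = ", "), ")") else "",
      "\n")
  invisible(x)
}

#' Write a results bundle to a directory
#'
#' Writes `summary.csv` (results-table layout: parameter, estimate, 95%
#' interval, ess, psrf), `convergence.csv`, `predictive_values.csv`,
#' `draws.csv` (long format) and `report.json`. The JSON mirrors every
#' summary number at full precision, so re-reading it reproduces them
#' bit-exactly.
#'
#' @param report A `blcm_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path of `report.json`.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "blcm_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(report$summary),
                   file.path(dir, "summary.csv"), row.names = FALSE)
  utils::write.csv(report$convergence,
                   file.path(dir, "convergence.csv"), row.names = FALSE)
  utils::write.csv(report$predictive_values,
                   file.path(dir, "predictive_values.csv"), row.names = FALSE)
  write_draws(report$draws, file.path(dir, "draws.csv"))
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(list(
    selected = report$selected,
    converged = report$converged,
    failing = report$failing,
    summary = as.data.frame(report$summary),
    summary_independence = as.data.frame(report$summary_independence),
    summary_dependence = if (!is.null(report$summary_dependence))
      as.data.frame(report$summary_dependence) else NULL,
    predictive_values = report$predictive_values,
    convergence = report$convergence
  ), json_path, auto_unbox = TRUE, digits = I(17))
  invisible(json_path)
}

#' Re-read a results bundle JSON
#'
#' @param path Path to a `report.json` written by [write_report()].
#' @return The parsed list, with data.frame components restored.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' One-at-a-time prior sensitivity analysis
#'
#' Refits the selected pipeline once per prior slot (se1, sp1, se2, sp2 and
#' each prevalence), each time replacing that single prior with
#' `replacement`, and tabulates the resulting point estimates and intervals
#' next to the base fit, plus each refit's largest absolute deviation in
#' point estimate from base.
#'
#' @param config A [run_config()] for the base analysis (two-population
#'   data; the dependence stage is skipped — sensitivity is assessed on the
#'   independence model, as in the main analysis after selection).
#' @param replacement A [beta_prior()] substituted into each slot in turn
#'   (default Beta(2, 1)).
#' @return A list of class `blcm_sensitivity` with `base` (summary),
#'   `refits` (one summary per replaced slot), and `table`: one row per
#'   refit with the replaced slot, its estimates, and `max_abs_delta`.
#' @export
run_sensitivity <- function(config, replacement = beta_prior(2, 1)) {
  stopifnot(inherits(config, "run_config"))
  data <- if (!is.null(config$data)) config$data
          else simulate_study(config$scenario)$data
  K <- n_populations(data)
  base_priors <- if (!is.null(config$priors)) config$priors
                 else minimally_informative_priors(K)
  grid <- sensitivity_grid(base_priors, replacement)

  base_fit <- gibbs_independence(data, base_priors, config$mcmc)
  base_sum <- summarize_draws(base_fit)
  base_est <- stats::setNames(base_sum$estimate, base_sum$parameter)

  refits <- lapply(grid, function(pr) {
    summarize_draws(gibbs_independence(data, pr, config$mcmc))
  })

  table <- do.call(rbind, lapply(names(refits), function(slot) {
    s <- refits[[slot]]
    est <- stats::setNames(s$estimate, s$parameter)
    common <- intersect(names(est), names(base_est))
    wide <- as.data.frame(as.list(est))
    cbind(data.frame(replaced = slot, stringsAsFactors = FALSE), wide,
          data.frame(max_abs_delta = max(abs(est[common] - base_est[common]))))
  }))
  rownames(table) <- NULL
  structure(list(base = base_sum, refits = refits, table = table,
                 replacement = replacement),
            class = "blcm_sensitivity")
}

#' @export
print.blcm_sensitivity <- function(x, digits = 3, ...) {
  cat(sprintf("Prior sensitivity analysis: replacement Beta(%g, %g), %d refits\n",
              x$replacement$alpha, x$replacement$beta, nrow(x$table)))
  df <- x$table
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Read a run configuration from YAML or JSON
#'
#' The file may contain `data` (path to counts), `priors` (per-slot
#' `{alpha, beta}` or `{mode, percentile_value, percentile}`), `mcmc`
#' (`n_chains`, `burn_in`, `n_iterations`, `seed`, `thin`) and report
#' options (`pv_test`, `psrf_max`, `ess_min`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  data <- if (!is.null(obj$data)) read_counts(obj$data) else NULL
  K <- if (!is.null(data)) n_populations(data) else 2L
  priors <- NULL
  if (!is.null(obj$priors)) {
    mk <- function(spec, label) {
      if (!is.null(spec$alpha)) beta_prior(spec$alpha, spec$beta, label)
      else elicit_beta(spec$mode, spec$percentile_value,
                       spec$percentile %||% 0.95, label)
    }
    prev_specs <- obj$priors[grepl("^prev", names(obj$priors))]
    priors <- prior_set(
      se1 = mk(obj$priors$se1, "se1"), sp1 = mk(obj$priors$sp1, "sp1"),
      se2 = mk(obj$priors$se2, "se2"), sp2 = mk(obj$priors$sp2, "sp2"),
      prevalence = lapply(seq_len(K), function(k)
        mk(prev_specs[[paste0("prev", k)]], paste0("prev", k)))
    )
  }
  m <- obj$mcmc %||% list()
  mcmc <- mcmc_config(
    n_chains = m$n_chains %||% 2, burn_in = m$burn_in %||% 5000,
    n_iterations = m$n_iterations %||% 10000, seed = m$seed %||% 1,
    thin = m$thin %||% 1
  )
  run_config(data = data, priors = priors, mcmc = mcmc,
             pv_test = obj$pv_test %||% 1,
             psrf_max = obj$psrf_max %||% 1.05,
             ess_min = obj$ess_min %||% 1000)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
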