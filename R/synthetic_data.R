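# Synthetic two-test, K-population datasets with known truth, emulating the
# burnout screening study design (two populations of 100 and 42 patients,
# clinician-rated EDTB and self-reported OLBI dichotomized at >44).

#' Simulation scenario with known truth
#'
#' Defaults reproduce the study conditions: populations of 100 (Belgian) and
#' 42 (Swiss) individuals, EDTB sensitivity/specificity 0.905/0.822, OLBI
#' 0.730/0.726, burnout prevalences 0.518 and 0.817, conditionally
#' independent tests (both covariances 0).
#'
#' @param sizes Positive integer population sizes.
#' @param params A [model_parameters()] object with one prevalence per
#'   population; its `dependence` slot, when present, induces within-class
#'   correlation between the two tests.
#' @param seed Integer seed; the same spec always yields the same dataset.
#' @param emit_olbi_scores Also draw an integer OLBI total score (16-64)
#'   consistent with each record's binary OLBI result.
#' @param population_ids Population labels.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(sizes = c(100, 42),
                          params = study_truth(),
                          seed = 1,
                          emit_olbi_scores = FALSE,
                          population_ids = NULL) {
  if (any(sizes < 1) || any(sizes != round(sizes))) {
    stop("population sizes must be positive integers", call. = FALSE)
  }
  stopifnot(inherits(params, "model_parameters"))
  if (length(params$prevalence) != length(sizes)) {
    stop("need one prevalence per population size", call. = FALSE)
  }
  if (is.null(population_ids)) {
    population_ids <- if (length(sizes) == 2) c("Belgian", "Swiss")
                      else paste0("pop", seq_along(sizes))
  }
  structure(list(sizes = as.integer(sizes), params = params,
                 seed = as.integer(seed),
                 emit_olbi_scores = isTRUE(emit_olbi_scores),
                 population_ids = as.character(population_ids)),
            class = "scenario_spec")
}

#' Study-design true parameter values
#'
#' The point estimates of the motivating burnout study, used as simulation
#' truth: EDTB 0.905/0.822, OLBI 0.730/0.726, prevalences 0.518 (Belgian)
#' and 0.817 (Swiss).
#'
#' @param cov_dpos,cov_dneg Optional within-class covariances (default 0:
#'   conditional independence).
#' @return A [model_parameters()] object.
#' @export
study_truth <- function(cov_dpos = 0, cov_dneg = 0) {
  dep <- if (cov_dpos != 0 || cov_dneg != 0) {
    dependence_terms(cov_dpos, cov_dneg)
  } else NULL
  model_parameters(test_accuracy(0.905, 0.822), test_accuracy(0.730, 0.726),
                   prevalence = c(0.518, 0.817), dependence = dep)
}

#' Simulate a two-test study with known truth
#'
#' For each individual, latent status is Bernoulli(prevalence of their
#' population); the joint test pattern is then drawn from the within-class
#' bivariate Bernoulli defined by the sensitivities (latent positives) or
#' specificities (latent negatives) plus the corresponding covariance term.
#'
#' @param spec A [scenario_spec()].
#' @return A list of class `blcm_simulation` with components `data` (a
#'   [study_data()]), `records` (individual-level data.frame with columns
#'   `population`, `latent`, `test1`, `test2` and optionally `olbi_score`)
#'   and `truth` (the generating scenario, a self-describing manifest).
#' @examples
#' sim <- simulate_study(scenario_spec(seed = 7))
#' sim$data
#' @export
simulate_study <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  p <- spec$params
  cp <- if (is.null(p$dependence)) 0 else p$dependence$cov_dpos
  cn <- if (is.null(p$dependence)) 0 else p$dependence$cov_dneg
  apos <- class_cell_probs(p$test1$se, p$test2$se, cp)
  aneg <- class_cell_probs(1 - p$test1$sp, 1 - p$test2$sp, cn)
  # cells (1,1), (1,0), (0,1), (0,0)
  t1_of_cell <- c(1L, 1L, 0L, 0L)
  t2_of_cell <- c(1L, 0L, 1L, 0L)
  recs <- lapply(seq_along(spec$sizes), function(k) {
    n <- spec$sizes[k]
    latent <- stats::rbinom(n, 1L, p$prevalence[k])
    cell <- integer(n)
    n_pos <- sum(latent == 1)
    if (n_pos > 0) cell[latent == 1] <- sample.int(4L, n_pos, replace = TRUE, prob = apos)
    if (n_pos < n) cell[latent == 0] <- sample.int(4L, n - n_pos, replace = TRUE, prob = aneg)
    data.frame(population = spec$population_ids[k],
               latent = latent,
               test1 = t1_of_cell[cell],
               test2 = t2_of_cell[cell],
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, recs)
  if (spec$emit_olbi_scores) {
    records <- simulate_olbi_scores(records)
  }
  structure(list(
    data = tabulate_records(records),
    records = records,
    truth = spec
  ), class = "blcm_simulation")
}

#' Attach OLBI total scores consistent with binary results
#'
#' Draws an integer OLBI score for each record, uniform on 45-64 for
#' positives and on 16-44 for negatives, so that [dichotomize_olbi()]
#' reproduces the binary result exactly. Only the dichotomy enters the
#' latent class model; the scores exist so individual-level pipelines
#' (score -> dichotomy -> tabulation) can be exercised end to end.
#'
#' @param records Data.frame with a binary `test2` column.
#' @return `records` with an added integer `olbi_score` column.
#' @export
simulate_olbi_scores <- function(records) {
  stopifnot(is.data.frame(records), "test2" %in% names(records))
  n <- nrow(records)
  pos <- records$test2 == 1
  score <- integer(n)
  score[pos] <- sample(45:64, sum(pos), replace = TRUE)
  score[!pos] <- sample(16:44, sum(!pos), replace = TRUE)
  records$olbi_score <- score
  records
}

#' Write a simulation and its truth manifest to disk
#'
#' @param sim A `blcm_simulation`.
#' @param dir Output directory (created if needed).
#' @param stem File stem (default `"synthetic"`).
#' @return Invisibly, the paths written: counts CSV, records CSV and a JSON
#'   truth manifest recording sizes, true parameters and seed.
#' @export
write_simulation <- function(sim, dir, stem = "synthetic") {
  stopifnot(inherits(sim, "blcm_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts_path <- file.path(dir, paste0(stem, "_counts.csv"))
  records_path <- file.path(dir, paste0(stem, "_records.csv"))
  manifest_path <- file.path(dir, paste0(stem, "_manifest.json"))
  write_counts(sim$data, counts_path)
  utils::write.csv(sim$records, records_path, row.names = FALSE, quote = FALSE)
  spec <- sim$truth
  p <- spec$params
  jsonlite::write_json(list(
    sizes = spec$sizes,
    population_ids = spec$population_ids,
    seed = spec$seed,
    truth = list(
      se1 = p$test1$se, sp1 = p$test1$sp,
      se2 = p$test2$se, sp2 = p$test2$sp,
      prevalence = p$prevalence,
      cov_dpos = if (is.null(p$dependence)) 0 else p$dependence$cov_dpos,
      cov_dneg = if (is.null(p$dependence)) 0 else p$dependence$cov_dneg
    )
  ), manifest_path, auto_unbox = TRUE, digits = I(17))
  invisible(c(counts = counts_path, records = records_path,
              manifest = manifest_path))
}
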