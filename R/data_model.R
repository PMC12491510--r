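# Data structures for cross-classified two-test results.
#
# Cell index convention, used everywhere in the package:
#   first index  = test 1 (EDTB) result, second index = test 2 (OLBI) result,
#   1 = positive. Cells are always ordered (1,1), (1,0), (0,1), (0,0).

.CELL_NAMES <- c("n11", "n10", "n01", "n00")

#' Cross-tabulated two-test results for one population
#'
#' Bundles the four cells of the 2x2 cross-classification of two binary
#' diagnostic test results observed in a single population. The first index
#' is the test 1 result, the second the test 2 result, `1` meaning positive,
#' so `n10` counts individuals positive on test 1 and negative on test 2.
#'
#' @param population_id Character label identifying the population.
#' @param n11,n10,n01,n00 Non-negative integer counts.
#' @return An object of class `population_counts`: a named list with the
#'   population label and the four counts.
#' @examples
#' population_counts("Belgian", n11 = 36, n10 = 11, n01 = 9, n00 = 44)
#' @export
population_counts <- function(population_id, n11, n10, n01, n00) {
  counts <- c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts n11, n10, n01, n00 must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) < 1) {
    stop("population '", population_id, "' has no observations (total count 0)",
         call. = FALSE)
  }
  structure(
    list(population_id = as.character(population_id),
         n11 = as.integer(n11), n10 = as.integer(n10),
         n01 = as.integer(n01), n00 = as.integer(n00)),
    class = "population_counts"
  )
}

#' @export
print.population_counts <- function(x, ...) {
  cat("Population", x$population_id, ": ",
      paste(sprintf("%s=%d", .CELL_NAMES, unlist(x[.CELL_NAMES])), collapse = " "),
      " (n=", sum(unlist(x[.CELL_NAMES])), ")\n", sep = "")
  invisible(x)
}

#' Multi-population study data for two diagnostic tests
#'
#' The observed data of a Hui-Walter design: the 2x2 cross-tabulation of two
#' binary test results in each of K populations. At least two populations
#' are required for the base (conditional independence) model to be
#' identifiable without informative priors.
#'
#' @param populations List of [population_counts()] objects, in study order.
#' @param test_names Character vector of length 2 naming test 1 and test 2.
#' @return An object of class `study_data` with components `counts` (a
#'   data.frame with columns `population`, `n11`, `n10`, `n01`, `n00`) and
#'   `test_names`.
#' @examples
#' study_data(list(
#'   population_counts("Belgian", 30, 17, 12, 41),
#'   population_counts("Swiss", 25, 9, 4, 4)
#' ))
#' @export
study_data <- function(populations, test_names = c("EDTB", "OLBI")) {
  if (!is.list(populations) || length(populations) < 1) {
    stop("'populations' must be a non-empty list of population_counts", call. = FALSE)
  }
  ok <- vapply(populations, inherits, logical(1), what = "population_counts")
  if (!all(ok)) stop("every element of 'populations' must be a population_counts",
                     call. = FALSE)
  ids <- vapply(populations, `[[`, character(1), "population_id")
  if (anyDuplicated(ids)) {
    stop("population ids must be unique; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (length(test_names) != 2) stop("exactly two tests are modelled", call. = FALSE)
  counts <- data.frame(
    population = ids,
    n11 = vapply(populations, `[[`, integer(1), "n11"),
    n10 = vapply(populations, `[[`, integer(1), "n10"),
    n01 = vapply(populations, `[[`, integer(1), "n01"),
    n00 = vapply(populations, `[[`, integer(1), "n00"),
    stringsAsFactors = FALSE
  )
  structure(list(counts = counts, test_names = as.character(test_names)),
            class = "study_data")
}

#' @export
print.study_data <- function(x, ...) {
  cat("Two-test study data (", x$test_names[1], " x ", x$test_names[2], "), ",
      nrow(x$counts), " population(s)\n", sep = "")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Number of populations in a study_data object
#' @param data A `study_data` object.
#' @return Integer count of populations.
#' @export
n_populations <- function(data) {
  stopifnot(inherits(data, "study_data"))
  nrow(data$counts)
}

#' Dichotomize an OLBI total score
#'
#' The Oldenburg Burnout Inventory total score ranges from 16 to 64 (16 items
#' scored 1-4). Scores strictly greater than 44 are classified as
#' high-severity burnout (positive); a score of exactly 44 is negative.
#'
#' @param score Integer vector of OLBI total scores in `[16, 64]`.
#' @return Integer vector of 0/1 results, 1 = positive.
#' @examples
#' dichotomize_olbi(c(16, 44, 45, 64))  # 0 0 1 1
#' @export
dichotomize_olbi <- function(score) {
  if (any(!is.finite(score)) || any(score < 16 | score > 64)) {
    stop("OLBI scores must lie in the admissible range [16, 64]", call. = FALSE)
  }
  as.integer(score > 44)
}

#' Cross-tabulate individual-level records into study data
#'
#' Resolves each record's test 2 result (directly, or from an OLBI score via
#' [dichotomize_olbi()]) and tabulates the 2x2 cells per population.
#' Populations appear in the output in order of first appearance.
#'
#' @param records A data.frame with columns `population`, `test1` (0/1) and
#'   either `test2` (0/1) or `olbi_score` (integer 16-64). When both are
#'   present `test2` wins. `edtb` and `olbi` are accepted as aliases for
#'   `test1` and `test2`.
#' @param test_names Passed to [study_data()].
#' @return A [study_data()] object.
#' @export
tabulate_records <- function(records, test_names = c("EDTB", "OLBI")) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("no records to tabulate", call. = FALSE)
  }
  # accept instrument-named columns as aliases for the positional ones
  alias <- c(edtb = "test1", olbi = "test2")
  for (a in names(alias)) {
    if (a %in% names(records) && !alias[[a]] %in% names(records)) {
      names(records)[names(records) == a] <- alias[[a]]
    }
  }
  if (!all(c("population", "test1") %in% names(records))) {
    stop("records need columns 'population' and 'test1' (or 'edtb')",
         call. = FALSE)
  }
  t2 <- rep(NA_integer_, nrow(records))
  if ("test2" %in% names(records)) t2 <- as.integer(records$test2)
  if ("olbi_score" %in% names(records)) {
    need <- is.na(t2) & !is.na(records$olbi_score)
    if (any(need)) t2[need] <- dichotomize_olbi(records$olbi_score[need])
  }
  if (anyNA(t2)) {
    stop("record(s) ", paste(utils::head(which(is.na(t2)), 5), collapse = ", "),
         " have no resolvable test 2 result (need 'test2' or 'olbi_score')",
         call. = FALSE)
  }
  t1 <- as.integer(records$test1)
  if (any(!t1 %in% c(0L, 1L)) || any(!t2 %in% c(0L, 1L))) {
    stop("test results must be binary 0/1", call. = FALSE)
  }
  pops <- unique(as.character(records$population))
  out <- lapply(pops, function(p) {
    i <- records$population == p
    population_counts(
      p,
      n11 = sum(t1[i] == 1 & t2[i] == 1),
      n10 = sum(t1[i] == 1 & t2[i] == 0),
      n01 = sum(t1[i] == 0 & t2[i] == 1),
      n00 = sum(t1[i] == 0 & t2[i] == 0)
    )
  })
  study_data(out, test_names = test_names)
}

#' Read cross-tabulated study data from CSV or JSON
#'
#' CSV files must be comma-separated UTF-8 with a header row and columns
#' `population`, `n11`, `n10`, `n01`, `n00` (cell convention: first index =
#' test 1 result, 1 = positive). The JSON mirror is an object with fields
#' `test_names` and `populations` (array of objects with the same fields).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return A [study_data()] object.
#' @seealso [write_counts()]
#' @export
read_counts <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as.data.frame(obj$populations, stringsAsFactors = FALSE)
    test_names <- if (!is.null(obj$test_names)) obj$test_names else c("EDTB", "OLBI")
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    test_names <- c("EDTB", "OLBI")
  }
  required <- c("population", .CELL_NAMES)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  for (cl in .CELL_NAMES) {
    if (any(df[[cl]] < 0)) stop("negative count in column '", cl, "'", call. = FALSE)
  }
  pops <- lapply(seq_len(nrow(df)), function(i) {
    population_counts(df$population[i], df$n11[i], df$n10[i], df$n01[i], df$n00[i])
  })
  study_data(pops, test_names = test_names)
}

#' Write cross-tabulated study data to CSV or JSON
#'
#' @param data A [study_data()] object.
#' @param path Output file path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return `path`, invisibly. Reading the file back with [read_counts()]
#'   reproduces `data` exactly.
#' @export
write_counts <- function(data, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(data, "study_data"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    jsonlite::write_json(
      list(test_names = data$test_names, populations = data$counts),
      path, auto_unbox = TRUE, digits = I(17)
    )
  } else {
    utils::write.csv(data$counts, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
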