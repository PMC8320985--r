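# Benchmark harness: published lower-bound reference table and a sweep over
# (n, d) cells comparing the exact oracle, greedy baseline and EORS.

#' Published lower bounds on A^\{GC,NL\}(n, d, w)
#'
#' Reference table of reported lower bounds on the maximum size of a
#' length-`n` DNA code with minimum Hamming distance `d`, GC weight
#' `w = floor(n/2)` and the no-runlength constraint, for `4 <= n <= 10`:
#' the altruistic-algorithm values and the EORS values they are compared
#' against. Used as reference data for benchmarking and improvement
#' arithmetic, never as a computational shortcut.
#'
#' @return data.frame with columns `n`, `d`, `altruistic`, `eors`.
#' @export
reference_bounds <- function() {
  rows <- rbind(
    c(4, 3, 11, 12),
    c(5, 3, 17, 20), c(5, 4, 7, 8),
    c(6, 3, 44, 55), c(6, 4, 16, 21), c(6, 5, 6, 8),
    c(7, 3, 110, 125), c(7, 4, 36, 46), c(7, 5, 11, 16), c(7, 6, 4, 6),
    c(8, 3, 289, 364), c(8, 4, 86, 110), c(8, 5, 29, 38), c(8, 6, 9, 15),
    c(8, 7, 4, 5), c(8, 8, 4, 4),
    c(9, 3, 662, 737), c(9, 4, 199, 226), c(9, 5, 59, 71), c(9, 6, 15, 26),
    c(9, 7, 8, 11), c(9, 8, 4, 5), c(9, 9, 4, 4),
    c(10, 3, 1810, 1856), c(10, 4, 525, 546), c(10, 5, 141, 153),
    c(10, 6, 43, 53), c(10, 7, 7, 22), c(10, 8, 5, 9), c(10, 9, 4, 5)
  )
  data.frame(n = as.integer(rows[, 1]), d = as.integer(rows[, 2]),
             altruistic = as.integer(rows[, 3]), eors = as.integer(rows[, 4]))
}

#' Relative improvement over a reference bound
#'
#' Percentage increase of `achieved` over `reference`:
#' `100 * (achieved - reference) / reference`.
#'
#' @param achieved,reference positive set sizes.
#' @return numeric percentage.
#' @examples
#' improvement_percent(364, 289)  # ~26
#' @export
improvement_percent <- function(achieved, reference) {
  if (any(reference < 1)) stop("reference must be >= 1")
  100 * (achieved - reference) / reference
}

#' Benchmark sweep over (n, d) cells
#'
#' Runs the requested methods on each `(n, d)` cell at `w = floor(n/2)`,
#' no-runlength on, and reports one row per cell and method: achieved size
#' `M`, the coding rate `log4(M)/n` recomputed from `M` and `n`, the seed
#' and the iteration/draw budgets. Per-cell failures (e.g. an enumeration
#' guard) are recorded in the `error` column and the sweep continues.
#'
#' @param cells data.frame with columns `n` and `d`.
#' @param methods subset of `"exact"`, `"greedy"`, `"eors"`.
#' @param eo,rs parameter objects for the EORS method.
#' @param restarts restarts for the greedy baseline.
#' @param seed master seed; cell seeds are derived deterministically.
#' @return data.frame of benchmark rows.
#' @export
benchmark_sweep <- function(cells, methods = c("exact", "greedy", "eors"),
                            eo = eo_params(t_max = 100L),
                            rs = rs_params(budget = 10000L),
                            restarts = 10L, seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(is.data.frame(cells), all(c("n", "d") %in% names(cells)))
  out <- list()
  for (i in seq_len(nrow(cells))) {
    n <- as.integer(cells$n[i]); d <- as.integer(cells$d[i])
    profile <- constraint_profile(n, d)
    cell_seed <- (as.integer(seed) + 7919L * i) %% .Machine$integer.max
    for (m in methods) {
      M <- NA_integer_; err <- NA_character_
      budget <- switch(m,
                       exact = NA_integer_,
                       greedy = as.integer(restarts),
                       eors = as.integer(eo$t_max))
      res <- tryCatch(switch(m,
        exact = max_clique_exact(build_conflict_graph(profile)),
        greedy = greedy_random_baseline(profile, restarts = restarts,
                                        seed = cell_seed),
        eors = eors_search(profile, eo = eo, rs = rs, seed = cell_seed)
      ), error = function(e) e)
      if (inherits(res, "error")) err <- conditionMessage(res)
      else M <- length(res)
      out[[length(out) + 1L]] <- data.frame(
        n = n, d = d, method = m, M = M,
        rate = if (is.na(M) || M < 1L) NA_real_ else coding_rate(M, n),
        seed = if (m == "exact") NA_integer_ else cell_seed,
        budget = budget, error = err, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write a benchmark table
#'
#' Emits the sweep as tab-separated text and, when `json` is given, as JSON.
#'
#' @param rows data.frame from [benchmark_sweep()].
#' @param path output TSV path.
#' @param json optional output JSON path.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(rows, path, json = NULL) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(rows, json, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}
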