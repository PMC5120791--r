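#' Leave-out experiment designs
#'
#' Four grouped leave-out designs probe how much MRI information about a
#' patient the predictor is allowed to see:
#'
#' * `exp1_measurement` -- leave out the single test measurement (classic
#'   leave-one-out; training may contain the same patient, same side, other
#'   visits).
#' * `exp2_patient_side` -- leave out every measurement sharing the test
#'   row's patient *and* side (the opposite side of the same patient stays).
#' * `exp3_same_time` -- leave out every measurement sharing the test row's
#'   patient and visit (other visits of the same patient stay).
#' * `exp4_patient` -- leave out every measurement of the test row's patient
#'   (leave-one-patient-out; no MRI information about that patient at all).
#'
#' The short aliases `"exp1"` ... `"exp4"` are accepted everywhere.
#'
#' @return `leave_out_modes()`: the four canonical mode names.
#' @export
leave_out_modes <- function() {
  c("exp1_measurement", "exp2_patient_side", "exp3_same_time", "exp4_patient")
}

normalize_mode <- function(mode) {
  modes <- leave_out_modes()
  short <- c(exp1 = modes[1], exp2 = modes[2], exp3 = modes[3], exp4 = modes[4])
  if (mode %in% modes) return(mode)
  if (mode %in% names(short)) return(short[[mode]])
  stop("unknown leave-out mode: ", mode, call. = FALSE)
}

# rows excluded from training for a given test row (always includes it)
exclusion_set <- function(table, test_row, mode) {
  pid <- table$patient_id
  switch(mode,
    exp1_measurement = test_row,
    exp2_patient_side = which(pid == pid[test_row] &
                                table$side == table$side[test_row]),
    exp3_same_time = which(pid == pid[test_row] &
                             table$visit_id == table$visit_id[test_row]),
    exp4_patient = which(pid == pid[test_row]))
}

#' Training rows for one test measurement under a leave-out design
#'
#' @param table cohort data frame with `patient_id` and, as the mode
#'   requires, `side` and `visit_id` columns.
#' @param test_row index of the held-out measurement.
#' @param mode one of [leave_out_modes()] (or `"exp1"`..`"exp4"`).
#' @return integer vector of training row indices; the test row is never
#'   included.
#' @examples
#' d <- generate_cohort(cohort_config(n_patients = 5), seed = 1)
#' length(build_training_indices(d, 1, "exp1"))  # nrow(d) - 1
#' @export
build_training_indices <- function(table, test_row, mode) {
  stopifnot(is.data.frame(table), "patient_id" %in% names(table))
  mode <- normalize_mode(mode)
  if (length(test_row) != 1 || test_row < 1 || test_row > nrow(table))
    stop("test_row out of range", call. = FALSE)
  if (mode == "exp2_patient_side" && !"side" %in% names(table))
    stop("mode exp2_patient_side needs a side column", call. = FALSE)
  if (mode == "exp3_same_time" && !"visit_id" %in% names(table))
    stop("mode exp3_same_time needs a visit_id column", call. = FALSE)
  setdiff(seq_len(nrow(table)), exclusion_set(table, test_row, mode))
}

#' Pearson correlation with a t-based p-value
#'
#' The product-moment correlation together with the two-sided p-value of the
#' transform \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom.
#' The p-value is reported as computed, with no reporting floor (perfectly
#' collinear inputs return the smallest positive double). A seeded
#' permutation alternative is available for small samples.
#'
#' @param a,b numeric vectors of equal length, at least 3, each with nonzero
#'   variance.
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_perm number of permutations for `method = "permutation"`.
#' @param seed permutation seed.
#' @return list with elements `r` and `p`.
#' @examples
#' pearson_r_pvalue(1:10, (1:10)^2)
#' @export
pearson_r_pvalue <- function(a, b, method = c("t", "permutation"),
                             n_perm = 10000, seed = 1) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("a and b must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("missing values not allowed", call. = FALSE)
  da <- a - mean(a); db <- b - mean(b)
  va <- sum(da^2); vb <- sum(db^2)
  if (va == 0 || vb == 0)
    stop("correlation undefined: an input has zero variance", call. = FALSE)
  r <- sum(da * db) / sqrt(va * vb)
  r <- max(-1, min(1, r))
  if (method == "t") {
    p <- if (abs(r) == 1) .Machine$double.xmin else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      max(2 * pt(-abs(tstat), df = n - 2), .Machine$double.xmin)
    }
  } else {
    seeds <- derive_seeds(seed, 1)
    set.seed(seeds[1])
    rp <- replicate(n_perm, {
      bp <- b[sample.int(n)]
      sum(da * (bp - mean(bp))) / sqrt(va * sum((bp - mean(bp))^2))
    })
    p <- (1 + sum(abs(rp) >= abs(r) - 1e-15)) / (n_perm + 1)
  }
  list(r = r, p = p)
}

#' Run one leave-out cross-validation experiment
#'
#' For every row of the (complete) table, fits a regression forest on the
#' training rows given by [build_training_indices()] under the chosen
#' leave-out design, predicts the held-out row, and reports the Pearson
#' correlation between predicted and measured CBF over all rows. Before each
#' fit the disjointness of the training set and the design's exclusion set is
#' asserted, so information leakage from the held-out patient/side/visit is
#' structurally impossible.
#'
#' Each test row's forest gets its own derived seed, so results are
#' independent of evaluation order and fully reproducible from `seed`.
#'
#' @param table complete cohort data frame (impute first if needed) with
#'   grouping keys (`patient_id`, `side`, `visit_id`) intact.
#' @param mode leave-out design, see [leave_out_modes()].
#' @param ntree,mtry,nodemin forest hyperparameters (defaults 500, 3, 5).
#' @param seed master seed.
#' @param predictors predictor columns; default the 11 cohort predictors.
#' @param response response column, default `"cbf"`.
#' @param strata optional column name: training rows are additionally
#'   restricted to the test row's stratum (e.g. fit healthy and diseased
#'   separately by passing a health-status column).
#' @param response_observed optional logical vector marking rows whose
#'   response was actually measured (not imputed); when given, the
#'   experiment is restricted to those rows.
#' @return object of class `"cv_experiment"`: per-row `y`, `yhat` and
#'   `learning_n`, the overall Pearson `r` and `p`, the mode and
#'   hyperparameters.
#' @seealso [run_experiments()], [summarize_experiments()]
#' @export
run_experiment <- function(table, mode, ntree = 500, mtry = 3, nodemin = 5,
                           seed = 1, predictors = NULL, response = "cbf",
                           strata = NULL, response_observed = NULL) {
  stopifnot(is.data.frame(table))
  mode <- normalize_mode(mode)
  if (!is.null(response_observed)) {
    stopifnot(length(response_observed) == nrow(table))
    table <- table[response_observed, , drop = FALSE]
  }
  if (is.null(predictors)) {
    predictors <- if (all(cohort_predictors() %in% names(table)))
      cohort_predictors()
    else setdiff(names(table), c("patient_id", "side", "visit_id", "group",
                                 "mass_M", "insonation_angle", response))
  }
  n <- nrow(table)
  if (n < 3) stop("need at least 3 rows (correlation undefined)", call. = FALSE)
  used <- table[, c(predictors, response), drop = FALSE]
  if (anyNA(used))
    stop("table has missing values in model columns; impute first with rf_impute()",
         call. = FALSE)
  y <- as.double(table[[response]])
  enc <- encode_frame(table, predictors)
  m <- min(mtry, length(predictors))
  row_seeds <- derive_seeds(seed, n)

  yhat <- numeric(n)
  learning_n <- integer(n)
  for (i in seq_len(n)) {
    tr <- build_training_indices(table, i, mode)
    excl <- exclusion_set(table, i, mode)
    if (length(intersect(tr, excl)) > 0 || i %in% tr)
      stop("internal leakage check failed for row ", i, call. = FALSE)
    if (!is.null(strata))
      tr <- tr[table[[strata]][tr] == table[[strata]][i]]
    if (length(tr) < 2)
      stop("training set for row ", i, " has fewer than 2 rows", call. = FALSE)
    tseeds <- derive_seeds(row_seeds[i], ntree)
    trees <- cpp_fit_forest(enc$X[tr, , drop = FALSE], y[tr], enc$nlev, m,
                            as.integer(nodemin), as.double(tseeds), TRUE)
    yhat[i] <- cpp_predict_forest(trees, enc$X[i, , drop = FALSE], enc$nlev)
    learning_n[i] <- length(tr)
  }
  ct <- pearson_r_pvalue(yhat, y)
  structure(list(mode = mode, y = y, yhat = yhat, learning_n = learning_n,
                 r = ct$r, p = ct$p, n = n,
                 ntree = ntree, mtry = m, nodemin = nodemin, seed = seed),
            class = "cv_experiment")
}

#' @export
print.cv_experiment <- function(x, ...) {
  rng <- range(x$learning_n)
  cat("Leave-out experiment", x$mode, "\n")
  cat("  rows:", x$n, "  learning data:",
      if (rng[1] == rng[2]) rng[1] else paste0(rng[1], "-", rng[2]), "\n")
  cat(sprintf("  r = %.3f, p = %.3g  (%d trees, mtry %d)\n",
              x$r, x$p, x$ntree, x$mtry))
  invisible(x)
}

#' Scatter of measured versus predicted CBF
#'
#' @param x a [run_experiment()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cv_experiment <- function(x, ...) {
  graphics::plot(x$yhat, x$y, xlab = "predicted CBF (ml/min/100g)",
                 ylab = "measured CBF (ml/min/100g)",
                 main = sprintf("%s: r = %.2f", x$mode, x$r), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Run several leave-out experiments on one table
#'
#' @param table complete cohort data frame.
#' @param modes leave-out designs to run (default all four).
#' @param ... passed to [run_experiment()] (shared seed and hyperparameters).
#' @return named list of class `"cv_experiment_list"`.
#' @export
run_experiments <- function(table, modes = c("exp1", "exp2", "exp3", "exp4"),
                            ...) {
  modes <- vapply(modes, normalize_mode, "")
  out <- lapply(modes, function(mo) run_experiment(table, mo, ...))
  names(out) <- modes
  class(out) <- "cv_experiment_list"
  out
}

#' @export
print.cv_experiment_list <- function(x, ...) {
  print(summarize_experiments(x))
  invisible(x)
}

#' @export
summary.cv_experiment_list <- function(object, ...) summarize_experiments(object)

#' Tabulate leave-out experiment results
#'
#' The machine-readable analogue of a per-experiment summary table: one row
#' per experiment with the range of per-row learning-set sizes (a single
#' number when all rows trained on equally many rows, otherwise
#' `"min-max"`), the Pearson correlation between predicted and measured
#' response, and its p-value.
#'
#' @param results a `"cv_experiment_list"`, a list of `"cv_experiment"`
#'   objects, or a single one.
#' @return data frame with columns `experiment`, `learning_data`,
#'   `learning_min`, `learning_max`, `r`, `p`.
#' @export
summarize_experiments <- function(results) {
  if (inherits(results, "cv_experiment")) results <- list(results)
  if (length(results) == 0) stop("no experiment results to summarize", call. = FALSE)
  rows <- lapply(results, function(x) {
    if (!inherits(x, "cv_experiment"))
      stop("summarize_experiments expects cv_experiment objects", call. = FALSE)
    if (length(x$yhat) == 0 || length(x$y) == 0)
      stop("experiment result has empty prediction vectors", call. = FALSE)
    rng <- range(x$learning_n)
    data.frame(experiment = x$mode,
               learning_data = if (rng[1] == rng[2]) as.character(rng[1])
                               else paste0(rng[1], "-", rng[2]),
               learning_min = rng[1], learning_max = rng[2],
               r = x$r, p = x$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
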