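#' Mean/mode initialization of missing cells
#'
#' Initial guesses for iterative imputation: numeric missing cells take the
#' column mean of the observed cells, categorical missing cells the column
#' mode (ties broken toward the first level in sorted order). Observed cells
#' are untouched.
#'
#' @param data data frame.
#' @param vars columns to initialize (default all).
#' @return the data frame with the selected columns filled.
#' @export
mean_mode_initialize <- function(data, vars = names(data)) {
  stopifnot(is.data.frame(data))
  for (v in vars) {
    col <- data[[v]]
    if (is.null(col)) stop("column '", v, "' not found", call. = FALSE)
    miss <- is.na(col)
    if (!any(miss)) next
    if (all(miss))
      stop("column '", v, "' is fully missing and cannot be imputed", call. = FALSE)
    if (is.numeric(col)) {
      data[[v]][miss] <- mean(col[!miss])
    } else {
      obs <- as.character(col[!miss])
      tabcnt <- table(obs)
      data[[v]][miss] <- names(tabcnt)[which.max(tabcnt)]
    }
  }
  data
}

#' Change statistic between two imputation iterations
#'
#' Measures how much the imputed cells moved between successive iterations.
#' The numeric statistic is \eqn{\sum (curr - prev)^2 / \sum curr^2}, both
#' sums running over the originally-missing numeric cells; the categorical
#' statistic is the fraction of originally-missing categorical cells whose
#' level changed.
#'
#' @param prev,curr data frames of identical shape (successive imputed
#'   matrices).
#' @param mask logical matrix, `TRUE` marking originally missing cells;
#'   columns named after the data columns.
#' @return named numeric vector `c(numeric = ..., categorical = ...)`.
#' @export
imputation_delta <- function(prev, curr, mask) {
  if (!identical(dim(prev), dim(curr)) || !identical(names(prev), names(curr)))
    stop("prev and curr must have identical shape", call. = FALSE)
  if (nrow(mask) != nrow(prev) || is.null(colnames(mask)))
    stop("mask must have one row per data row and named columns", call. = FALSE)
  num_num <- num_den <- 0
  cat_chg <- cat_tot <- 0
  for (v in colnames(mask)) {
    m <- mask[, v]
    if (!any(m)) next
    if (is.numeric(curr[[v]])) {
      num_num <- num_num + sum((curr[[v]][m] - prev[[v]][m])^2)
      num_den <- num_den + sum(curr[[v]][m]^2)
    } else {
      cat_chg <- cat_chg + sum(as.character(curr[[v]][m]) !=
                                 as.character(prev[[v]][m]))
      cat_tot <- cat_tot + sum(m)
    }
  }
  c(numeric = if (num_den > 0) num_num / num_den else 0,
    categorical = if (cat_tot > 0) cat_chg / cat_tot else 0)
}

#' Iterative random-forest imputation of a mixed-type table
#'
#' Implements the iterative scheme in which the \eqn{N \times (p+1)} data
#' matrix \eqn{\xi} (predictors plus response) is completed column by column:
#' after mean/mode initialization, each column with missing entries is taken
#' in turn (ascending count of missing values), a regression forest is fit on
#' the rows where that column is observed using all other columns as
#' predictors, the missing entries are replaced by forest predictions, and
#' the sweep is repeated until the matrix stops changing.
#'
#' Stopping: the iteration ends when both change statistics
#' ([imputation_delta()]) fall below their tolerances, or when the numeric
#' statistic increases relative to the previous sweep (in which case the
#' previous matrix is returned -- the standard stopping rule for this
#' scheme), or at `max_iter`. Only the first two count as convergence.
#'
#' Categorical columns are imputed by regressing their integer level codes
#' and rounding each prediction to the nearest code, so imputed values can
#' only be levels observed in that column.
#'
#' @param data data frame with missing values.
#' @param vars columns forming the imputation matrix. Default: the 11 cohort
#'   predictors plus `cbf` when the cohort schema is present, otherwise every
#'   column.
#' @param ntree,mtry,nodemin forest hyperparameters for the per-column fits
#'   (default 100 trees -- smaller than a final prediction forest, since one
#'   forest is fit per incomplete column per sweep).
#' @param max_iter maximum number of sweeps.
#' @param tol_numeric,tol_categorical convergence tolerances for the two
#'   change statistics.
#' @param exclude_response drop the response column from the imputation
#'   matrix (it is neither imputed nor used as a predictor). Imputing the
#'   response from the predictors before cross-validation leaks information
#'   into later training sets; the default keeps the response in, matching
#'   the once-on-the-full-matrix reading described in the vignette.
#' @param response name of the response column (used by `exclude_response`).
#' @param seed master seed; per-column, per-sweep forests get derived seeds.
#' @return object of class `"rf_impute"`: list with `data` (the input with
#'   imputed cells filled in; observed cells bit-identical), `mask` (logical
#'   matrix of originally-missing cells over `vars`), and `report`
#'   (iterations, per-sweep change trace, `converged`, stopping `reason`).
#' @examples
#' d <- data.frame(x = c(1, NA, 3, 4, 5, 6), g = c("a", "a", "b", "b", NA, "b"),
#'                 y = c(2, 2.1, 5.9, 6, 6.2, 5.8))
#' imp <- rf_impute(d, vars = c("x", "g", "y"), ntree = 20, nodemin = 2)
#' imp$data
#' @export
rf_impute <- function(data, vars = NULL, ntree = 100, mtry = 3, nodemin = 5,
                      max_iter = 10, tol_numeric = 1e-4, tol_categorical = 0,
                      exclude_response = FALSE, response = "cbf", seed = 1) {
  stopifnot(is.data.frame(data), max_iter >= 1)
  if (is.null(vars)) {
    cohortish <- all(c(cohort_predictors(), "cbf") %in% names(data))
    vars <- if (cohortish) c(cohort_predictors(), "cbf") else names(data)
  }
  if (exclude_response) vars <- setdiff(vars, response)
  k <- length(vars)
  if (k < 2) stop("need at least two columns to impute", call. = FALSE)

  mask <- sapply(vars, function(v) is.na(data[[v]]))
  if (nrow(data) == 1) mask <- matrix(mask, 1, k, dimnames = list(NULL, vars))
  for (v in vars) if (all(mask[, v]))
    stop("column '", v, "' is fully missing and cannot be imputed", call. = FALSE)

  ximp <- mean_mode_initialize(data[, vars, drop = FALSE], vars)
  miss_cols <- vars[colSums(mask) > 0]
  miss_cols <- miss_cols[order(colSums(mask)[miss_cols])]  # best-informed first

  trace <- data.frame(iteration = integer(), numeric = numeric(),
                      categorical = numeric())
  converged <- FALSE
  reason <- "max_iter"
  iterations <- 0L

  if (length(miss_cols) == 0) {
    trace <- data.frame(iteration = 1L, numeric = 0, categorical = 0)
    iterations <- 1L
    converged <- TRUE
    reason <- "tolerance"
  } else {
    col_seeds <- matrix(derive_seeds(seed, max_iter * length(miss_cols)),
                        nrow = max_iter)
    prev_delta_num <- Inf
    for (it in seq_len(max_iter)) {
      prev <- ximp
      for (sidx in seq_along(miss_cols)) {
        v <- miss_cols[sidx]
        others <- setdiff(vars, v)
        obs <- !mask[, v]
        col <- ximp[[v]]
        is_cat <- !is.numeric(col)
        if (is_cat) {
          lv <- sort(unique(as.character(data[[v]][obs])))
          yv <- match(as.character(col), lv)
        } else yv <- col
        enc <- encode_frame(ximp, others)
        m <- min(mtry, length(others))
        tseeds <- derive_seeds(col_seeds[it, sidx], ntree)
        trees <- cpp_fit_forest(enc$X[obs, , drop = FALSE], as.double(yv[obs]),
                                enc$nlev, m, as.integer(nodemin),
                                as.double(tseeds), TRUE)
        pred <- cpp_predict_forest(trees, enc$X[!obs, , drop = FALSE], enc$nlev)
        if (is_cat) {
          code <- pmin(length(lv), pmax(1L, as.integer(round(pred))))
          ximp[[v]][!obs] <- lv[code]
        } else {
          ximp[[v]][!obs] <- pred
        }
      }
      iterations <- it
      delta <- imputation_delta(prev, ximp, mask)
      trace <- rbind(trace, data.frame(iteration = it, numeric = delta[["numeric"]],
                                       categorical = delta[["categorical"]]))
      if (delta[["numeric"]] <= tol_numeric &&
          delta[["categorical"]] <= tol_categorical) {
        converged <- TRUE; reason <- "tolerance"; break
      }
      if (it >= 2 && delta[["numeric"]] > prev_delta_num) {
        ximp <- prev                 # keep the matrix before the deterioration
        converged <- TRUE; reason <- "delta_increase"; break
      }
      prev_delta_num <- delta[["numeric"]]
    }
  }

  out <- data
  for (v in vars) out[[v]][mask[, v]] <- ximp[[v]][mask[, v]]
  structure(list(data = out, mask = mask, vars = vars,
                 report = list(iterations = iterations, trace = trace,
                               converged = converged, reason = reason),
                 ntree = ntree, mtry = mtry, nodemin = nodemin, seed = seed),
            class = "rf_impute")
}

#' @export
print.rf_impute <- function(x, ...) {
  r <- x$report
  cat("Random-forest imputation:", sum(x$mask), "cells imputed over",
      r$iterations, if (r$iterations == 1) "sweep\n" else "sweeps\n")
  cat("  stopped by", r$reason,
      if (r$converged) "(converged)\n" else "(not converged)\n")
  invisible(x)
}
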