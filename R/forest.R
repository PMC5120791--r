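#' Fit a regression random forest
#'
#' Grows an ensemble of CART-style regression trees by bootstrap aggregation.
#' Each tree is grown on an independent bootstrap resample of the \eqn{N}
#' training rows; at every node with at least `nodemin` rows, `mtry` candidate
#' predictors are drawn uniformly without replacement and the node is split at
#' the cut (numeric threshold or categorical level subset) that maximally
#' reduces the within-node sum of squared errors of a piecewise-constant fit.
#' Leaves store the mean response of their region, and the forest prediction
#' is the plain average of the per-tree predictions,
#' \deqn{F(x) = \frac{1}{T}\sum_{t=1}^{T} T_t(x).}
#'
#' Splitting is deterministic given the seed: a single master seed spawns one
#' independent random stream per tree (used for its bootstrap draw and its
#' per-node variable draws), so the result does not depend on the order in
#' which trees are grown. Gain ties are broken toward the earliest predictor
#' in schema (column) order, then the lowest threshold. A node is split only
#' when it holds at least `nodemin` rows and the best candidate split has a
#' strictly positive error reduction with two nonempty children.
#'
#' Training data must be complete; impute first (see [rf_impute()]).
#'
#' @param formula model formula, e.g. `cbf ~ .` or `cbf ~ bfv + age`.
#'   Predictors are used as-is (no dummy expansion); factors, characters and
#'   logicals are treated as categorical.
#' @param data data frame holding response and predictors, no missing values
#'   in the used columns.
#' @param ntree number of trees \eqn{T} (default 500).
#' @param mtry number of candidate predictors drawn at each node (default 3).
#'   Values of at least `p` use every predictor and consume no randomness.
#' @param nodemin minimum node size required to attempt a split (default 5).
#' @param seed integer master seed controlling all randomness.
#' @param bootstrap logical; `FALSE` grows every tree on the unresampled
#'   training rows (deterministic fit for oracle-style comparisons).
#' @return An object of class `"rforest"`: a list with the grown `trees`
#'   (flattened node arrays, including the 1-based bootstrap indices `inbag`),
#'   the encoding `schema`, training response `y`, encoded predictors `X`,
#'   and hyperparameters.
#' @seealso [predict.rforest()], [grow_tree()], [best_split()],
#'   [write_forest()]
#' @examples
#' d <- generate_cohort(cohort_config(n_patients = 20), seed = 1)
#' fit <- rforest(cbf ~ bfv + age + hct, d, ntree = 25, seed = 1)
#' cor(predict(fit), d$cbf)
#' @export
rforest <- function(formula, data, ntree = 500, mtry = 3, nodemin = 5,
                    seed = 1, bootstrap = TRUE) {
  stopifnot(is.data.frame(data), ntree >= 1, nodemin >= 1)
  tf <- stats::terms(formula, data = data)
  if (attr(tf, "response") != 1L) stop("formula needs a response", call. = FALSE)
  response <- as.character(attr(tf, "variables"))[2L]
  vars <- attr(tf, "term.labels")
  if (length(vars) < 1L) stop("formula needs at least one predictor", call. = FALSE)
  used <- data[, c(vars, response), drop = FALSE]
  if (anyNA(used))
    stop("training data contain missing values; impute first, e.g. with rf_impute()",
         call. = FALSE)
  y <- data[[response]]
  if (!is.numeric(y)) stop("response must be numeric", call. = FALSE)
  enc <- encode_frame(data, vars)
  if (mtry < 1) stop("mtry must be >= 1", call. = FALSE)
  m <- min(as.integer(mtry), length(vars))
  tree_seeds <- derive_seeds(seed, ntree)
  trees <- cpp_fit_forest(enc$X, as.double(y), enc$nlev, m,
                          as.integer(nodemin), as.double(tree_seeds), bootstrap)
  structure(list(trees = trees,
                 schema = list(vars = vars, nlev = enc$nlev, levels = enc$levels),
                 response = response, y = as.double(y), X = enc$X,
                 ntree = as.integer(ntree), mtry = m,
                 nodemin = as.integer(nodemin), seed = seed,
                 bootstrap = bootstrap, N = nrow(data),
                 call = match.call()),
            class = "rforest")
}

#' Predict from a regression random forest
#'
#' Averages the per-tree predictions at each row of `newdata`. Every
#' predictor used at fit time must be present and observed; categorical
#' values must be levels seen at fit time.
#'
#' @param object an [rforest()] fit.
#' @param newdata data frame of predictors; omitted = training data
#'   (in-sample predictions).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.rforest <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    X <- object$X
  } else {
    stopifnot(is.data.frame(newdata))
    if (anyNA(newdata[, object$schema$vars, drop = FALSE]))
      stop("newdata contains missing predictor values", call. = FALSE)
    X <- encode_frame(newdata, object$schema$vars, object$schema)$X
  }
  cpp_predict_forest(object$trees, X, object$schema$nlev)
}

#' @export
fitted.rforest <- function(object, ...) predict.rforest(object)

#' @export
residuals.rforest <- function(object, ...) object$y - predict.rforest(object)

#' @export
print.rforest <- function(x, ...) {
  cat("Regression random forest\n")
  cat("  response:", x$response, "  predictors:", length(x$schema$vars), "\n")
  cat("  trees:", x$ntree, "  mtry:", x$mtry, "  nodemin:", x$nodemin,
      "  bootstrap:", x$bootstrap, "\n")
  cat("  training rows:", x$N, "\n")
  invisible(x)
}

#' @export
summary.rforest <- function(object, ...) {
  yhat <- predict.rforest(object)
  res <- object$y - yhat
  out <- list(ntree = object$ntree, mtry = object$mtry,
              nodemin = object$nodemin, N = object$N,
              leaves = vapply(object$trees, function(tr) sum(tr$var < 0L), 1L),
              insample_r = if (sd(yhat) > 0) stats::cor(yhat, object$y) else NA_real_,
              insample_rmse = sqrt(mean(res^2)))
  class(out) <- "summary.rforest"
  out
}

#' @export
print.summary.rforest <- function(x, ...) {
  cat("Regression random forest:", x$ntree, "trees on", x$N, "rows\n")
  cat("  leaves per tree:", min(x$leaves), "-", max(x$leaves), "\n")
  cat(sprintf("  in-sample r = %.3f, RMSE = %.3f\n", x$insample_r, x$insample_rmse))
  invisible(x)
}

#' Grow a single regression tree
#'
#' Recursive binary partitioning with constant leaf models: every node with
#' at least `nodemin` rows draws `mtry` candidate predictors and takes the
#' split with maximal sum-of-squared-error reduction; leaves store the mean
#' response of the rows they hold. With `mtry = NULL` (all predictors) and
#' `rows = NULL` the construction is fully deterministic, which is the
#' configuration compared against an exhaustive CART search in the tests.
#'
#' @param data complete data frame.
#' @param response name of the numeric response column.
#' @param vars predictor column names (default: all other columns).
#' @param mtry candidate predictors per node; `NULL` = all.
#' @param nodemin minimum node size to attempt a split.
#' @param seed seed for the per-node variable draws (unused when `mtry` covers
#'   all predictors).
#' @param rows optional 1-based training row indices, possibly repeated (a
#'   bootstrap sample); `NULL` = all rows.
#' @return An object of class `"rtree"`: the flattened node arrays in `tree`
#'   (`var[k] < 0` marks leaf `k`, whose mean response is `value[k]`; child
#'   pointers are 0-based), the encoding schema, and the leaf count `K`.
#' @examples
#' d <- data.frame(x = c(1, 2, 3, 4), y = c(0, 0, 10, 10))
#' tr <- grow_tree(d, "y", nodemin = 2)
#' predict(tr, data.frame(x = c(1.5, 3.5)))
#' @export
grow_tree <- function(data, response, vars = setdiff(names(data), response),
                      mtry = NULL, nodemin = 5, seed = 1, rows = NULL) {
  stopifnot(is.data.frame(data), nrow(data) >= 1, length(vars) >= 1)
  used <- data[, c(vars, response), drop = FALSE]
  if (anyNA(used))
    stop("data contain missing values; impute first, e.g. with rf_impute()",
         call. = FALSE)
  y <- data[[response]]
  if (!is.numeric(y)) stop("response must be numeric", call. = FALSE)
  enc <- encode_frame(data, vars)
  m <- if (is.null(mtry)) length(vars) else min(as.integer(mtry), length(vars))
  if (m < 1) stop("mtry must be >= 1", call. = FALSE)
  if (is.null(rows)) rows <- seq_len(nrow(data))
  tree <- cpp_grow_tree(enc$X, as.double(y), enc$nlev, m, as.integer(nodemin),
                        as.double(seed), as.integer(rows))
  structure(list(tree = tree,
                 schema = list(vars = vars, nlev = enc$nlev, levels = enc$levels),
                 response = response, K = sum(tree$var < 0L),
                 nodemin = as.integer(nodemin), mtry = m),
            class = "rtree")
}

#' @export
predict.rtree <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata))
  if (anyNA(newdata[, object$schema$vars, drop = FALSE]))
    stop("newdata contains missing predictor values", call. = FALSE)
  X <- encode_frame(newdata, object$schema$vars, object$schema)$X
  cpp_predict_tree(object$tree, X, object$schema$nlev)
}

#' @export
print.rtree <- function(x, ...) {
  cat("Regression tree with", x$K, "leaves over", length(x$schema$vars),
      "predictors\n")
  invisible(x)
}

#' Best single split of a node
#'
#' Searches all candidate predictors and all admissible cut positions for the
#' binary split that maximally reduces the within-node sum of squared errors
#' of a constant fit on each side. Numeric cuts sit at midpoints between
#' consecutive distinct sorted values; categorical splits enumerate every
#' nonempty proper level subset. Ties keep the earliest predictor in `vars`
#' schema order, then the lowest cut.
#'
#' @param data complete data frame (the rows of one node).
#' @param response name of the numeric response column.
#' @param vars candidate predictor names.
#' @return `NULL` when no split yields a positive error reduction with two
#'   nonempty children (e.g. constant response or all-constant candidates);
#'   otherwise a list of class `"split_decision"` with `variable`, `kind`
#'   (`"numeric"` or `"categorical"`), `threshold` (numeric kind, left =
#'   `value <= threshold`) or `levels_left` (categorical kind), and
#'   `sse_reduction`.
#' @examples
#' d <- data.frame(x = c(1, 2, 3, 4), y = c(0, 0, 10, 10))
#' best_split(d, "y")
#' @export
best_split <- function(data, response, vars = setdiff(names(data), response)) {
  stopifnot(is.data.frame(data), length(vars) >= 1)
  if (nrow(data) < 1) stop("no rows to split", call. = FALSE)
  used <- data[, c(vars, response), drop = FALSE]
  if (anyNA(used)) stop("data contain missing values", call. = FALSE)
  y <- data[[response]]
  if (!is.numeric(y)) stop("response must be numeric", call. = FALSE)
  enc <- encode_frame(data, vars)
  s <- cpp_best_split(enc$X, as.double(y), enc$nlev, seq_along(vars))
  if (s$var < 1) return(NULL)
  v <- vars[s$var]
  if (s$is_cat) {
    lv <- enc$levels[[v]]
    left <- lv[bitwAnd(as.integer(s$mask), bitwShiftL(1L, seq_along(lv) - 1L)) > 0L]
    structure(list(variable = v, kind = "categorical", levels_left = left,
                   sse_reduction = s$gain), class = "split_decision")
  } else {
    structure(list(variable = v, kind = "numeric", threshold = s$thr,
                   sse_reduction = s$gain), class = "split_decision")
  }
}

#' @export
print.split_decision <- function(x, ...) {
  if (x$kind == "numeric")
    cat(sprintf("split %s <= %g (SSE reduction %.6g)\n", x$variable,
                x$threshold, x$sse_reduction))
  else
    cat(sprintf("split %s in {%s} (SSE reduction %.6g)\n", x$variable,
                paste(x$levels_left, collapse = ","), x$sse_reduction))
  invisible(x)
}

#' Serialize a forest to JSON
#'
#' Writes the full model -- per-tree flattened node arrays (split variable,
#' threshold or level mask, child pointers, leaf means, bootstrap indices),
#' the predictor schema with categorical levels, and all hyperparameters
#' including the seed -- at full numeric precision, so a round trip through
#' [read_forest()] reproduces predictions exactly.
#'
#' @param forest an [rforest()] fit.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_forest <- function(forest, path) {
  stopifnot(inherits(forest, "rforest"))
  payload <- list(
    format = "flowforest-rforest",
    version = 1L,
    response = forest$response,
    schema = list(vars = forest$schema$vars, nlev = forest$schema$nlev,
                  levels = forest$schema$levels),
    hyper = list(ntree = forest$ntree, mtry = forest$mtry,
                 nodemin = forest$nodemin, seed = forest$seed,
                 bootstrap = forest$bootstrap, N = forest$N),
    y = forest$y,
    trees = forest$trees)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' Read a serialized forest
#'
#' @param path JSON file written by [write_forest()].
#' @return an object of class `"rforest"` (without the encoded training
#'   matrix, so in-sample refitting helpers are unavailable; prediction on
#'   new data is exact).
#' @export
read_forest <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(p$format, "flowforest-rforest"))
    stop("not a flowforest forest file", call. = FALSE)
  trees <- lapply(p$trees, function(tr)
    list(var = as.integer(tr$var), thr = as.double(tr$thr),
         mask = as.double(tr$mask), left = as.integer(tr$left),
         right = as.integer(tr$right), value = as.double(tr$value),
         inbag = as.integer(tr$inbag)))
  levels <- p$schema$levels
  # jsonlite reads the named list back with NULLs dropped; restore numerics
  levs <- stats::setNames(vector("list", length(p$schema$vars)), p$schema$vars)
  for (v in names(levels))
    if (length(levels[[v]])) levs[[v]] <- as.character(levels[[v]])
  structure(list(trees = trees,
                 schema = list(vars = as.character(p$schema$vars),
                               nlev = as.integer(p$schema$nlev), levels = levs),
                 response = p$response, y = as.double(p$y), X = NULL,
                 ntree = as.integer(p$hyper$ntree), mtry = as.integer(p$hyper$mtry),
                 nodemin = as.integer(p$hyper$nodemin), seed = p$hyper$seed,
                 bootstrap = isTRUE(p$hyper$bootstrap), N = as.integer(p$hyper$N),
                 call = NULL),
            class = "rforest")
}
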