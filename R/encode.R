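# Internal: map a mixed-type data frame onto the numeric matrix the C++ tree
# code consumes.  Numeric columns pass through; factor/character/logical
# columns become 1-based level codes.  `schema$levels[[k]]` is NULL for a
# numeric column and the level vector otherwise, so the same schema encodes
# new data consistently at prediction time.

encode_frame <- function(data, vars, schema = NULL) {
  n <- nrow(data)
  X <- matrix(0, n, length(vars), dimnames = list(NULL, vars))
  nlev <- integer(length(vars))
  levs <- vector("list", length(vars))
  names(levs) <- vars
  for (k in seq_along(vars)) {
    v <- vars[k]
    col <- data[[v]]
    if (is.null(col)) stop("column '", v, "' not found in data", call. = FALSE)
    known <- if (is.null(schema)) NULL else schema$levels[[v]]
    if (is.null(schema) && is.numeric(col)) {
      X[, k] <- as.double(col)
    } else if (!is.null(schema) && is.null(known)) {
      if (!is.numeric(col)) stop("column '", v, "' must be numeric", call. = FALSE)
      X[, k] <- as.double(col)
    } else {
      ch <- as.character(col)
      lv <- if (!is.null(known)) known else sort(unique(ch[!is.na(ch)]))
      if (length(lv) > 31L)
        stop("categorical column '", v, "' has more than 31 levels", call. = FALSE)
      code <- match(ch, lv)
      if (any(!is.na(ch) & is.na(code)))
        stop("column '", v, "' contains levels unseen at fit time", call. = FALSE)
      X[, k] <- as.double(code)
      nlev[k] <- length(lv)
      levs[[k]] <- lv
    }
  }
  list(X = X, nlev = nlev, levels = levs, vars = vars)
}

# Internal: derive a reproducible vector of integer sub-seeds from one master
# seed without perturbing the caller's RNG state.
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n, replace = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
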