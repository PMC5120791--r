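# Independent brute-force CART oracle, written directly from the definition:
# enumerate every candidate variable and every admissible cut, take the split
# with maximal SSE reduction of constant fits, recurse while a node holds at
# least n_min rows.  Ties keep the earliest variable in column order, then
# the lowest cut.  Kept deliberately naive and separate from the package's
# implementation.
#
# Fixture values live on a dyadic grid (multiples of 0.25) so all sums are
# exact in double precision and gain comparisons cannot hinge on accumulator
# width.

oracle_best_split <- function(X, y, nlev, vars = seq_len(ncol(X))) {
  n <- length(y)
  S <- 0; SS <- 0
  for (yy in y) { S <- S + yy; SS <- SS + yy * yy }
  base <- S * S / n
  tol <- 1e-12 * (SS + 1)
  best <- list(var = -1L, gain = tol)
  for (j in sort(vars)) {
    if (nlev[j] == 0) {
      o <- order(X[, j])
      xs <- X[o, j]; ys <- y[o]
      sl <- 0
      for (k in seq_len(n - 1)) {
        sl <- sl + ys[k]
        if (xs[k] == xs[k + 1]) next
        nl <- k; nr <- n - k; sr <- S - sl
        gain <- sl * sl / nl + sr * sr / nr - base
        if (gain > best$gain)
          best <- list(var = j, is_cat = FALSE, thr = (xs[k] + xs[k + 1]) / 2,
                       mask = 0, gain = gain)
      }
    } else {
      L <- nlev[j]
      cn <- tabulate(X[, j], L)
      cs <- vapply(seq_len(L), function(c) sum(y[X[, j] == c]), 0)
      for (msk in seq_len(2L^L - 2L)) {
        if (bitwAnd(msk, 1L) == 0L) next     # canonical: level 1 goes left
        inl <- bitwAnd(msk, bitwShiftL(1L, seq_len(L) - 1L)) > 0L
        nl <- sum(cn[inl])
        if (nl == 0 || nl == n) next
        sl <- sum(cs[inl]); sr <- S - sl; nr <- n - nl
        gain <- sl * sl / nl + sr * sr / nr - base
        if (gain > best$gain)
          best <- list(var = j, is_cat = TRUE, thr = 0, mask = msk, gain = gain)
      }
    }
  }
  if (best$var < 0) NULL else best
}

# flattened preorder tree (0-based children, var = -1 at leaves), the same
# layout the package produces, so structures can be compared exactly
oracle_grow <- function(X, y, nlev, n_min) {
  nodes <- list()
  build <- function(rows) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(pending = TRUE)
    s <- NULL
    if (length(rows) >= n_min)
      s <- oracle_best_split(X[rows, , drop = FALSE], y[rows], nlev)
    if (is.null(s)) {
      ssum <- 0
      for (r in rows) ssum <- ssum + y[r]
      nodes[[id]] <<- list(var = -1L, thr = 0, mask = 0, left = -1L,
                           right = -1L, value = ssum / length(rows))
      return(id)
    }
    goleft <- if (!s$is_cat) X[rows, s$var] <= s$thr else
      bitwAnd(s$mask, bitwShiftL(1L, as.integer(X[rows, s$var]) - 1L)) > 0L
    l <- build(rows[goleft])
    r <- build(rows[!goleft])
    nodes[[id]] <<- list(var = s$var - 1L, thr = s$thr, mask = as.double(s$mask),
                         left = l - 1L, right = r - 1L, value = 0)
    id
  }
  build(seq_along(y))
  list(var = vapply(nodes, `[[`, 1L, "var"),
       thr = vapply(nodes, `[[`, 0, "thr"),
       mask = vapply(nodes, `[[`, 0, "mask"),
       left = vapply(nodes, `[[`, 1L, "left"),
       right = vapply(nodes, `[[`, 1L, "right"),
       value = vapply(nodes, `[[`, 0, "value"))
}

# random all-numeric table on the dyadic grid
rand_dyadic_table <- function(seed, max_rows = 12, max_pred = 3) {
  set.seed(seed)
  n <- sample(4:max_rows, 1)
  p <- sample(1:max_pred, 1)
  X <- matrix(sample(seq(0, 10, by = 0.5), n * p, replace = TRUE), n, p)
  y <- sample(seq(0, 8, by = 0.25), n, replace = TRUE)
  d <- as.data.frame(X)
  names(d) <- paste0("x", seq_len(p))
  d$y <- y
  d
}

# number of leaf regions of a grown tree that accept the point (partition
# property: must be exactly 1), evaluated from the leaf-region constraints
# rather than by routing
count_accepting_leaves <- function(tree, xrow, nlev) {
  rec <- function(node, ok) {
    k <- node + 1L
    if (tree$var[k] < 0L) return(as.integer(ok))
    j <- tree$var[k] + 1L
    gl <- if (nlev[j] == 0)
      xrow[j] <= tree$thr[k]
    else
      bitwAnd(as.integer(tree$mask[k]), bitwShiftL(1L, as.integer(xrow[j]) - 1L)) > 0L
    rec(tree$left[k], ok && gl) + rec(tree$right[k], ok && !gl)
  }
  rec(0L, TRUE)
}
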