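test_that("best_split finds the obvious cut and reports its SSE reduction", {
  d <- data.frame(x = c(1, 2, 3, 4), y = c(0, 0, 10, 10))
  s <- best_split(d, "y")
  expect_equal(s$variable, "x")
  expect_equal(s$kind, "numeric")
  expect_equal(s$threshold, 2.5)
  expect_equal(s$sse_reduction, 100)
})

test_that("best_split returns NULL when no split can reduce error", {
  d <- data.frame(x = c(1, 2, 3, 4), y = rep(7, 4))
  expect_null(best_split(d, "y"))
  # all candidate values constant: no admissible cut either
  d2 <- data.frame(x = rep(2, 5), y = c(1, 2, 3, 4, 5))
  expect_null(best_split(d2, "y"))
  expect_error(best_split(d[0, ], "y"), "rows")
})

test_that("best_split agrees with exhaustive search on mixed-type tables", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- 8
    d <- data.frame(x1 = sample(seq(0, 10, 0.5), n, replace = TRUE),
                    x2 = sample(seq(0, 10, 0.5), n, replace = TRUE),
                    g = sample(c("N", "Y"), n, replace = TRUE),
                    y = sample(seq(0, 8, 0.25), n, replace = TRUE))
    X <- cbind(d$x1, d$x2, match(d$g, c("N", "Y")))
    nlev <- c(0L, 0L, 2L)
    ref <- oracle_best_split(X, d$y, nlev)
    got <- best_split(d, "y", vars = c("x1", "x2", "g"))
    if (is.null(ref)) {
      expect_null(got)
    } else {
      expect_equal(got$variable, c("x1", "x2", "g")[ref$var])
      expect_identical(got$sse_reduction, ref$gain)
      if (ref$is_cat) {
        expect_equal(got$kind, "categorical")
        expect_equal(got$levels_left,
                     c("N", "Y")[bitwAnd(ref$mask, 1:2) > 0])
      } else {
        expect_identical(got$threshold, ref$thr)
      }
    }
  }
})

test_that("grow_tree stops immediately below the minimum node size", {
  d <- data.frame(x = c(1, 2, 3, 4), y = c(1, 2, 3, 10))
  tr <- grow_tree(d, "y", nodemin = 5)
  expect_equal(tr$K, 1L)
  expect_equal(predict(tr, data.frame(x = 99)), mean(d$y))
})

test_that("grow_tree with all predictors matches the exhaustive CART oracle", {
  set.seed(77)
  d <- rand_dyadic_table(1001, max_rows = 10, max_pred = 2)
  tr <- grow_tree(d, "y", mtry = NULL, nodemin = 2)
  X <- as.matrix(d[, setdiff(names(d), "y"), drop = FALSE])
  ref <- oracle_grow(X, d$y, rep(0L, ncol(X)), n_min = 2)
  expect_identical(tr$tree$var, ref$var)
  expect_identical(tr$tree$thr, ref$thr)
  expect_identical(tr$tree$left, ref$left)
  expect_identical(tr$tree$right, ref$right)
  expect_identical(tr$tree$value, ref$value)
})

test_that("a plateau response is recovered exactly, one leaf per plateau", {
  # five rectangular plateaus over two predictors, no noise
  grid <- expand.grid(x1 = seq(0.5, 9.5, by = 1), x2 = seq(0.5, 9.5, by = 1))
  plateau <- function(x1, x2) {
    ifelse(x1 <= 3, ifelse(x2 <= 5, 1, 2),
           ifelse(x1 <= 6, 3, ifelse(x2 <= 4, 4, 5)))
  }
  d <- data.frame(grid, y = plateau(grid$x1, grid$x2))
  tr <- grow_tree(d, "y", nodemin = 2)
  expect_equal(tr$K, 5L)
  expect_equal(sort(tr$tree$value[tr$tree$var < 0]), 1:5, tolerance = 0)
  expect_equal(predict(tr, d), d$y)
})

test_that("a forest of one tree without bootstrap equals that tree", {
  d <- rand_dyadic_table(5, max_rows = 12, max_pred = 3)
  f <- rforest(y ~ ., d, ntree = 1, mtry = 10, nodemin = 2, seed = 9,
               bootstrap = FALSE)
  tr <- grow_tree(d, "y", nodemin = 2)
  set.seed(6)
  q <- d[sample(nrow(d), 20, replace = TRUE), , drop = FALSE]
  for (v in setdiff(names(q), "y")) q[[v]] <- q[[v]] + rnorm(20)
  expect_identical(predict(f, q), predict(tr, q))
})

test_that("a constant response yields constant predictions", {
  d <- data.frame(x1 = rnorm(30), x2 = rnorm(30), y = rep(4.25, 30))
  f <- rforest(y ~ ., d, ntree = 20, mtry = 1, nodemin = 5, seed = 1)
  expect_equal(predict(f, d), rep(4.25, 30))
})

test_that("forest predictions average the trees and stay in the training hull", {
  d <- rand_dyadic_table(42, max_rows = 12, max_pred = 2)
  f <- rforest(y ~ ., d, ntree = 15, mtry = 1, nodemin = 3, seed = 2)
  q <- data.frame(x1 = runif(200, -5, 15), x2 = runif(200, -5, 15))
  q <- q[, names(d)[names(d) != "y"], drop = FALSE]
  per_tree <- vapply(seq_along(f$trees), function(t) {
    g <- f; g$trees <- f$trees[t]
    predict(g, q)
  }, numeric(nrow(q)))
  expect_equal(predict(f, q), rowMeans(per_tree))
  expect_true(all(predict(f, q) >= min(d$y) - 1e-12))
  expect_true(all(predict(f, q) <= max(d$y) + 1e-12))
})

test_that("every query point lands in exactly one leaf of every tree", {
  d <- generate_cohort(cohort_config(n_patients = 30), seed = 3)
  f <- rforest(cbf ~ bfv + age + hct + diabetes + gender, d, ntree = 5,
               mtry = 2, nodemin = 5, seed = 4)
  enc <- flowforest:::encode_frame(d, f$schema$vars, f$schema)
  set.seed(11)
  pts <- enc$X[sample(nrow(enc$X), 1000, replace = TRUE), ]
  pts[, 1:3] <- pts[, 1:3] + rnorm(3000)   # jitter the numeric coordinates
  for (tr in f$trees) {
    counts <- apply(pts, 1, function(x) count_accepting_leaves(tr, x, enc$nlev))
    expect_true(all(counts == 1L))
  }
})

test_that("bootstrap resamples have size N and the expected distinct fraction", {
  n <- 50
  d <- data.frame(x = rnorm(n), y = rnorm(n))
  f <- rforest(y ~ x, d, ntree = 10000, mtry = 1, nodemin = n + 1, seed = 13)
  sizes <- vapply(f$trees, function(tr) length(tr$inbag), 1L)
  expect_true(all(sizes == n))
  distinct <- vapply(f$trees, function(tr) length(unique(tr$inbag)) / n, 0)
  expect_equal(mean(distinct), 1 - (1 - 1 / n)^n, tolerance = 0.005)
})

test_that("the same seed reproduces a forest and trees do not depend on T", {
  d <- generate_cohort(cohort_config(n_patients = 20), seed = 5)
  f1 <- rforest(cbf ~ bfv + age + hct, d, ntree = 10, seed = 99)
  f2 <- rforest(cbf ~ bfv + age + hct, d, ntree = 10, seed = 99)
  expect_identical(f1$trees, f2$trees)
  # per-tree seed streams: the first 5 trees of a 10-tree forest are the
  # 5-tree forest, so results cannot depend on construction order
  f3 <- rforest(cbf ~ bfv + age + hct, d, ntree = 5, seed = 99)
  expect_identical(f1$trees[1:5], f3$trees)
})

test_that("row order does not matter when the fit is deterministic", {
  d <- rand_dyadic_table(8, max_rows = 12, max_pred = 2)
  set.seed(88)
  perm <- sample(nrow(d))
  f1 <- rforest(y ~ ., d, ntree = 3, mtry = 10, nodemin = 2, seed = 1,
                bootstrap = FALSE)
  f2 <- rforest(y ~ ., d[perm, ], ntree = 3, mtry = 10, nodemin = 2, seed = 1,
                bootstrap = FALSE)
  q <- rand_dyadic_table(9, max_rows = 10, max_pred = 2)[names(d)]
  expect_equal(predict(f1, q), predict(f2, q))
})

test_that("a planted-effect cohort is learnable in sample", {
  cfg <- cohort_config(effect = effect_spec(noise_sd = 0.1),
                       n_patients = 60)
  d <- generate_cohort(cfg, seed = 21)
  form <- stats::reformulate(cohort_predictors(), "cbf")
  f <- rforest(form, d, ntree = 100, mtry = 3, nodemin = 5, seed = 22)
  expect_gt(cor(predict(f), d$cbf), 0.9)
  # independent reference ensemble reaches the same regime on the same data
  if (requireNamespace("randomForest", quietly = TRUE)) {
    dd <- d[, c(cohort_predictors(), "cbf")]
    for (v in c("diabetes", "hypertension", "gender")) dd[[v]] <- factor(dd[[v]])
    set.seed(1)
    rf <- randomForest::randomForest(cbf ~ ., dd, ntree = 100)
    expect_gt(cor(predict(rf, dd), dd$cbf), 0.9)
  }
})

test_that("fitting refuses incomplete data and predict refuses missing cells", {
  d <- data.frame(x = c(1, NA, 3, 4, 5), y = 1:5)
  expect_error(rforest(y ~ x, d, ntree = 2), "rf_impute")
  expect_error(grow_tree(d, "y"), "rf_impute")
  d2 <- data.frame(x = 1:5, y = (1:5) / 2)
  f <- rforest(y ~ x, d2, ntree = 2, nodemin = 2, seed = 1)
  expect_error(predict(f, data.frame(x = NA_real_)), "missing")
})

test_that("forests survive a JSON round trip exactly", {
  d <- generate_cohort(cohort_config(n_patients = 15), seed = 7)
  f <- rforest(cbf ~ bfv + age + gender + diabetes, d, ntree = 8, seed = 3)
  path <- tempfile(fileext = ".json")
  write_forest(f, path)
  g <- read_forest(path)
  q <- d[sample(nrow(d), 20, replace = TRUE), ]
  expect_identical(predict(f, q), predict(g, q))
  expect_identical(g$schema$levels$gender, c("F", "M"))
  unlink(path)
})
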