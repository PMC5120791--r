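test_that("the default cohort reproduces the study dimensions", {
  d <- generate_cohort(cohort_config(), seed = 1)
  expect_equal(nrow(d), 261)
  expect_equal(length(unique(d$patient_id)), 88)
  grp <- table(d$group[!duplicated(d$patient_id)])
  expect_equal(as.integer(grp[c("healthy", "HTN", "DM", "DM-HTN")]),
               c(28, 41, 2, 17))
  per_patient <- table(table(d$patient_id))
  expect_equal(as.integer(per_patient[c("1", "2", "3", "4", "5", "6", "8")]),
               c(1, 49, 1, 32, 1, 3, 1))
  expect_equal(sum(!is.na(d$mass_M)), 98)
  expect_equal(sum(!is.na(d$insonation_angle)), 98)
  # fully observed predictors/response before missingness injection
  expect_false(anyNA(d[, c(cohort_predictors(), "cbf")]))
  expect_true(all(d$cbf > 0) && all(d$bfv > 0) && all(d$hct > 0))
})

test_that("generation is deterministic in config and seed", {
  cfg <- cohort_config()
  expect_identical(generate_cohort(cfg, seed = 7), generate_cohort(cfg, seed = 7))
  expect_false(identical(generate_cohort(cfg, seed = 7),
                         generate_cohort(cfg, seed = 8)))
})

test_that("a zero-variance single-patient config hits the configured means", {
  pars <- default_covariate_params()
  for (v in names(pars$side_independent))
    for (g in names(pars$side_independent[[v]]))
      pars$side_independent[[v]][[g]]["sd"] <- 0
  for (v in names(pars$side_dependent))
    for (g in names(pars$side_dependent[[v]]))
      for (s in names(pars$side_dependent[[v]][[g]]))
        pars$side_dependent[[v]][[g]][[s]]["sd"] <- 0
  cfg <- cohort_config(n_patients = 1, measurement_counts = c(`1` = 1),
                       covariate_params = pars,
                       mass_params = c(mean = 270, sd = 0))
  d <- generate_cohort(cfg, seed = 3)
  expect_equal(nrow(d), 1)
  g <- if (d$group == "healthy") "healthy" else "diseased"
  for (v in names(pars$side_independent))
    expect_identical(d[[v]], unname(pars$side_independent[[v]][[g]]["mean"]))
  for (v in c("bfv", "mca_diameter", "cbf"))
    expect_identical(d[[v]], unname(pars$side_dependent[[v]][[g]][[d$side]]["mean"]))
})

test_that("patient structure is consistent across rows", {
  d <- generate_cohort(cohort_config(), seed = 11)
  split_rows <- split(d, d$patient_id)
  for (pd in split_rows) {
    for (v in c("hct", "icv", "height", "bmi", "age", "head_length",
                "diabetes", "hypertension", "gender", "group"))
      expect_equal(length(unique(pd[[v]])), 1)
    expect_false(any(duplicated(pd[, c("side", "visit_id")])))
  }
})

test_that("generated marginals match configured group moments at scale", {
  d <- generate_cohort(cohort_config(n_patients = 600), seed = 19)
  pars <- default_covariate_params()
  dp <- d[!duplicated(d$patient_id), ]
  dp$gclass <- ifelse(dp$group == "healthy", "healthy", "diseased")
  for (v in c("hct", "height", "icv", "bmi")) {
    for (g in c("healthy", "diseased")) {
      x <- dp[[v]][dp$gclass == g]
      mu <- pars$side_independent[[v]][[g]][["mean"]]
      sdv <- pars$side_independent[[v]][[g]][["sd"]]
      expect_lt(abs(mean(x) - mu), 3 * sdv / sqrt(length(x)))
    }
  }
  d$gclass <- ifelse(d$group == "healthy", "healthy", "diseased")
  # repeat visits share a patient-side latent level, so use one (independent)
  # draw per patient-side for the standard error
  d1 <- d[!duplicated(paste(d$patient_id, d$side)), ]
  for (v in c("bfv", "cbf")) {
    for (g in c("healthy", "diseased")) for (s in c("left", "right")) {
      x <- d1[[v]][d1$gclass == g & d1$side == s]
      mu <- pars$side_dependent[[v]][[g]][[s]][["mean"]]
      sdv <- pars$side_dependent[[v]][[g]][[s]][["sd"]]
      expect_lt(abs(mean(x) - mu), 3 * sdv / sqrt(length(x)))
    }
  }
})

test_that("under a null effect no predictor correlates with CBF", {
  cfg <- cohort_config(n_patients = 3400, effect = effect_spec(mode = "null"))
  d <- generate_cohort(cfg, seed = 23)
  expect_gte(nrow(d), 10000)
  expect_lt(abs(cor(d$bfv, d$cbf)), 0.03)
  # independence holds conditionally on clinical group and side (the group
  # itself shifts both CBF and several covariate means, as configured)
  gclass <- ifelse(d$group == "healthy", "healthy", "diseased")
  for (g in c("healthy", "diseased")) for (s in c("left", "right")) {
    sub <- d[gclass == g & d$side == s, ]
    bound <- 4 / sqrt(nrow(sub))
    for (v in cohort_predictors()) {
      x <- sub[[v]]
      if (!is.numeric(x)) x <- as.numeric(factor(x))
      if (sd(x) == 0) next
      expect_lt(abs(cor(x, sub$cbf)), bound)
    }
  }
})

test_that("left and right CBF correlate as configured within a patient", {
  for (rho in c(0.4, 0.75)) {
    cfg <- cohort_config(n_patients = 1500, lr_cbf_correlation = rho,
                         effect = effect_spec(mode = "null"))
    d <- generate_cohort(cfg, seed = 31)
    L <- d[d$side == "left", ]; R <- d[d$side == "right", ]
    m <- match(paste(L$patient_id, L$visit_id), paste(R$patient_id, R$visit_id))
    ok <- !is.na(m)
    expect_gt(sum(ok), 1000)
    expect_lt(abs(cor(L$cbf[ok], R$cbf[m[ok]]) - rho), 0.06)
  }
})

test_that("invalid configurations fail with the offending field named", {
  expect_error(cohort_config(group_proportions = c(healthy = 0.5, HTN = 0.4,
                                                   DM = 0.2, `DM-HTN` = 0.1)),
               "group_proportions")
  expect_error(cohort_config(lr_cbf_correlation = 1.5), "lr_cbf_correlation")
  expect_error(cohort_config(measurement_counts = c(`2` = 10)),
               "measurement_counts")
  pars <- default_covariate_params()
  pars$side_independent$hct$healthy["sd"] <- -1
  expect_error(cohort_config(covariate_params = pars), "sd")
  expect_error(cohort_config(missingness = c(hct = 1.2)), "missingness")
})

test_that("missingness injection honours the probabilities", {
  d <- generate_cohort(cohort_config(), seed = 1)
  expect_identical(inject_missingness(d, spec = c(hct = 0, bfv = 0), seed = 2), d)
  d1 <- inject_missingness(d, spec = c(bfv = 1), seed = 2)
  expect_true(all(is.na(d1$bfv)))
  expect_identical(d1$hct, d$hct)
  expect_error(inject_missingness(d, spec = c(bfv = 1.5)), "\\[0, 1\\]")
  expect_error(inject_missingness(d, spec = c(nope = 0.5)), "nope")
})

test_that("default missingness leaves about 134 of 261 rows complete", {
  q <- unique(default_missingness())
  expect_length(q, 1)
  # binomial oracle: each of the 7 eligible columns keeps a cell with
  # probability 1-q, so a row is complete with (1-q)^7
  expect_equal(261 * (1 - q)^7, 134, tolerance = 1e-9)
  d <- generate_cohort(cohort_config(), seed = 5)
  vars <- c(cohort_predictors(), "cbf")
  complete <- vapply(1:200, function(s)
    sum(complete.cases(inject_missingness(d, seed = s)[, vars])), 1)
  expect_lt(abs(mean(complete) - 134), 10)
  # cbf stays observed: it is the MRI response, present for all rows
  expect_false(anyNA(inject_missingness(d, seed = 9)$cbf))
})

test_that("a user-supplied mask overrides the MCAR mechanism", {
  d <- generate_cohort(cohort_config(n_patients = 10), seed = 2)
  mask <- matrix(FALSE, nrow(d), 1, dimnames = list(NULL, "bfv"))
  mask[1:3, 1] <- TRUE
  d1 <- inject_missingness(d, mask = mask)
  expect_identical(which(is.na(d1$bfv)), 1:3)
})

test_that("the cohort CSV round-trips with L/R sides and empty missing cells", {
  d <- inject_missingness(generate_cohort(cohort_config(n_patients = 12),
                                          seed = 4), seed = 5)
  path <- tempfile(fileext = ".csv")
  write_cohort(d, path)
  hdr <- readLines(path, n = 2)
  expect_identical(hdr[1], paste(cohort_columns(), collapse = ","))
  expect_true(grepl(",(L|R),", hdr[2]))
  back <- read_cohort(path)
  expect_equal(back, d[, cohort_columns()], tolerance = 1e-12)
  unlink(path)
})
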