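#' Predictor and schema helpers for the cohort table
#'
#' The measurement table holds one row per (patient, side, visit) with the 11
#' clinical predictors -- hematocrit, intracranial volume, height, BMI, age,
#' head length, diabetes, hypertension, gender, TCD blood flow velocity and
#' MCA diameter -- and the pCASL CBF response, plus optional territory mass
#' and insonation angle columns used by the Poiseuille estimator.
#'
#' @return `cohort_predictors()`: character vector of the 11 predictor column
#'   names; `cohort_columns()`: the full CSV schema column order.
#' @export
cohort_predictors <- function() {
  c("hct", "icv", "height", "bmi", "age", "head_length",
    "diabetes", "hypertension", "gender", "bfv", "mca_diameter")
}

#' @rdname cohort_predictors
#' @export
cohort_columns <- function() {
  c("patient_id", "side", "visit_id", "hct", "icv", "height", "bmi", "age",
    "head_length", "diabetes", "hypertension", "gender", "bfv",
    "mca_diameter", "mass_M", "insonation_angle", "cbf")
}

# Published cohort moments: mean/sd per clinical group (healthy vs diseased),
# side-dependent variables additionally per insonated side.  Units follow the
# schema: hct %, icv ml, height m, bmi kg/m^2, age years, head_length dm,
# bfv cm/s, mca_diameter mm, cbf ml/min/100g.
default_covariate_params <- function() {
  list(
    side_independent = list(
      hct         = list(healthy = c(mean = 40.6, sd = 3.50),
                         diseased = c(mean = 39.5, sd = 3.12)),
      icv         = list(healthy = c(mean = 1547, sd = 211),
                         diseased = c(mean = 1634, sd = 248)),
      height      = list(healthy = c(mean = 1.67, sd = 0.0954),
                         diseased = c(mean = 1.65, sd = 0.0934)),
      bmi         = list(healthy = c(mean = 25.9, sd = 4.04),
                         diseased = c(mean = 27.3, sd = 5.24)),
      age         = list(healthy = c(mean = 67.7, sd = 8.02),
                         diseased = c(mean = 67.7, sd = 8.02)),
      head_length = list(healthy = c(mean = 1.90, sd = 0.106),
                         diseased = c(mean = 1.92, sd = 0.171))),
    side_dependent = list(
      bfv = list(healthy  = list(left = c(mean = 40.6, sd = 13.5),
                                 right = c(mean = 38.9, sd = 15.9)),
                 diseased = list(left = c(mean = 41.9, sd = 11.9),
                                 right = c(mean = 39.2, sd = 14.0))),
      mca_diameter = list(healthy  = list(left = c(mean = 2.35, sd = 0.388),
                                          right = c(mean = 2.33, sd = 0.309)),
                          diseased = list(left = c(mean = 2.48, sd = 0.261),
                                          right = c(mean = 2.50, sd = 0.258))),
      cbf = list(healthy  = list(left = c(mean = 40.7, sd = 9.27),
                                 right = c(mean = 40.3, sd = 8.86)),
                 diseased = list(left = c(mean = 37.8, sd = 9.25),
                                 right = c(mean = 37.0, sd = 10.2)))))
}

#' Planted predictor-to-CBF effect specification
#'
#' Controls the generative link between the predictors and the CBF response.
#' Under `mode = "null"` CBF is drawn independently of every predictor given
#' clinical group and side, so any apparent predictive skill downstream is
#' spurious. Under `mode = "planted"` the response is a linear combination of
#' standardized predictors plus a per-patient random offset and residual
#' noise, rescaled afterwards to the configured group/side CBF moments.
#'
#' @param mode `"planted"` or `"null"`.
#' @param coefficients named weights on standardized predictors (categorical
#'   predictors enter as standardized indicators of their second level).
#' @param patient_effect_sd dispersion of the shared per-patient offset, in
#'   standardized response units; this is what makes rows of one patient
#'   resemble each other beyond their shared covariates.
#' @param noise_sd residual dispersion, standardized units.
#' @return object of class `"effect_spec"`.
#' @export
effect_spec <- function(mode = c("planted", "null"),
                        coefficients = c(bfv = 1, mca_diameter = 0.5,
                                         hct = 0.4, age = -0.4, icv = 0.3,
                                         bmi = -0.3, height = 0.2,
                                         head_length = 0.1, diabetes = -0.2,
                                         hypertension = -0.2, gender = 0.1),
                        patient_effect_sd = 0.5, noise_sd = 0.5) {
  mode <- match.arg(mode)
  if (patient_effect_sd < 0) stop("effect_spec: patient_effect_sd must be >= 0",
                                  call. = FALSE)
  if (noise_sd < 0) stop("effect_spec: noise_sd must be >= 0", call. = FALSE)
  if (mode == "planted") {
    if (is.null(names(coefficients)) ||
        !all(names(coefficients) %in% cohort_predictors()))
      stop("effect_spec: coefficients must be named after cohort predictors",
           call. = FALSE)
  }
  structure(list(mode = mode, coefficients = coefficients,
                 patient_effect_sd = patient_effect_sd, noise_sd = noise_sd),
            class = "effect_spec")
}

#' Default per-variable missingness probabilities
#'
#' A uniform missing-completely-at-random rate on the seven continuous
#' predictors, calibrated so that a 261-row cohort keeps an expected
#' \eqn{261 \times (134/261) = 134} complete rows: \eqn{q = 1-(134/261)^{1/7}}
#' (about 0.091 per column). Age, the categorical predictors and the CBF
#' response are always observed.
#'
#' @return named numeric vector of per-column missing probabilities.
#' @export
default_missingness <- function() {
  q <- 1 - (134 / 261)^(1 / 7)
  stats::setNames(rep(q, 7),
                  c("hct", "icv", "height", "bmi", "head_length",
                    "bfv", "mca_diameter"))
}

# largest-remainder rounding of nonnegative targets to integers with a fixed
# total; deterministic (ties resolved by position)
largest_remainder <- function(x, total) {
  f <- floor(x)
  rem <- total - sum(f)
  if (rem > 0) {
    ord <- order(-(x - f), seq_along(x))
    f[ord[seq_len(rem)]] <- f[ord[seq_len(rem)]] + 1
  }
  as.integer(f)
}

#' Configure a synthetic cohort
#'
#' Assembles and validates every knob of the cohort generator. The defaults
#' reproduce the structure of the study data: 88 patients contributing 261
#' left/right MCA measurements (measurement-count distribution over patients
#' of 1,49,1,32,1,3,0,1 for 1..8 measurements), clinical group proportions
#' 28/41/2/17 (healthy / hypertensive / diabetic / both) out of 88, published
#' group means and standard deviations for each covariate, and a missingness
#' process leaving about 134 of 261 rows complete.
#'
#' @param n_patients number of patients.
#' @param measurement_counts named integer vector mapping a measurement count
#'   (name) to the number of patients contributing that many measurements;
#'   must total `n_patients`. `NULL` scales the default 88-patient
#'   distribution to `n_patients` by largest-remainder rounding.
#' @param group_proportions named fractions over
#'   `c("healthy","HTN","DM","DM-HTN")`, summing to 1.
#' @param covariate_params nested list of `c(mean, sd)` per variable, per
#'   group and (for side-dependent variables) per side; see
#'   `flowforest:::default_covariate_params()` for the expected shape.
#' @param lr_cbf_correlation within-patient left-right CBF correlation in
#'   \[0, 1\], induced by a shared per-patient latent term whose variance
#'   fraction equals this value (used under the null effect mode).
#' @param visit_sd_fraction fraction of a side-dependent variable's variance
#'   that is redrawn at each visit (the rest is a patient-side latent level),
#'   in \[0, 1\]; governs across-time within-patient resemblance.
#' @param effect an [effect_spec()].
#' @param missingness named per-variable missing probabilities used by
#'   [inject_missingness()]'s default.
#' @param prop_male fraction of male patients.
#' @param mass_angle_rows number of rows for which territory mass and
#'   insonation angle are generated (the rest are left missing); default 98.
#' @param mass_params `c(mean, sd)` of territory mass, grams.
#' @param angle_range insonation-angle range, degrees, within \[0, 90).
#' @param seed default RNG seed used by [generate_cohort()].
#' @return object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_patients = 88,
                          measurement_counts = NULL,
                          group_proportions = c(healthy = 28, HTN = 41,
                                                DM = 2, `DM-HTN` = 17) / 88,
                          covariate_params = default_covariate_params(),
                          lr_cbf_correlation = 0.75,
                          visit_sd_fraction = 0.2,
                          effect = effect_spec(),
                          missingness = default_missingness(),
                          prop_male = 38 / 88,
                          mass_angle_rows = 98,
                          mass_params = c(mean = 270, sd = 30),
                          angle_range = c(0, 40),
                          seed = 1) {
  if (!is.numeric(n_patients) || n_patients < 1)
    stop("cohort_config: n_patients must be a positive count", call. = FALSE)
  n_patients <- as.integer(n_patients)
  if (is.null(measurement_counts)) {
    base <- c(`1` = 1, `2` = 49, `3` = 1, `4` = 32, `5` = 1, `6` = 3,
              `7` = 0, `8` = 1)
    measurement_counts <- stats::setNames(
      largest_remainder(base * n_patients / 88, n_patients), names(base))
  }
  if (is.null(names(measurement_counts)) ||
      anyNA(suppressWarnings(as.integer(names(measurement_counts)))))
    stop("cohort_config: measurement_counts must be named by measurement count",
         call. = FALSE)
  if (sum(measurement_counts) != n_patients)
    stop("cohort_config: measurement_counts must total n_patients", call. = FALSE)
  if (abs(sum(group_proportions) - 1) > 1e-12)
    stop("cohort_config: group_proportions must sum to 1", call. = FALSE)
  if (any(group_proportions < 0))
    stop("cohort_config: group_proportions must be nonnegative", call. = FALSE)
  if (!setequal(names(group_proportions), c("healthy", "HTN", "DM", "DM-HTN")))
    stop("cohort_config: group_proportions must be named healthy, HTN, DM, DM-HTN",
         call. = FALSE)
  sds <- unlist(covariate_params)
  sds <- sds[grepl("\\.sd$", names(sds))]
  if (any(sds < 0))
    stop("cohort_config: covariate_params contains a negative sd", call. = FALSE)
  if (lr_cbf_correlation < 0 || lr_cbf_correlation > 1)
    stop("cohort_config: lr_cbf_correlation must lie in [0, 1]", call. = FALSE)
  if (visit_sd_fraction < 0 || visit_sd_fraction > 1)
    stop("cohort_config: visit_sd_fraction must lie in [0, 1]", call. = FALSE)
  if (!inherits(effect, "effect_spec"))
    stop("cohort_config: effect must be an effect_spec()", call. = FALSE)
  if (any(missingness < 0 | missingness > 1))
    stop("cohort_config: missingness probabilities must lie in [0, 1]",
         call. = FALSE)
  if (prop_male < 0 || prop_male > 1)
    stop("cohort_config: prop_male must lie in [0, 1]", call. = FALSE)
  if (mass_params[["sd"]] < 0)
    stop("cohort_config: mass_params sd must be >= 0", call. = FALSE)
  if (angle_range[1] < 0 || angle_range[2] >= 90 ||
      angle_range[1] > angle_range[2])
    stop("cohort_config: angle_range must lie within [0, 90)", call. = FALSE)
  structure(list(n_patients = n_patients,
                 measurement_counts = measurement_counts,
                 group_proportions = group_proportions,
                 covariate_params = covariate_params,
                 lr_cbf_correlation = lr_cbf_correlation,
                 visit_sd_fraction = visit_sd_fraction,
                 effect = effect, missingness = missingness,
                 prop_male = prop_male,
                 mass_angle_rows = as.integer(mass_angle_rows),
                 mass_params = mass_params, angle_range = angle_range,
                 seed = seed),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  n_rows <- sum(as.integer(names(x$measurement_counts)) * x$measurement_counts)
  cat("Synthetic cohort configuration\n")
  cat("  patients:", x$n_patients, " measurements:", n_rows, "\n")
  cat("  groups:", paste(sprintf("%s %.1f%%", names(x$group_proportions),
                                 100 * x$group_proportions), collapse = ", "), "\n")
  cat("  effect mode:", x$effect$mode,
      " L/R CBF correlation:", x$lr_cbf_correlation, "\n")
  invisible(x)
}

# zero-truncated normal draws; rejection redraw, exact mean when sd = 0
rtrunc0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- x <= 0
    if (!any(bad)) break
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  x
}

#' Generate a synthetic cohort table
#'
#' Draws a fully observed measurement table with the configured structure:
#' patients are assigned to clinical groups in the configured proportions
#' (largest-remainder exact counts, randomly permuted over patients) and to
#' measurement counts from the configured distribution; side-independent
#' covariates are drawn once per patient from zero-truncated normal
#' distributions with the configured group moments; side-dependent variables
#' (velocity, diameter, CBF) combine a patient-side latent level with
#' per-visit redraws; left and right CBF share a per-patient latent term
#' whose variance fraction is `lr_cbf_correlation`. A patient with an odd
#' measurement count lacks one side at the last visit. Under a planted
#' effect, CBF is the configured linear combination of standardized
#' predictors plus patient offset and noise, rescaled to the configured
#' group/side CBF moments.
#'
#' Territory mass and insonation angle are generated for
#' `config$mass_angle_rows` randomly chosen rows and left missing elsewhere;
#' they are inputs to [cbf_tcd()], not part of the predictor set.
#'
#' @param config a [cohort_config()].
#' @param seed RNG seed; `NULL` uses `config$seed`. Identical config and seed
#'   give a bit-identical table.
#' @return data frame with the [cohort_columns()] schema plus a `group`
#'   column; one row per (patient, side, visit).
#' @examples
#' d <- generate_cohort(cohort_config(), seed = 42)
#' nrow(d)           # 261 measurements
#' length(unique(d$patient_id))
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(seed %||% config$seed))
  np <- config$n_patients

  grp_names <- c("healthy", "HTN", "DM", "DM-HTN")
  counts <- largest_remainder(config$group_proportions[grp_names] * np, np)
  group_p <- if (np > 1) sample(rep(grp_names, counts)) else rep(grp_names, counts)
  gclass_p <- ifelse(group_p == "healthy", "healthy", "diseased")
  gender_p <- ifelse(runif(np) < config$prop_male, "M", "F")
  diabetes_p <- ifelse(group_p %in% c("DM", "DM-HTN"), "Y", "N")
  hypertension_p <- ifelse(group_p %in% c("HTN", "DM-HTN"), "Y", "N")

  si <- config$covariate_params$side_independent
  si_draw <- matrix(0, np, length(si), dimnames = list(NULL, names(si)))
  for (v in names(si)) {
    pr <- si[[v]]
    for (g in c("healthy", "diseased")) {
      sel <- gclass_p == g
      si_draw[sel, v] <- rtrunc0(sum(sel), pr[[g]][["mean"]], pr[[g]][["sd"]])
    }
  }

  mc <- rep(as.integer(names(config$measurement_counts)),
            config$measurement_counts)
  mc <- if (np > 1) sample(mc) else mc

  # expand to rows: visits 1..ceiling(k/2), both sides except possibly the last
  pid <- sprintf("P%03d", seq_len(np))
  rows <- vector("list", np)
  for (i in seq_len(np)) {
    k <- mc[i]
    nv <- ceiling(k / 2)
    side <- rep(c("left", "right"), nv)
    visit <- rep(seq_len(nv), each = 2)
    if (k %% 2 == 1) {
      drop_side <- sample(c("left", "right"), 1)
      last <- which(visit == nv & side == drop_side)
      side <- side[-last]; visit <- visit[-last]
    }
    rows[[i]] <- data.frame(patient_id = pid[i], side = side, visit_id = visit,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  n <- nrow(tab)
  pidx <- match(tab$patient_id, pid)

  tab$group <- group_p[pidx]
  gclass_r <- gclass_p[pidx]
  for (v in names(si)) tab[[v]] <- si_draw[, v][pidx]
  tab$diabetes <- diabetes_p[pidx]
  tab$hypertension <- hypertension_p[pidx]
  tab$gender <- gender_p[pidx]

  sd_par <- config$covariate_params$side_dependent
  w <- config$visit_sd_fraction
  ps_key <- paste(tab$patient_id, tab$side)
  ps_levels <- unique(ps_key)
  ps_idx <- match(ps_key, ps_levels)

  moments <- function(v) {
    mu <- numeric(n); sg <- numeric(n)
    for (g in c("healthy", "diseased")) for (s in c("left", "right")) {
      sel <- gclass_r == g & tab$side == s
      mu[sel] <- sd_par[[v]][[g]][[s]][["mean"]]
      sg[sel] <- sd_par[[v]][[g]][[s]][["sd"]]
    }
    list(mu = mu, sg = sg)
  }

  draw_side_dep <- function(v, extra_patient = 0) {
    mm <- moments(v)
    z_p <- rnorm(np)[pidx]
    z_ps <- rnorm(length(ps_levels))[ps_idx]
    z_row <- rnorm(n)
    a_p <- sqrt(extra_patient)
    a_ps <- sqrt((1 - extra_patient) * (1 - w))
    a_row <- sqrt((1 - extra_patient) * w)
    val <- mm$mu + mm$sg * (a_p * z_p + a_ps * z_ps + a_row * z_row)
    for (it in 1:100) {                # re-draw visit noise for nonpositive values
      bad <- val <= 0 & mm$sg > 0
      if (!any(bad)) break
      z_row[bad] <- rnorm(sum(bad))
      val[bad] <- mm$mu[bad] + mm$sg[bad] *
        (a_p * z_p[bad] + a_ps * z_ps[bad] + a_row * z_row[bad])
    }
    val
  }

  tab$bfv <- draw_side_dep("bfv")
  tab$mca_diameter <- draw_side_dep("mca_diameter")

  eff <- config$effect
  if (eff$mode == "null") {
    tab$cbf <- draw_side_dep("cbf", extra_patient = config$lr_cbf_correlation)
  } else {
    std <- function(x) {
      if (is.character(x)) x <- as.numeric(factor(x, levels = sort(unique(x))))
      s <- sd(x)
      if (is.na(s) || s == 0) return(rep(0, length(x)))
      (x - mean(x)) / s
    }
    score <- rep(0, n)
    for (v in names(eff$coefficients))
      score <- score + eff$coefficients[[v]] * std(tab[[v]])
    offset <- rnorm(np, 0, eff$patient_effect_sd)[pidx]
    raw <- score + offset + rnorm(n, 0, eff$noise_sd)
    mm <- moments("cbf")
    s0 <- sd(raw)
    tab$cbf <- if (n < 2 || is.na(s0) || s0 == 0) mm$mu else
      mm$mu + mm$sg * (raw - mean(raw)) / s0
    tab$cbf <- pmax(tab$cbf, .Machine$double.eps)
  }

  tab$mass_M <- NA_real_
  tab$insonation_angle <- NA_real_
  nm <- min(config$mass_angle_rows, n)
  if (nm > 0) {
    sel <- if (n > 1) sample(n, nm) else 1L
    tab$mass_M[sel] <- rtrunc0(nm, config$mass_params[["mean"]],
                               config$mass_params[["sd"]])
    tab$insonation_angle[sel] <- runif(nm, config$angle_range[1],
                                       config$angle_range[2])
  }

  out <- tab[, c(cohort_columns(), "group")]
  rownames(out) <- NULL
  out
}

#' Inject missing values completely at random
#'
#' Sets each eligible cell to `NA` independently with its per-column
#' probability. Cells left observed are untouched. The default probabilities
#' ([default_missingness()]) are calibrated so a default 261-row cohort keeps
#' about 134 complete rows. For missingness mechanisms other than MCAR,
#' supply a precomputed logical `mask` (TRUE = set missing) instead of
#' probabilities.
#'
#' @param table cohort data frame.
#' @param spec named per-column missing probabilities in \[0, 1\].
#' @param seed RNG seed.
#' @param exempt_response keep the `cbf` column fully observed even if named
#'   in `spec`.
#' @param mask optional logical matrix (rows x named columns, column names
#'   required) overriding the MCAR draw.
#' @return the table with `NA`s inserted.
#' @export
inject_missingness <- function(table, spec = default_missingness(), seed = 1,
                               exempt_response = TRUE, mask = NULL) {
  stopifnot(is.data.frame(table))
  if (!is.null(mask)) {
    if (is.null(colnames(mask)) || nrow(mask) != nrow(table))
      stop("mask must be a logical matrix with named columns and one row per table row",
         call. = FALSE)
    for (v in colnames(mask)) table[[v]][mask[, v]] <- NA
    return(table)
  }
  if (any(spec < 0 | spec > 1))
    stop("missingness probabilities must lie in [0, 1]", call. = FALSE)
  bad <- setdiff(names(spec), names(table))
  if (length(bad))
    stop("missingness spec names unknown columns: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (exempt_response) spec <- spec[setdiff(names(spec), "cbf")]
  set.seed(as.integer(seed))
  for (v in names(spec)) {
    hit <- runif(nrow(table)) < spec[[v]]
    table[[v]][hit] <- NA
  }
  table
}

#' Read and write the cohort CSV
#'
#' The on-disk schema is one header row with columns exactly
#' `patient_id, side, visit_id, hct, icv, height, bmi, age, head_length,
#' diabetes, hypertension, gender, bfv, mca_diameter, mass_M,
#' insonation_angle, cbf`; missing cells are empty; `side` uses `L`/`R`;
#' categorical columns use `Y`/`N` and `M`/`F` literals. The in-memory
#' representation spells sides out as `"left"`/`"right"`.
#'
#' @param table cohort data frame (extra columns such as `group` are dropped
#'   on write).
#' @param file path.
#' @return `read_cohort()`: the cohort data frame; `write_cohort()`: `file`,
#'   invisibly.
#' @export
write_cohort <- function(table, file) {
  stopifnot(is.data.frame(table), all(cohort_columns() %in% names(table)))
  out <- table[, cohort_columns()]
  out$side <- unname(c(left = "L", right = "R")[out$side])
  write.csv(out, file, row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(file) {
  cls <- c(patient_id = "character", side = "character", visit_id = "integer",
           hct = "numeric", icv = "numeric", height = "numeric",
           bmi = "numeric", age = "numeric", head_length = "numeric",
           diabetes = "character", hypertension = "character",
           gender = "character", bfv = "numeric", mca_diameter = "numeric",
           mass_M = "numeric", insonation_angle = "numeric", cbf = "numeric")
  tab <- read.csv(file, colClasses = cls, na.strings = "")
  if (!identical(names(tab), cohort_columns()))
    stop("unexpected cohort CSV columns", call. = FALSE)
  tab$side <- unname(c(L = "left", R = "right")[tab$side])
  tab
}
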