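#' Moment-matched log-normal parameters
#'
#' Returns the `meanlog`/`sdlog` of the log-normal distribution whose
#' natural-scale mean and standard deviation equal the supplied values:
#' `sdlog^2 = log(1 + (sd/mean)^2)`, `meanlog = log(mean) - sdlog^2/2`.
#' Used to draw right-skewed variables (triglycerides, glucose) that
#' still reproduce a printed mean +/- SD exactly.
#'
#' @param mean,sd target natural-scale mean and SD, both `> 0`.
#' @return list with `meanlog`, `sdlog`.
#' @export
lognormal_params <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# continuous variables drawn by the copula, in canonical order
.sim_vars <- c("age", "stature_m", "body_mass_kg", "wc_cm", "hc_cm",
               "fm_fraction", "sbp", "dbp", "glucose_mgdl", "tg_mgdl",
               "hdl_mgdl")

#' Default synthetic-cohort specification
#'
#' Parameters of a two-group (MetS-/MetS+) cohort of women with severe
#' obesity: n = 876, target MetS prevalence 0.62, and per-group means
#' and SDs of age, stature, body mass, waist and hip circumference,
#' fat-mass fraction, blood pressures, fasting glucose, triglycerides
#' and HDL-C taken from the descriptive statistics of such a cohort
#' (e.g. MetS+ triglycerides 153.3 +/- 68.4 mg/dL, MetS- HDL-C
#' 56.7 +/- 12.0 mg/dL). Triglycerides and glucose are drawn
#' log-normally (moment-matched) to give the right-skewed, strictly
#' positive distributions typical of lipid panels; all other variables
#' are normal. A single within-group Gaussian-copula correlation matrix
#' couples the variables: strong waist--body-mass (0.8) and waist--hip
#' (0.7) correlations, mild positive correlations (0.1--0.4) elsewhere
#' among the anthropometric and pressure variables, and a negative
#' triglyceride--HDL correlation (-0.3). Physiologic truncation bounds
#' and per-group drug-treatment probabilities complete the spec.
#'
#' @return an object of class `cohort_spec`.
#' @export
default_cohort_spec <- function() {
  gs <- function(means, sds, drug_probs) {
    list(mean = stats::setNames(means, .sim_vars),
         sd = stats::setNames(sds, .sim_vars),
         drug_probs = drug_probs)
  }
  spec <- list(
    n = 876L,
    prevalence_target = 0.62,
    groups = list(
      "MetS-" = gs(
        means = c(47.1, 1.58, 106.4, 116.7, 132.5, 0.509, 124.0, 75.8,
                  82.2, 96.4, 56.7),
        sds = c(15.2, 0.08, 15.8, 11.8, 11.5, 0.056, 14.3, 8.0, 10.7,
                31.0, 12.0),
        drug_probs = c(on_glucose_drug = 0.01, on_bp_drug = 0.20,
                       on_tg_drug = 0.01, on_hdl_drug = 0.01)),
      "MetS+" = gs(
        means = c(55.2, 1.57, 108.7, 123.6, 133.1, 0.510, 130.0, 77.3,
                  106.0, 153.3, 46.1),
        sds = c(11.8, 0.07, 17.7, 12.5, 14.0, 0.055, 13.8, 7.8, 35.0,
                68.4, 11.0),
        drug_probs = c(on_glucose_drug = 0.05, on_bp_drug = 0.65,
                       on_tg_drug = 0.12, on_hdl_drug = 0.02))
    ),
    family = stats::setNames(
      ifelse(.sim_vars %in% c("tg_mgdl", "glucose_mgdl"), "lognormal",
             "normal"), .sim_vars),
    correlation = .default_correlation(),
    bounds = list(age = c(18, 83), stature_m = c(1.30, 2.00),
                  body_mass_kg = c(60, 250), wc_cm = c(60, 200),
                  hc_cm = c(70, 220), fm_fraction = c(0.20, 0.75),
                  sbp = c(80, 250), dbp = c(40, 150),
                  glucose_mgdl = c(40, 500), tg_mgdl = c(30, 1000),
                  hdl_mgdl = c(5, 150)),
    max_resample = 1000L
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
}

.default_correlation <- function() {
  k <- length(.sim_vars)
  r <- diag(k)
  dimnames(r) <- list(.sim_vars, .sim_vars)
  set_r <- function(a, b, value) {
    r[a, b] <<- value
    r[b, a] <<- value
  }
  set_r("body_mass_kg", "wc_cm", 0.8)
  set_r("wc_cm", "hc_cm", 0.7)
  set_r("body_mass_kg", "hc_cm", 0.4)
  set_r("body_mass_kg", "stature_m", 0.3)
  set_r("body_mass_kg", "fm_fraction", 0.4)
  set_r("wc_cm", "fm_fraction", 0.3)
  set_r("hc_cm", "fm_fraction", 0.3)
  set_r("sbp", "dbp", 0.4)
  set_r("age", "sbp", 0.3)
  set_r("age", "glucose_mgdl", 0.2)
  set_r("wc_cm", "sbp", 0.2)
  set_r("wc_cm", "glucose_mgdl", 0.2)
  set_r("wc_cm", "tg_mgdl", 0.2)
  set_r("glucose_mgdl", "tg_mgdl", 0.2)
  set_r("tg_mgdl", "hdl_mgdl", -0.3)
  r
}

#' Validate a cohort specification
#'
#' Checks group parameters (positive SDs, probabilities in \[0, 1\],
#' log-normal families only on strictly positive variables), the
#' correlation matrix (symmetric, unit diagonal, positive
#' semi-definite) and the prevalence target.
#'
#' @param spec a `cohort_spec`.
#' @return `spec`, invisibly validated.
#' @export
validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!(spec$prevalence_target > 0 && spec$prevalence_target < 1)) {
    stop("prevalence_target must lie strictly in (0, 1)", call. = FALSE)
  }
  for (g in names(spec$groups)) {
    grp <- spec$groups[[g]]
    if (any(grp$sd <= 0)) {
      stop(sprintf("group '%s' has non-positive SDs", g), call. = FALSE)
    }
    if (any(grp$drug_probs < 0 | grp$drug_probs > 1)) {
      stop(sprintf("group '%s' drug probabilities outside [0, 1]", g),
           call. = FALSE)
    }
    ln <- names(spec$family)[spec$family == "lognormal"]
    if (any(grp$mean[ln] <= 0)) {
      stop("log-normal family requires strictly positive means",
           call. = FALSE)
    }
  }
  r <- spec$correlation
  if (!isSymmetric(unname(r)) || any(abs(diag(r) - 1) > 1e-12)) {
    stop("correlation matrix must be symmetric with unit diagonal",
         call. = FALSE)
  }
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("correlation matrix is not positive semi-definite",
         call. = FALSE)
  }
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort spec: n = %d, target MetS prevalence %.2f\n  groups: %s; %d continuous variables (%s log-normal)\n",
    x$n, x$prevalence_target, paste(names(x$groups), collapse = ", "),
    length(.sim_vars),
    paste(names(x$family)[x$family == "lognormal"], collapse = ", ")))
  invisible(x)
}

#' Simulate a synthetic two-group cohort
#'
#' Draws group membership Bernoulli(`prevalence_target`), then the
#' continuous variables of each subject from the group's Gaussian
#' copula: correlated standard normals (Cholesky factor of the shared
#' correlation matrix) pushed through the per-variable marginal (normal
#' or moment-matched log-normal). Subjects falling outside the
#' physiologic bounds are redrawn whole (resampling, not clipping, so
#' distributional shape is preserved), up to `spec$max_resample`
#' attempts. Drug flags are Bernoulli per group. Fat mass in kg is
#' derived as `fm_fraction * body_mass_kg`. The same seed always
#' reproduces the identical cohort.
#'
#' @param spec a `cohort_spec`, e.g. [default_cohort_spec()].
#' @param seed integer seed; all randomness flows from it.
#' @return a data.frame in the canonical cohort schema plus a final
#'   `latent_group` column holding the generating group (`"MetS-"` /
#'   `"MetS+"`). The latent group is the simulation truth; downstream
#'   evaluation labels should come from [classify_mets()] on the
#'   generated measurements.
#' @export
simulate_cohort <- function(spec, seed) {
  validate_cohort_spec(spec)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  n <- spec$n
  in_plus <- stats::rbinom(n, 1L, spec$prevalence_target) == 1L
  group <- ifelse(in_plus, "MetS+", "MetS-")
  chol_r <- chol(spec$correlation)
  k <- length(.sim_vars)
  x <- matrix(NA_real_, n, k, dimnames = list(NULL, .sim_vars))
  flags <- matrix(FALSE, n, length(.drug_columns),
                  dimnames = list(NULL, .drug_columns))
  for (g in names(spec$groups)) {
    idx <- which(group == g)
    if (!length(idx)) next
    x[idx, ] <- .draw_group(length(idx), spec, g, chol_r)
    grp <- spec$groups[[g]]
    for (fl in .drug_columns) {
      flags[idx, fl] <- stats::runif(length(idx)) < grp$drug_probs[[fl]]
    }
  }
  cohort <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = x[, "age"], stature_m = x[, "stature_m"],
    body_mass_kg = x[, "body_mass_kg"], wc_cm = x[, "wc_cm"],
    hc_cm = x[, "hc_cm"],
    fm_kg = x[, "fm_fraction"] * x[, "body_mass_kg"],
    sbp = x[, "sbp"], dbp = x[, "dbp"],
    glucose_mgdl = x[, "glucose_mgdl"], tg_mgdl = x[, "tg_mgdl"],
    hdl_mgdl = x[, "hdl_mgdl"],
    stringsAsFactors = FALSE
  )
  for (fl in .drug_columns) cohort[[fl]] <- flags[, fl]
  cohort$latent_group <- group
  validate_cohort(cohort)
}

# draw m subjects of group g, resampling out-of-bounds rows whole
.draw_group <- function(m, spec, g, chol_r) {
  grp <- spec$groups[[g]]
  k <- length(.sim_vars)
  draw <- function(rows) {
    z <- matrix(stats::rnorm(rows * k), rows, k) %*% chol_r
    out <- matrix(NA_real_, rows, k, dimnames = list(NULL, .sim_vars))
    for (j in seq_len(k)) {
      v <- .sim_vars[j]
      if (spec$family[[v]] == "lognormal") {
        p <- lognormal_params(grp$mean[[v]], grp$sd[[v]])
        out[, j] <- exp(p$meanlog + p$sdlog * z[, j])
      } else {
        out[, j] <- grp$mean[[v]] + grp$sd[[v]] * z[, j]
      }
    }
    out
  }
  in_bounds <- function(mat) {
    ok <- rep(TRUE, nrow(mat))
    for (v in names(spec$bounds)) {
      b <- spec$bounds[[v]]
      ok <- ok & mat[, v] >= b[1] & mat[, v] <= b[2]
    }
    ok
  }
  x <- draw(m)
  bad <- which(!in_bounds(x))
  attempts <- 0L
  while (length(bad)) {
    attempts <- attempts + 1L
    if (attempts > spec$max_resample) {
      stop(sprintf(
        "group '%s': %d subject(s) still out of bounds after %d resampling rounds",
        g, length(bad), spec$max_resample), call. = FALSE)
    }
    x[bad, ] <- draw(length(bad))
    bad <- bad[!in_bounds(x[bad, , drop = FALSE])]
  }
  x
}

#' Parameter-recovery check for a simulated cohort
#'
#' Compares per-group, per-variable sample means of a simulated cohort
#' against the generating spec: z = (sample mean - spec mean) /
#' (spec SD / sqrt(n_group)), passing when |z| does not exceed
#' `tolerance_multiplier`. The fat-mass fraction is recovered from
#' `fm_kg / body_mass_kg`. A group absent from the cohort is reported
#' as such rather than raising an error.
#'
#' @param cohort data.frame from [simulate_cohort()] (needs the
#'   `latent_group` column, or supply `group`).
#' @param spec the generating `cohort_spec`.
#' @param tolerance_multiplier maximum tolerated |z|; default 4.
#' @param group optional group labels overriding `cohort$latent_group`.
#' @return data.frame with `group`, `variable`, `n`, `sample_mean`,
#'   `spec_mean`, `z`, `pass`.
#' @export
spec_recovery_check <- function(cohort, spec, tolerance_multiplier = 4,
                                group = cohort$latent_group) {
  validate_cohort_spec(spec)
  if (is.null(group)) {
    stop("cohort has no latent_group column and no group was supplied",
         call. = FALSE)
  }
  vals <- cohort
  vals$fm_fraction <- cohort$fm_kg / cohort$body_mass_kg
  rows <- list()
  for (g in names(spec$groups)) {
    idx <- which(group == g)
    grp <- spec$groups[[g]]
    for (v in .sim_vars) {
      if (!length(idx)) {
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, variable = v, n = 0L, sample_mean = NA_real_,
          spec_mean = grp$mean[[v]], z = NA_real_, pass = NA,
          stringsAsFactors = FALSE)
        next
      }
      sm <- mean(vals[[v]][idx])
      z <- (sm - grp$mean[[v]]) /
        (grp$sd[[v]] / sqrt(length(idx)))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, variable = v, n = length(idx), sample_mean = sm,
        spec_mean = grp$mean[[v]], z = z,
        pass = abs(z) <= tolerance_multiplier, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
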