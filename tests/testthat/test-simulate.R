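test_that("default spec transcribes the two-group summary statistics", {
  spec <- default_cohort_spec()
  expect_equal(spec$n, 876L)
  expect_equal(spec$prevalence_target, 0.62)
  expect_equal(spec$groups[["MetS+"]]$mean[["tg_mgdl"]], 153.3)
  expect_equal(spec$groups[["MetS+"]]$sd[["tg_mgdl"]], 68.4)
  expect_equal(spec$groups[["MetS-"]]$mean[["hdl_mgdl"]], 56.7)
  expect_equal(spec$groups[["MetS-"]]$mean[["glucose_mgdl"]], 82.2)
  expect_equal(spec$groups[["MetS+"]]$mean[["wc_cm"]], 123.6)
  # correlation matrix is a valid PSD correlation matrix
  r <- spec$correlation
  expect_true(isSymmetric(unname(r)))
  expect_equal(unname(diag(r)), rep(1, nrow(r)))
  expect_gte(min(eigen(r, symmetric = TRUE,
                       only.values = TRUE)$values), 0)
})

test_that("invalid specs are rejected before sampling", {
  spec <- default_cohort_spec()
  spec$correlation["tg_mgdl", "hdl_mgdl"] <- 0.9  # breaks symmetry
  expect_error(simulate_cohort(spec, 1), "symmetric")
  spec2 <- default_cohort_spec()
  spec2$groups[["MetS+"]]$sd[["age"]] <- 0
  expect_error(simulate_cohort(spec2, 1), "non-positive SDs")
  spec3 <- default_cohort_spec()
  spec3$prevalence_target <- 1
  expect_error(simulate_cohort(spec3, 1), "prevalence")
  spec4 <- default_cohort_spec()
  k <- nrow(spec4$correlation)
  spec4$correlation[] <- matrix(-0.5, k, k) + 1.5 * diag(k)
  expect_error(simulate_cohort(spec4, 1),
               "positive semi-definite")
})

test_that("log-normal moment matching is exact analytically", {
  for (ms in list(c(153.3, 68.4), c(96.4, 31.0), c(106.0, 35.0),
                  c(82.2, 10.7))) {
    p <- lognormal_params(ms[1], ms[2])
    mean_back <- exp(p$meanlog + p$sdlog^2 / 2)
    var_back <- (exp(p$sdlog^2) - 1) * exp(2 * p$meanlog + p$sdlog^2)
    expect_equal(mean_back, ms[1], tolerance = 1e-9)
    expect_equal(sqrt(var_back), ms[2], tolerance = 1e-9)
  }
})

test_that("a fixed seed reproduces the identical cohort and CSV bytes", {
  spec <- default_cohort_spec()
  spec$n <- 150L
  a <- simulate_cohort(spec, seed = 99)
  b <- simulate_cohort(spec, seed = 99)
  expect_identical(a, b)
  c <- simulate_cohort(spec, seed = 100)
  expect_false(identical(a, c))

  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_cohort(a, f1, comments = "seed: 99")
  write_cohort(b, f2, comments = "seed: 99")
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("near-degenerate noise collapses sample means onto spec means", {
  spec <- default_cohort_spec()
  spec$n <- 60L
  for (g in names(spec$groups)) {
    spec$groups[[g]]$sd[] <- 1e-9
  }
  co <- simulate_cohort(spec, seed = 7)
  for (g in names(spec$groups)) {
    idx <- co$latent_group == g
    if (!any(idx)) next
    means <- spec$groups[[g]]$mean
    expect_lt(abs(mean(co$tg_mgdl[idx]) - means[["tg_mgdl"]]), 1e-6)
    expect_lt(abs(mean(co$wc_cm[idx]) - means[["wc_cm"]]), 1e-6)
    expect_lt(abs(mean(co$stature_m[idx]) - means[["stature_m"]]),
              1e-6)
  }
})

test_that("default cohort recovers the generating group means within CLT bounds", {
  co <- simulate_cohort(default_cohort_spec(), seed = 20240401)
  report <- spec_recovery_check(co, default_cohort_spec(),
                                tolerance_multiplier = 4)
  expect_true(all(report$pass, na.rm = TRUE))
  expect_equal(nrow(report), 22L)  # 2 groups x 11 variables

  # a 10-SE shift on one variable must be flagged
  shifted <- default_cohort_spec()
  n_plus <- sum(co$latent_group == "MetS+")
  shifted$groups[["MetS+"]]$mean[["wc_cm"]] <-
    shifted$groups[["MetS+"]]$mean[["wc_cm"]] +
    10 * shifted$groups[["MetS+"]]$sd[["wc_cm"]] / sqrt(n_plus)
  bad <- spec_recovery_check(co, shifted, tolerance_multiplier = 4)
  expect_false(bad$pass[bad$group == "MetS+" &
                          bad$variable == "wc_cm"])

  # zero tolerance fails on nondegenerate data
  strict <- spec_recovery_check(co, default_cohort_spec(),
                                tolerance_multiplier = 0)
  expect_false(all(strict$pass))
})

test_that("generated cohorts respect physiologic bounds and schema", {
  spec <- default_cohort_spec()
  spec$n <- 400L
  co <- simulate_cohort(spec, seed = 3)
  expect_s3_class(validate_cohort(co), "data.frame")
  for (v in names(spec$bounds)) {
    col <- if (v == "fm_fraction") co$fm_kg / co$body_mass_kg else
      co[[v]]
    expect_gte(min(col), spec$bounds[[v]][1])
    expect_lte(max(col), spec$bounds[[v]][2])
  }
  expect_equal(nrow(co), 400L)
  expect_true(all(co$latent_group %in% c("MetS-", "MetS+")))
})

test_that("classifier labels agree with the latent groups on the default spec", {
  co <- simulate_cohort(default_cohort_spec(), seed = 1)
  cls <- classify_mets(co)
  agreement <- mean((co$latent_group == "MetS+") == cls$mets)
  expect_gte(agreement, 0.8)
  # MetS+ group has the higher mean TG by construction
  tab <- group_descriptives(co, co$latent_group,
                            variables = "tg_mgdl")
  expect_gt(tab[["mean_MetS+"]], tab[["mean_MetS-"]])
})
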