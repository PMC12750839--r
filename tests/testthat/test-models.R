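test_that("noiseless synthetic data is fitted exactly", {
  cfg <- cohort_config(n = 200, seed = 51, school_sd = 0, noise_sd = 0,
                       prob_gender = c(male = 0.5, female = 0.5, other = 0))
  coh <- generate_cohort(cfg)
  for (pv in c("sleep", "lpa")) {
    # a perfect fit makes summary.lm warn; that is the scenario under test
    m <- suppressWarnings(
      fit_composition_model(coh$data, "happiness", pivot = pv))
    b <- rotate_basis(pivot = pv)
    truth <- true_ilr_beta(cfg, "happiness", b)
    est <- m$coefficients$estimate[match(paste0("z", 1:3),
                                         m$coefficients$term)]
    expect_equal(est, unname(truth), tolerance = 1e-8)
    expect_equal(m$r2, 1, tolerance = 1e-8)
    ct <- m$coefficients
    expect_equal(ct$estimate[ct$term == "age"], cfg$beta_age,
                 tolerance = 1e-8)
    expect_equal(ct$estimate[ct$term == "genderfemale"], cfg$beta_gender,
                 tolerance = 1e-8)
  }
})

test_that("OLS estimates match the normal-equations oracle on a small fixture", {
  set.seed(52)
  coh <- toy_cohort(n = 30, seed = 52,
                    prob_gender = c(male = 0.5, female = 0.5, other = 0))
  d <- coh$data
  m <- fit_composition_model(d, "optimism", pivot = "sed")
  Z <- ilr_pivot(d[, mb_parts()], rotate_basis(pivot = "sed"))
  X <- cbind(1, Z, d$age, as.numeric(d$gender == "female"))
  expect_equal(m$coefficients$estimate, oracle_ols(X, d$optimism),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("cluster-robust covariance matches the hand-built CR1 sandwich", {
  coh <- toy_cohort(n = 70, seed = 53)
  d <- coh$data[coh$data$gender %in% c("male", "female"), ]
  m <- fit_composition_model(d, "happiness")
  X <- stats::model.matrix(m$fit)
  vc <- oracle_cluster_vcov(X, m$residuals, as.character(d$school))
  expect_equal(unname(m$vcov_cluster), unname(vc), tolerance = 1e-10)
  expect_true(isSymmetric(m$vcov_cluster))
  expect_true(min(eigen(m$vcov_cluster, symmetric = TRUE,
                        only.values = TRUE)$values) >= -1e-10)
})

test_that("with singleton clusters the sandwich reduces to the HC analogue", {
  coh <- toy_cohort(n = 40, seed = 54,
                    prob_gender = c(male = 0.5, female = 0.5, other = 0))
  d <- coh$data
  d$school <- factor(seq_len(nrow(d)))  # one participant per cluster
  m <- fit_composition_model(d, "happiness")
  X <- stats::model.matrix(m$fit)
  e <- m$residuals
  n <- nrow(X); k <- ncol(X)
  bread <- solve(crossprod(X))
  meat <- crossprod(X * e)
  hc1 <- (n / (n - 1)) * ((n - 1) / (n - k)) * bread %*% meat %*% bread
  expect_equal(unname(m$vcov_cluster), unname(hc1), tolerance = 1e-10)
})

test_that("fit statistics are invariant across the four pivot rotations", {
  coh <- toy_cohort(n = 90, seed = 55)
  rot <- fit_rotations(coh$data, "happiness")
  ms <- rot$models
  for (pv in mb_parts()[-1]) {
    expect_equal(ms[[pv]]$r2, ms$sleep$r2, tolerance = 1e-8)
    expect_equal(ms[[pv]]$model_p, ms$sleep$model_p, tolerance = 1e-8)
    expect_equal(ms[[pv]]$fitted, ms$sleep$fitted, tolerance = 1e-8)
    expect_equal(ms[[pv]]$residuals, ms$sleep$residuals, tolerance = 1e-8)
  }
  expect_equal(nrow(rot$table), 4)
  expect_equal(rot$table$label[rot$table$pivot == "lpa"],
               "LPA vs. (Sleep + SED + MVPA)")
  expect_equal(rot$table$label[rot$table$pivot == "mvpa"],
               "MVPA vs. (Sleep + SED + LPA)")
})

test_that("sign recovery: the calibrated LPA effect surfaces in the LPA row", {
  cfg <- cohort_config(n = 600, seed = 56, n_schools = 12)
  coh <- generate_cohort(cfg)
  rot <- fit_rotations(coh$data, "happiness")
  lpa <- rot$table[rot$table$pivot == "lpa", ]
  expect_gt(lpa$beta, 0)
  expect_lt(lpa$p, 0.05)
  sed <- rot$table[rot$table$pivot == "sed", ]
  expect_lt(sed$beta, 0)
})

test_that("degenerate designs raise informative errors", {
  coh <- toy_cohort(n = 40, seed = 57)
  d <- coh$data
  d1 <- d; d1$gender <- "male"
  expect_error(fit_composition_model(d1, "happiness"), "gender")
  d2 <- d; d2$school <- "s1"
  expect_error(fit_composition_model(d2, "happiness"), "clusters")
  d3 <- d[d$gender %in% c("male", "female"), ]
  d3$age2 <- d3$age
  expect_error(
    fit_composition_model(d3, "happiness", covariates = c("age", "age2", "gender")),
    "collinear")
  expect_error(fit_composition_model(d[1:6, ], "happiness"), "few")
})

test_that("participants outside the two modelled gender levels are dropped", {
  coh <- toy_cohort(n = 80, seed = 58)
  n_other <- sum(!coh$data$gender %in% c("male", "female"))
  m <- fit_composition_model(coh$data, "happiness")
  expect_equal(m$n_dropped_gender, n_other)
  expect_equal(m$n_used, 80 - n_other)
})

test_that("diagnostics behave on calibrated and pathological inputs", {
  coh <- toy_cohort(n = 100, seed = 59)
  m <- fit_composition_model(coh$data, "connectedness")
  dg <- model_diagnostics(m)
  expect_true(is.finite(dg$shapiro$p.value))
  expect_true(is.finite(dg$bp$p.value))
  expect_false(dg$collinear)

  # Gaussian residuals: normality rarely flagged
  flags <- vapply(1:40, function(i) {
    coh_i <- toy_cohort(n = 60, seed = 600 + i)
    model_diagnostics(fit_composition_model(coh_i$data, "optimism"))$nonnormal
  }, logical(1))
  expect_lt(mean(flags), 0.25)

  # strongly heteroscedastic noise is usually flagged
  het <- vapply(1:20, function(i) {
    coh_i <- toy_cohort(n = 150, seed = 700 + i, noise_sd = 0)
    d <- coh_i$data
    set.seed(800 + i)
    scale <- (d$age - min(d$age) + 0.2)
    d$happiness <- d$happiness + rnorm(nrow(d), 0, 0.4 * scale)
    model_diagnostics(fit_composition_model(d, "happiness"))$heteroscedastic
  }, logical(1))
  expect_gt(mean(het), 0.5)
})
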