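test_that("noise-free balanced data is reproduced exactly", {
  d <- make_balanced(n_acc = 2, n_yr = 2, mu = 100,
                     g = c(0, 3), a = c(-1, 1), e_sd = 0)
  fit <- fit_mixed(d, "value", fixed = "accession_id", random = "year")
  # BLUE difference equals the observed mean difference
  expect_equal(diff(fit$fixed_effects$estimate), 3, tolerance = 1e-6)
  # residual variance at the boundary (zero up to the numerical floor)
  expect_lt(fit$residual_variances$variance, 1e-3 * var(d$value))
  expect_lt(max(abs(fit$residuals$residual)), 1e-3)
})

test_that("balanced one-way random layout matches closed-form ANOVA estimators", {
  withr::with_seed(42, {
    n_g <- 8; n_r <- 6
    d <- tidyr::expand_grid(grp = sprintf("G%d", 1:n_g), rep = 1:n_r)
    d$value <- 50 + rnorm(n_g, 0, 4)[match(d$grp, sprintf("G%d", 1:n_g))] +
      rnorm(nrow(d), 0, 2)
  })
  fit <- fit_mixed(d, "value", fixed = NULL, random = "grp")
  # closed form: sigma2_e = MSE, sigma2_g = (MSA - MSE) / n_r
  m <- anova(lm(value ~ grp, data = d))
  mse <- m["Residuals", "Mean Sq"]
  msa <- m["grp", "Mean Sq"]
  expect_equal(fit$residual_variances$variance, mse, tolerance = 1e-4)
  expect_equal(fit$variance_components$variance, max((msa - mse) / n_r, 0),
               tolerance = 1e-4)
})

test_that("homogeneous unbalanced fit agrees with lme4", {
  skip_if_not_installed("lme4")
  d <- make_balanced(n_acc = 25, n_yr = 7, e_sd = 2, seed = 5)
  d <- d[withr::with_seed(6, runif(nrow(d))) > 0.35, ]
  fit <- fit_mixed(d, "value", fixed = "accession_id", random = "year")
  lf <- lme4::lmer(value ~ 0 + accession_id + (1 | year), data = d,
                   REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$variance_components$variance, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$residual_variances$variance, vc$vcov[2], tolerance = 1e-4)
  expect_equal(fit$logLik, as.numeric(stats::logLik(lf)), tolerance = 1e-6)
  expect_equal(unname(fit$fixed_effects$estimate),
               unname(lme4::fixef(lf)), tolerance = 1e-5)
  expect_equal(unname(fit$fixed_effects$se),
               unname(sqrt(diag(as.matrix(stats::vcov(lf))))),
               tolerance = 1e-4)
})

test_that("year-heterogeneous fit agrees with nlme varIdent", {
  skip_if_not_installed("nlme")
  withr::with_seed(7, {
    d <- tidyr::expand_grid(accession_id = sprintf("A%02d", 1:20),
                            year = factor(2001:2005))
    d$value <- 50 +
      rnorm(20, 0, 3)[match(d$accession_id, sprintf("A%02d", 1:20))] +
      rnorm(5, 0, 5)[as.integer(d$year)] +
      rnorm(nrow(d), 0, c(1, 2, 0.5, 3, 1.5)[as.integer(d$year)])
  })
  fit <- fit_mixed(d, "value", fixed = "accession_id", random = "year",
                   residual_by = "year")
  lf <- nlme::lme(value ~ 0 + accession_id, random = ~ 1 | year, data = d,
                  weights = nlme::varIdent(form = ~ 1 | year),
                  method = "REML",
                  control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                             msMaxIter = 200))
  w <- coef(lf$modelStruct$varStruct, unconstrained = FALSE, allCoef = TRUE)
  s2_nlme <- (lf$sigma * w[levels(d$year)])^2
  expect_equal(fit$variance_components$variance,
               as.numeric(nlme::VarCorr(lf)[1, 1]), tolerance = 1e-2)
  expect_equal(fit$residual_variances$variance, unname(s2_nlme),
               tolerance = 2e-2)
  expect_equal(unname(fit$fixed_effects$estimate),
               unname(nlme::fixef(lf)), tolerance = 1e-2)
})

test_that("BLUEs are translation-equivariant", {
  d <- make_balanced(n_acc = 15, n_yr = 5, e_sd = 1.5, seed = 8)
  d <- d[withr::with_seed(9, runif(nrow(d))) > 0.3, ]
  b1 <- estimate_blues(d)$blues
  d2 <- dplyr::mutate(d, value = value + 37.5)
  b2 <- estimate_blues(d2)$blues
  expect_equal(b2$blue, b1$blue + 37.5, tolerance = 1e-8)
})

test_that("a single residual group reproduces the homogeneous fit", {
  d <- make_balanced(n_acc = 12, n_yr = 5, e_sd = 2, seed = 10)
  d$one <- "all"
  f1 <- fit_mixed(d, "value", fixed = "accession_id", random = "year")
  f2 <- fit_mixed(d, "value", fixed = "accession_id", random = "year",
                  residual_by = "one")
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-6)
  expect_equal(f1$residual_variances$variance, f2$residual_variances$variance,
               tolerance = 1e-6)
  expect_equal(f1$fixed_effects$estimate, f2$fixed_effects$estimate,
               tolerance = 1e-7)
})

test_that("restricted likelihood is non-decreasing over iterations", {
  sim <- simulate_historical(n_accessions = 120, years = 1991:2005,
                             years_observed = 5, seed = 12)
  fit <- fit_mixed(sim$data$records, "value", fixed = "accession_id",
                   random = "year", residual_by = "year")
  tr <- fit$convergence$trajectory
  expect_true(all(diff(tr) > -1e-6 * (abs(tr[-length(tr)]) + 1)))
  expect_true(fit$convergence$converged)
})

test_that("non-convergence raises an error carrying the trajectory", {
  d <- make_balanced(n_acc = 20, n_yr = 6, e_sd = 2, seed = 13)
  err <- tryCatch(
    fit_mixed(d, "value", fixed = "accession_id", random = "year",
              max_iter = 3),
    histphen_no_convergence = function(e) e)
  expect_s3_class(err, "histphen_no_convergence")
  expect_length(err$trajectory, 3L)
})

test_that("disconnected accession x year designs are reported", {
  d1 <- make_balanced(n_acc = 6, n_yr = 3, e_sd = 1, seed = 14)
  d2 <- make_balanced(n_acc = 6, n_yr = 3, e_sd = 1, seed = 15)
  d2$accession_id <- sub("^A0", "B0", d2$accession_id)
  d2$year <- d2$year + 10L
  expect_warning(
    fit_mixed(dplyr::bind_rows(d1, d2), "value", fixed = "accession_id",
              random = "year"),
    "disconnected")
})

test_that("entry-mean heritability matches the printed worked examples", {
  # after-correction components (FT, PH, TGW)
  expect_equal(round(heritability(15.62, 6.48, 5.09), 2), 0.92)
  expect_equal(round(heritability(346.72, 98.53, 5.04), 2), 0.95)
  expect_equal(round(heritability(29.67, 13.76, 4.30), 2), 0.90)
  # before-correction components
  expect_equal(round(heritability(15.23, 9.08, 5.13), 2), 0.90)
  expect_equal(round(heritability(342.15, 102.62, 5.05), 2), 0.94)
  expect_equal(round(heritability(28.98, 16.13, 4.42), 2), 0.89)
  # degenerate and invalid input
  expect_equal(heritability(0, 5, 3), 0)
  expect_error(heritability(-1, 5, 3), "non-negative")
  expect_error(heritability(1, 5, 0), "positive")
})

test_that("studentized residuals are calibrated and catch a gross contaminant", {
  sim <- simulate_historical(n_accessions = 120, years = 2001:2006,
                             years_observed = 5, seed = 16)
  rec <- sim$data$records
  fit <- fit_mixed(rec, "value", fixed = "accession_id", random = "year",
                   residual_by = "year")
  st <- studentized_residuals(fit)
  expect_equal(nrow(st), nrow(rec))
  expect_gt(sd(st$studentized), 0.9)
  expect_lt(sd(st$studentized), 1.1)

  # a 10-sigma shift on one record must give the largest |studentized|
  s2 <- sim$truth$year_effects$sigma2_e[match(rec$year[100],
                                              sim$truth$year_effects$year)]
  rec$value[100] <- rec$value[100] + 10 * sqrt(s2)
  fit2 <- fit_mixed(rec, "value", fixed = "accession_id", random = "year",
                    residual_by = "year")
  st2 <- studentized_residuals(fit2)
  expect_equal(which.max(abs(st2$studentized)), 100L)
})

test_that("multi-factor validation-trial model recovers a zero interaction", {
  boundary <- vapply(1:10, function(s) {
    gen <- withr::with_seed(100 + s, tibble::tibble(
      accession_id = sprintf("A%02d", 1:30),
      genotypic_value = 100 + rnorm(30, 0, 4)))
    d <- simulate_validation(gen, n_env = 3, n_trials = 2, n_reps = 2,
                             n_blocks = 3, sigma2_gxe = 0, seed = 200 + s)
    fit <- fit_mixed(d, "value", fixed = "accession_id",
                     random = c("environment", "accession_id:environment",
                                "environment:trial",
                                "environment:trial:replicate",
                                "environment:trial:replicate:block"))
    v <- fit$variance_components
    gxe <- v$variance[v$term == "accession_id:environment"]
    gxe < 0.1 * mean_residual_variance(fit)
  }, logical(1))
  expect_gte(sum(boundary), 8L)
})

test_that("estimate_blues: single-year and orthogonal reductions", {
  # single year: BLUEs equal the observations (each accession seen once)
  d <- make_balanced(n_acc = 20, n_yr = 1, e_sd = 1, seed = 17)
  b <- estimate_blues(d, heterogeneous = FALSE)$blues
  dev <- b$blue - d$value[match(b$accession_id, d$accession_id)]
  expect_lt(max(dev) - min(dev), 1e-6)
  expect_true(all(b$n_years == 1L))

  # balanced design, homogeneous residuals: GLS reduces to OLS, so BLUEs
  # equal accession means up to a common constant
  d2 <- make_balanced(n_acc = 20, n_yr = 5, e_sd = 1.5, seed = 18)
  b2 <- estimate_blues(d2, heterogeneous = FALSE)$blues
  am <- tapply(d2$value, d2$accession_id, mean)
  dev2 <- b2$blue - am[b2$accession_id]
  expect_lt(max(dev2) - min(dev2), 1e-6)
})

test_that("BLUEs track the true genotypic values on a complete design", {
  sim <- simulate_historical(n_accessions = 160, years = 2001:2006,
                             missingness = "full", seed = 19)
  b <- estimate_blues(sim$data$records)
  tr <- sim$truth$accessions
  expect_gt(cor(b$blues$blue,
                tr$genotypic_value[match(b$blues$accession_id,
                                         tr$accession_id)]),
            0.95)
})

test_that("tidy and glance return the documented shapes", {
  d <- make_balanced(n_acc = 10, n_yr = 4, e_sd = 1, seed = 20)
  fit <- fit_mixed(d, "value", fixed = "accession_id", random = "year")
  tv <- tidy(fit)
  expect_true(all(c("effect", "group", "estimate") %in% names(tv)))
  tf <- tidy(fit, "fixed")
  expect_equal(nrow(tf), 10L)
  g <- glance(fit)
  expect_equal(g$nobs, nrow(d))
  expect_true(g$converged)
})
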