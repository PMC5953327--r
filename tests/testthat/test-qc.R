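test_that("plausibility filter drops by the first violated rule and is idempotent", {
  rec <- tibble::tibble(
    accession_id = sprintf("A%d", 1:5),
    year = 1990L,
    trait = "FT",
    value = c(150, 400, 160, 155, 150),
    taxon = c("Triticum aestivum", "Triticum aestivum", "Hordeum vulgare",
              "Triticum aestivum", "Triticum aestivum"),
    sowing_date = as.Date(c("1989-10-10", "1989-10-10", "1989-10-10",
                            "1989-04-01", "1989-10-10"))
  )
  out <- plausibility_filter(rec, plausibility_rules())
  expect_equal(nrow(out$records), 2L)
  expect_equal(out$report$rule[match(2:4, out$report$row)],
               c("bounds:FT", "taxon", "sowing"))
  # idempotence: a second pass drops nothing
  again <- plausibility_filter(out$records, plausibility_rules())
  expect_equal(again$n_dropped, 0L)
  expect_identical(again$records, out$records)
})

test_that("plausibility filter warns on unknown traits and honours availability", {
  rec <- tibble::tibble(accession_id = c("A1", "A2"), year = 1990L,
                        trait = "SPIKE", value = c(5, 6))
  expect_warning(out <- plausibility_filter(rec, plausibility_rules()),
                 "SPIKE")
  expect_equal(nrow(out$records), 2L)

  rec2 <- tibble::tibble(accession_id = c("A1", "A2"), year = 1990L,
                         trait = "FT", value = c(150, 151))
  pp <- tibble::tibble(accession_id = c("A1", "A2"),
                       available = c(TRUE, FALSE))
  out2 <- plausibility_filter(rec2,
                              plausibility_rules(require_available = TRUE),
                              passport = pp)
  expect_equal(out2$records$accession_id, "A1")
  expect_equal(out2$report$rule, "available")
})

test_that("rule sets validate their bounds", {
  expect_error(plausibility_rules(trait_bounds = list(FT = c(220, 100))),
               "min < max")
})

test_that("Holm flagging matches an independent step-down oracle", {
  z <- withr::with_seed(21, rnorm(100))
  z <- c(z, 10)
  fit <- fake_fit(z)
  fl <- detect_outliers(fit, alpha = 0.05)
  p <- 2 * pnorm(-abs(z))
  expect_equal(fl$flagged, holm_oracle(p, 0.05))
  expect_equal(which(fl$flagged), 101L)   # exactly the contaminant

  expect_equal(sum(detect_outliers(fake_fit(rep(0, 50)), 0.05)$flagged), 0L)
  expect_error(detect_outliers(fit, alpha = 0), "alpha")
  expect_error(detect_outliers(fit, alpha = 1), "alpha")
})

test_that("Holm flags are invariant to record order", {
  z <- withr::with_seed(22, c(rnorm(80), 6, -7))
  fl1 <- detect_outliers(fake_fit(z), 0.05)
  perm <- withr::with_seed(23, sample(length(z)))
  fl2 <- detect_outliers(fake_fit(z[perm]), 0.05)
  expect_equal(fl1$flagged[perm], fl2$flagged)
})

test_that("studentization refuses a zero-variance group with several records", {
  fit <- fake_fit(c(0, 0, 1, 2), group = c("a", "a", "b", "b"),
                  sigma2 = c(0, 1))
  expect_error(studentized_residuals(fit), "zero")
})

test_that("outlier pass removes contaminants and little else", {
  n_true <- n_found <- n_false <- n_rec <- 0
  for (s in 1:3) {
    sim <- simulate_historical(n_accessions = 300, years = 1996:2005,
                               years_observed = 6, seed = 23 + s)
    inj <- inject_outliers(sim$data$records, rate = 0.01, magnitude = 8,
                           sigma_e = dplyr::select(sim$truth$year_effects,
                                                   year, sigma2_e),
                           seed = 50 + s)
    op <- outlier_pass(inj$records, alpha = 0.05)
    truth_keys <- paste(inj$flags$accession_id, inj$flags$year)
    found_keys <- paste(op$flags$accession_id, op$flags$year)
    n_true <- n_true + length(truth_keys)
    n_found <- n_found + sum(truth_keys %in% found_keys)
    n_false <- n_false + sum(!found_keys %in% truth_keys)
    n_rec <- n_rec + nrow(inj$records)
    if (s == 1) {
      # the refit must see a smaller residual variance
      expect_lt(mean_residual_variance(op$fit_after),
                mean_residual_variance(op$fit_before))
    }
  }
  expect_gte(n_found / n_true, 0.9)
  expect_lte(n_false / n_rec, 0.001)
})

test_that("outlier pass on clean data removes almost nothing", {
  removed <- vapply(1:5, function(s) {
    sim <- simulate_historical(n_accessions = 100, years = 2001:2006,
                               years_observed = 4, seed = 30 + s)
    outlier_pass(sim$data$records, alpha = 0.05)$removed_fraction
  }, numeric(1))
  expect_true(all(removed <= 0.001))
})

test_that("year CV follows its definition and flags the constructed bad year", {
  fit <- fake_fit(rep(0, 4), group = c("1990", "1990", "1991", "1991"),
                  sigma2 = c(4, 0))
  fit$fixed <- "year"
  fit$residual_by <- "year"
  fit$fixed_effects <- tibble::tibble(term = "year",
                                      level = c("1990", "1991"),
                                      estimate = c(100, 50), se = 0)
  cv <- year_cv(fit)
  expect_equal(cv$cv, c(sqrt(4) / 100, 0))

  fit$fixed_effects$estimate[2] <- -5
  expect_error(year_cv(fit), "undefined")

  sim <- simulate_historical(n_accessions = 150, years = 1991:2010,
                             years_observed = 6,
                             bad_year = list(year = 2000), seed = 26)
  fy <- fit_mixed(sim$data$records, "value", fixed = "year",
                  random = "accession_id", residual_by = "year")
  cv2 <- year_cv(fy)
  expect_equal(cv2$year[which.max(cv2$cv)], "2000")
})

test_that("weather index finds a planted driver and refuses overfit", {
  withr::with_seed(27, {
    yrs <- 1981:2010
    weather <- tidyr::expand_grid(year = yrs, month = 1:12)
    weather$rainfall <- rnorm(nrow(weather), 40, 15)
    weather$t_avg <- rnorm(nrow(weather), 9, 2)
    weather$flat <- 5  # zero-variance candidate
    april <- weather$rainfall[weather$month == 4]
    ye <- tibble::tibble(year = yrs,
                         effect = 0.8 * as.numeric(scale(april)) +
                           rnorm(length(yrs), 0, 0.3))
  })
  idx <- fit_weather_index(ye, weather)
  expect_equal(idx$selected$variable[1], "rainfall")
  expect_equal(idx$selected$month[1], 4L)
  expect_gt(idx$selected$coefficient[1], 0)
  expect_false(any(idx$selected$variable == "flat"))
  expect_gt(idx$r_squared, 0.5)
  expect_error(fit_weather_index(ye, weather, max_terms = 29), "overfit")
  expect_error(fit_weather_index(ye[1:5, ], weather), "at least")
})

test_that("weather index stays weak on pure-noise year effects", {
  null_runs <- vapply(1:10, function(s) {
    withr::with_seed(300 + s, {
      yrs <- 1981:2005
      weather <- tidyr::expand_grid(year = yrs, month = 1:12)
      weather$rainfall <- rnorm(nrow(weather), 40, 15)
      weather$humidity <- rnorm(nrow(weather), 75, 6)
      ye <- tibble::tibble(year = yrs, effect = rnorm(length(yrs)))
    })
    idx <- fit_weather_index(ye, weather)
    c(r2 = idx$r_squared, k = nrow(idx$selected))
  }, numeric(2))
  # without signal the retained index is small and weak
  expect_lt(median(null_runs["r2", ]), 0.45)
  expect_true(all(null_runs["k", ] <= 4))
})

test_that("year flagging needs both an inflated CV and a weather anomaly", {
  cv <- tibble::tibble(year = 2001:2010, cv = c(rep(0.02, 9), 0.09))
  w_flat <- tibble::tibble(year = 2001:2010,
                           w = withr::with_seed(28, rnorm(10)))
  fl <- flag_outlier_years(cv, w_flat, k_cv = 2, k_w = 3)
  expect_false(any(fl$flagged))          # CV inflated, index unremarkable

  w_anom <- w_flat
  w_anom$w[10] <- 30
  fl2 <- flag_outlier_years(cv, w_anom, k_cv = 2, k_w = 3)
  expect_equal(fl2$year[fl2$flagged], 2010L)

  cv_flat <- tibble::tibble(year = 2001:2010, cv = rep(0.02, 10))
  fl3 <- flag_outlier_years(cv_flat, w_anom, k_cv = 2, k_w = 3)
  expect_false(any(fl3$flagged))         # anomaly alone is not enough

  same <- tibble::tibble(year = 2001:2005, cv = 0.02)
  fl4 <- flag_outlier_years(same, tibble::tibble(year = 2001:2005, w = 1))
  expect_false(any(fl4$flagged))         # identical years: nothing to flag
  expect_error(flag_outlier_years(same[1:2, ], w_flat[1:2, ]), "3 years")
})

test_that("qc_pipeline survives an empty dataset and keeps clean data intact", {
  empty <- historical_dataset(tibble::tibble(
    accession_id = character(), year = integer(), trait = character(),
    value = numeric()))
  qc0 <- qc_pipeline(empty)
  expect_s3_class(qc0, "hp_qc")
  expect_equal(nrow(qc0$records), 0L)

  sim <- simulate_historical(n_accessions = 150, years = 1991:2010,
                             years_observed = 5, seed = 29)
  qc <- qc_pipeline(sim$data)
  expect_gte(nrow(qc$records) / nrow(sim$data$records), 0.998)
  counts <- qc$report$counts
  expect_equal(counts$fraction, counts$dropped / counts$tested)
})

test_that("qc_pipeline flags and removes a planted disaster year", {
  sim <- simulate_historical(n_accessions = 150, years = 1986:2010,
                             years_observed = 6,
                             bad_year = list(year = 1995), seed = 31)
  qc <- qc_pipeline(sim$data)
  expect_true(1995L %in% qc$report$step3$flagged_years)
  expect_false(1995L %in% qc$records$year)
  expect_gte(glance(qc)$h2_after, glance(qc)$h2_before)
})
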