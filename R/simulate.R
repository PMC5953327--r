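## Synthetic historical genebank data ---------------------------------------
##
## The generator draws records from the same model the analysis assumes,
##   y_ij = mu + g_i + a_j + e_ij,
## with origin-linked accession means, year effects composed of a linear
## temporal trend + a weather-driven component + independent noise, and
## log-normally dispersed year-specific residual variances. Defaults are
## calibrated to flowering time of a large winter-wheat collection
## (mu = 160 days, sigma2_G = 15.6, sigma2_Y = 72, mean sigma2_e = 6.5,
## ~70 regeneration years, >93% of the accession x year matrix empty).

local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  if (!is.numeric(seed)) abort("seed must be numeric")
  withr::local_seed(as.integer(seed %% .Machine$integer.max),
                    .local_envir = env)
  invisible(NULL)
}

#' Default origin composition for simulated collections
#'
#' Eight origin countries with relative sizes matching the balanced
#' 160-accession subset used in the missing-pattern resampling study
#' (51:42:27:15:7:6:6:6) and origin mean shifts on the flowering-time scale
#' (days): southern origins flower earlier, Scandinavian later. Counts are
#' scaled to `n_accessions` (largest-remainder rounding).
#'
#' @param n_accessions Total number of accessions to split across origins.
#' @return A tibble with `origin`, `count`, `shift`.
#' @export
default_origins <- function(n_accessions) {
  base <- tibble(
    origin = c("DEU", "USA", "SWE", "GRC", "FRA", "AFG", "ALB", "GBR"),
    weight = c(51, 42, 27, 15, 7, 6, 6, 6),
    shift = c(0, -2, 3, -6, -1, -5, -4, 1)
  )
  raw <- n_accessions * base$weight / sum(base$weight)
  cnt <- floor(raw)
  rem <- n_accessions - sum(cnt)
  if (rem > 0) {
    topup <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[topup] <- cnt[topup] + 1L
  }
  tibble(origin = base$origin, count = as.integer(cnt), shift = base$shift)
}

#' Default weather drivers of simulated year effects
#'
#' Four standardized monthly weather variables (February maximum
#' temperature, April and June rainfall, April air humidity) jointly
#' contribute a configurable share of the year-effect variance; with the
#' default year variance of 72 the four equal coefficients explain ~38% of
#' the year-effect variation, giving the stepwise weather-index stage a
#' recoverable signal of known strength.
#'
#' @param total_variance Year-effect variance contributed by weather.
#' @return A tibble with `month`, `variable`, `coefficient` (per standard
#'   deviation of the weather variable).
#' @export
default_weather_model <- function(total_variance = 27.4) {
  co <- sqrt(total_variance / 4)
  tibble(
    month = c(2L, 4L, 6L, 4L),
    variable = c("t_max", "rainfall", "rainfall", "humidity"),
    coefficient = c(co, -co, -co, -co)
  )
}

## monthly climatology used to turn standardized draws into weather values
weather_climatology <- function() {
  tibble(
    month = 1:12,
    rain_mean = c(33, 27, 32, 35, 48, 55, 58, 52, 38, 32, 36, 40),
    rain_sd   = c(15, 13, 15, 18, 24, 28, 30, 27, 20, 16, 17, 18),
    hum_mean  = c(86, 82, 77, 70, 68, 68, 69, 71, 78, 84, 88, 88),
    hum_sd    = c(4, 5, 6, 6, 6, 5, 5, 5, 5, 4, 3, 3),
    tavg_mean = c(0.5, 1.3, 4.5, 8.9, 13.5, 16.5, 18.2, 17.8, 14.0, 9.3, 4.5, 1.6),
    tavg_sd   = c(3, 2.8, 2, 1.6, 1.4, 1.3, 1.4, 1.3, 1.4, 1.5, 1.8, 2.5),
    tspan     = c(5, 6, 8, 10, 11, 11, 11, 11, 9, 7, 5, 4)
  )
}

#' Simulate a historical genebank phenotype dataset
#'
#' Draws accession records under the additive model
#' \eqn{y_{ij} = \mu + g_i + a_j + e_{ij}}: accession effects
#' \eqn{g_i \sim N(\delta_{o(i)}, \sigma^2_G)} with origin mean shifts
#' \eqn{\delta}, year effects composed of a linear temporal trend, a
#' weather-driven component (a linear combination of standardized simulated
#' monthly weather variables), and independent noise so that the total
#' year-effect variance equals `sigma2_Y`; residuals
#' \eqn{e_{ij} \sim N(0, \sigma^2_{e^*j})} with per-year variances drawn
#' log-normally around `sigma2_e_mean`. An optional "bad year" gets a
#' multiplicatively inflated residual variance and an extreme value on the
#' first weather driver, to exercise the weather-index quality-control
#' stage.
#'
#' @param n_accessions Number of accessions.
#' @param years Calendar years of the regeneration campaign.
#' @param mu Trait intercept (defaults mimic flowering time in days of year).
#' @param trait Trait label written to the records.
#' @param sigma2_G Genetic variance (within origins).
#' @param sigma2_Y Total year-effect variance; must exceed the variance
#'   contributed by trend and weather.
#' @param sigma2_e_mean Mean of the per-year residual variances.
#' @param sigma_e_dispersion Log-scale SD of per-year residual variances
#'   (0 = homogeneous).
#' @param origins Tibble with `origin`, `count`, `shift` (see
#'   [default_origins()]); counts must sum to `n_accessions`.
#' @param trend_per_year Deterministic linear trend of year effects
#'   (days/year; negative = earlier flowering over time).
#' @param weather_model Tibble `month`, `variable`, `coefficient` of weather
#'   drivers of the year effect (see [default_weather_model()]); `NULL`
#'   disables the weather component.
#' @param bad_year Optional list with `year`, `var_factor` (residual-variance
#'   inflation, default 8), `weather_z` (standardized anomaly applied to each
#'   weather driver, sign-aligned so all push the year effect in the damaging
#'   direction; default -4, a once-in-decades extreme season) and
#'   `effect_shift` (additional year-effect damage beyond the linear weather
#'   path, emulating e.g. an epidemic triggered by the extreme weather;
#'   default -2 SD of the year effects). The switch exercises the
#'   weather-index quality-control stage.
#' @param missingness One of `"mcar"`, `"block_by_origin"`, `"block_random"`,
#'   `"full"`; applied via [apply_missingness()].
#' @param years_observed For `"mcar"`, the number of observed years per
#'   accession — a single integer or a vector to sample from (default 3:6,
#'   ~94% empty cells over 70 years); for the block patterns, a single
#'   integer (years per block).
#' @param outlier_rate,outlier_magnitude Fraction of records receiving a
#'   gross error of `outlier_magnitude` residual SDs (see
#'   [inject_outliers()]); 0 disables.
#' @param seed Integer seed; identical seeds give identical output.
#'
#' @return A list with `data` (a [historical_dataset()]: `records`,
#'   `passport`, `weather`) and `truth` (accession effects, year-effect
#'   decomposition, per-year residual variances, outlier flags, parameters).
#' @examples
#' sim <- simulate_historical(n_accessions = 160, years = 2001:2006,
#'                            years_observed = 3, seed = 42)
#' incidence_summary(sim$data)
#' @export
simulate_historical <- function(n_accessions = 6000,
                                years = 1946:2015,
                                mu = 160,
                                trait = "FT",
                                sigma2_G = 15.6,
                                sigma2_Y = 72,
                                sigma2_e_mean = 6.5,
                                sigma_e_dispersion = 0.4,
                                origins = default_origins(n_accessions),
                                trend_per_year = -0.27,
                                weather_model = default_weather_model(),
                                bad_year = NULL,
                                missingness = c("mcar", "block_by_origin",
                                                "block_random", "full"),
                                years_observed = 3:6,
                                outlier_rate = 0,
                                outlier_magnitude = 8,
                                seed = NULL) {
  missingness <- match.arg(missingness)
  stopifnot(sigma2_G >= 0, sigma2_Y >= 0, sigma2_e_mean >= 0,
            sigma_e_dispersion >= 0, outlier_rate >= 0, outlier_rate < 1)
  origins <- as_tibble(origins)
  if (sum(origins$count) != n_accessions) {
    abort("origin counts must sum to n_accessions")
  }
  n_years <- length(years)
  local_seed(seed)

  ## accessions
  acc <- sprintf("ACC%05d", seq_len(n_accessions))
  origin_of <- rep(origins$origin, origins$count)
  shift_of <- rep(origins$shift, origins$count)
  g <- rnorm(n_accessions, 0, sqrt(sigma2_G)) + shift_of

  ## weather: standardized draws z per (year, month, variable) -> values
  clim <- weather_climatology()
  vars <- c("rainfall", "humidity", "t_avg", "t_min", "t_max")
  zw <- array(rnorm(n_years * 12 * length(vars)),
              dim = c(n_years, 12, length(vars)),
              dimnames = list(as.character(years), 1:12, vars))
  ## t_min/t_max share the t_avg anomaly plus their own noise
  zw[, , "t_min"] <- 0.8 * zw[, , "t_avg"] + 0.6 * zw[, , "t_min"]
  zw[, , "t_max"] <- 0.8 * zw[, , "t_avg"] + 0.6 * zw[, , "t_max"]

  ## year-effect decomposition
  trend_comp <- trend_per_year * (years - mean(years))
  var_trend <- mean(trend_comp^2) - mean(trend_comp)^2
  weather_comp <- rep(0, n_years)
  if (!is.null(weather_model) && nrow(weather_model)) {
    wm <- as_tibble(weather_model)
    if (!is.null(bad_year)) {
      by_idx <- match(bad_year$year, years)
      if (is.na(by_idx)) abort("bad_year$year is not among simulated years")
      zbad <- bad_year$weather_z %||% -4
      ## a disaster season is anomalous in all its weather drivers at once,
      ## each pushing the year effect in the damaging direction
      for (r in seq_len(nrow(wm))) {
        zw[by_idx, wm$month[r], wm$variable[r]] <- zbad * sign(wm$coefficient[r])
      }
    }
    for (r in seq_len(nrow(wm))) {
      weather_comp <- weather_comp +
        wm$coefficient[r] * zw[, wm$month[r], wm$variable[r]]
    }
    var_weather <- sum(wm$coefficient^2)
  } else {
    var_weather <- 0
  }
  var_noise <- sigma2_Y - var_trend - var_weather
  if (var_noise < 0) {
    abort(paste0("sigma2_Y (", sigma2_Y, ") is smaller than the variance of ",
                 "trend + weather components (", round(var_trend + var_weather, 2),
                 "); increase sigma2_Y or weaken trend/weather"))
  }
  noise_comp <- rnorm(n_years, 0, sqrt(var_noise))
  a <- trend_comp + weather_comp + noise_comp
  if (!is.null(bad_year)) {
    ## damage beyond the linear weather path (epidemic-style contamination)
    by_idx <- match(bad_year$year, years)
    if (is.na(by_idx)) abort("bad_year$year is not among simulated years")
    a[by_idx] <- a[by_idx] + (bad_year$effect_shift %||% (-2 * sqrt(sigma2_Y)))
  }

  ## per-year residual variances (log-normal around the mean)
  if (sigma_e_dispersion > 0 && sigma2_e_mean > 0) {
    s2e <- stats::rlnorm(n_years,
                         log(sigma2_e_mean) - sigma_e_dispersion^2 / 2,
                         sigma_e_dispersion)
  } else {
    s2e <- rep(sigma2_e_mean, n_years)
  }
  if (!is.null(bad_year)) {
    by_idx <- match(bad_year$year, years)
    s2e[by_idx] <- s2e[by_idx] * (bad_year$var_factor %||% 8)
  }

  ## full grid, then missingness
  full <- tidyr::expand_grid(accession_id = acc, year = years)
  iy <- match(full$year, years)
  ia <- match(full$accession_id, acc)
  full$value <- mu + g[ia] + a[iy] + rnorm(nrow(full), 0, sqrt(s2e[iy]))
  full$trait <- trait
  full$taxon <- "Triticum aestivum"
  sow_doy <- 288 + sample(-10:10, nrow(full), replace = TRUE)
  full$sowing_date <- as.Date(sprintf("%d-01-01", full$year - 1L)) + sow_doy - 1L
  full <- full[, c("accession_id", "year", "trait", "value",
                   "sowing_date", "taxon")]

  blocks <- tibble(accession_id = acc, block = origin_of)
  records <- apply_missingness(
    full, pattern = missingness, years_observed = years_observed,
    blocks = blocks, seed = NULL   # inherits the live RNG stream
  )

  out_flags <- tibble(accession_id = character(), year = integer())
  if (outlier_rate > 0) {
    inj <- inject_outliers(records, rate = outlier_rate,
                           magnitude = outlier_magnitude,
                           sigma_e = tibble(year = years, sigma2_e = s2e),
                           seed = NULL)
    records <- inj$records
    out_flags <- inj$flags
  }

  passport <- tibble(
    accession_id = acc,
    origin_country = origin_of,
    acquisition_year = pmax(min(years) - sample(0:3, n_accessions, TRUE),
                            min(years) - 3L),
    available = TRUE
  )

  ## weather table on natural scales from the standardized draws
  wtab <- tidyr::expand_grid(year = years, month = 1:12)
  im <- wtab$month
  iyy <- match(wtab$year, years)
  zget <- function(v) zw[cbind(iyy, im, match(v, vars))]
  wtab$rainfall <- pmax(0, clim$rain_mean[im] + clim$rain_sd[im] * zget("rainfall"))
  wtab$humidity <- pmin(100, pmax(20, clim$hum_mean[im] + clim$hum_sd[im] * zget("humidity")))
  wtab$t_avg <- clim$tavg_mean[im] + clim$tavg_sd[im] * zget("t_avg")
  wtab$t_min <- wtab$t_avg - clim$tspan[im] / 2 + 0.8 * zget("t_min")
  wtab$t_max <- wtab$t_avg + clim$tspan[im] / 2 + 0.8 * zget("t_max")

  truth <- list(
    accessions = tibble(accession_id = acc, origin = origin_of,
                        shift = shift_of, g = g, genotypic_value = mu + g),
    year_effects = tibble(year = years, trend = trend_comp,
                          weather = weather_comp, noise = noise_comp,
                          a = a, sigma2_e = s2e,
                          expected_level = mu + a),
    weather_z = zw,
    outliers = out_flags,
    params = list(mu = mu, sigma2_G = sigma2_G, sigma2_Y = sigma2_Y,
                  sigma2_e_mean = sigma2_e_mean,
                  sigma_e_dispersion = sigma_e_dispersion,
                  trend_per_year = trend_per_year,
                  var_trend = var_trend, var_weather = var_weather,
                  var_noise = var_noise, bad_year = bad_year,
                  trait = trait, seed = seed)
  )
  list(data = historical_dataset(records, passport, wtab), truth = truth)
}

#' Apply a missing-data pattern to complete records
#'
#' Thins a record table down to the observation schedule of one of the
#' regeneration scenarios: `"block_by_origin"` keeps, for every block of
#' accessions, one shared random subset of years (the historical block-wise
#' regeneration, a MAR-violating pattern when blocks differ in their means);
#' `"block_random"` does the same after randomly permuting accessions into
#' blocks of identical sizes; `"mcar"` samples the year subset independently
#' per accession; `"full"` returns the input unchanged.
#'
#' @param records Data frame of phenotype records (`accession_id`, `year`, ...).
#' @param pattern One of `"mcar"`, `"block_by_origin"`, `"block_random"`,
#'   `"full"`.
#' @param years_observed Number of years kept per accession/block; for
#'   `"mcar"` a vector is allowed and the count is sampled per accession.
#' @param blocks Tibble `accession_id`, `block` (required for the block
#'   patterns; for `"block_random"` only the block sizes are used).
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return The thinned records tibble.
#' @export
apply_missingness <- function(records, pattern = c("mcar", "block_by_origin",
                                                   "block_random", "full"),
                              years_observed = 3L, blocks = NULL,
                              seed = NULL) {
  pattern <- match.arg(pattern)
  records <- as_tibble(records)
  if (pattern == "full") return(records)
  local_seed(seed)
  yrs <- sort(unique(records$year))
  if (max(years_observed) > length(yrs)) {
    abort("years_observed exceeds the number of distinct years in the records")
  }
  acc <- unique(records$accession_id)

  if (pattern == "mcar") {
    ny <- if (length(years_observed) == 1L) {
      rep(years_observed, length(acc))
    } else {
      sample(years_observed, length(acc), replace = TRUE)
    }
    kept <- purrr::map2(seq_along(acc), ny,
                        function(i, k) sample(yrs, k))
    names(kept) <- acc
    keep_key <- unlist(purrr::imap(kept, function(ys, a) paste(a, ys)))
    return(records[paste(records$accession_id, records$year) %in% keep_key, ])
  }

  if (is.null(blocks)) abort("block patterns require a `blocks` mapping")
  blocks <- as_tibble(blocks)
  if (!all(acc %in% blocks$accession_id)) {
    abort("every accession must appear in `blocks`")
  }
  blocks <- blocks[match(acc, blocks$accession_id), ]
  if (pattern == "block_random") {
    blocks$block <- sample(blocks$block)   # permute membership, sizes kept
  }
  k <- years_observed[1L]
  bl <- unique(blocks$block)
  yr_of_block <- lapply(bl, function(b) sample(yrs, k))
  names(yr_of_block) <- as.character(bl)
  block_of <- setNames(as.character(blocks$block),
                       as.character(blocks$accession_id))
  keep_key <- unlist(lapply(names(yr_of_block),
                            function(b) paste(b, yr_of_block[[b]])))
  keep <- paste(block_of[as.character(records$accession_id)],
                records$year) %in% keep_key
  records[keep, ]
}

#' Inject gross outliers into phenotype records
#'
#' Adds `+/- magnitude * sigma_e*j` (random sign) to a random fraction of
#' records, returning the modified records and the true flags, for testing
#' the studentized-residual outlier stage.
#'
#' @param records Phenotype records.
#' @param rate Fraction of records contaminated, in [0, 1).
#' @param magnitude Shift size in units of the year's residual SD.
#' @param sigma_e Either a single residual variance, a tibble
#'   `year`, `sigma2_e`, or `NULL` to use a rough per-year residual SD
#'   estimated from the data (year/accession means swept out).
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return A list with `records` and `flags` (tibble `accession_id`, `year`,
#'   `trait`, `row`).
#' @export
inject_outliers <- function(records, rate, magnitude = 8, sigma_e = NULL,
                            seed = NULL) {
  stopifnot(rate >= 0, rate < 1)
  records <- as_tibble(records)
  if (rate == 0 || nrow(records) == 0L) {
    return(list(records = records,
                flags = tibble(accession_id = character(), year = integer(),
                               trait = character(), row = integer())))
  }
  local_seed(seed)
  n <- nrow(records)
  if (is.null(sigma_e)) {
    ## crude per-year residual SD: sweep accession means, then pool by year
    dev <- records$value -
      stats::ave(records$value, records$accession_id, FUN = mean)
    sd_y <- stats::ave(dev, records$year, FUN = stats::sd)
    sd_y[!is.finite(sd_y) | sd_y == 0] <- stats::sd(dev)
    sdej <- sd_y
  } else if (is.data.frame(sigma_e)) {
    sdej <- sqrt(sigma_e$sigma2_e[match(records$year, sigma_e$year)])
    if (any(is.na(sdej))) abort("sigma_e table is missing some record years")
  } else {
    sdej <- rep(sqrt(sigma_e), n)
  }
  hit <- which(runif(n) < rate)
  sign_ <- sample(c(-1, 1), length(hit), replace = TRUE)
  records$value[hit] <- records$value[hit] + sign_ * magnitude * sdej[hit]
  flags <- tibble(accession_id = as.character(records$accession_id[hit]),
                  year = records$year[hit],
                  trait = if ("trait" %in% names(records))
                    as.character(records$trait[hit]) else NA_character_,
                  row = hit)
  list(records = records, flags = flags)
}

#' Simulate an orthogonal multi-environment validation trial
#'
#' Generates replicated trial records for a set of accessions with known
#' genotypic values, under the multi-factor random-effects decomposition
#' used for designed validation experiments: environment, accession x
#' environment interaction, trial, replicate within trial, and block within
#' replicate, plus an i.i.d. residual. All accessions appear in every
#' environment (orthogonal layout).
#'
#' @param genotypes Tibble `accession_id`, `genotypic_value` (e.g.
#'   `truth$accessions` from [simulate_historical()], using
#'   `genotypic_value`).
#' @param n_env,n_trials,n_reps,n_blocks Layout sizes (environments; trials
#'   per environment; replicates per trial; blocks per replicate).
#' @param sigma2_env,sigma2_gxe,sigma2_trial,sigma2_rep,sigma2_block,sigma2_e
#'   Variance components of the random factors and residual.
#' @param seed Optional seed.
#' @return A tibble with `accession_id`, `environment`, `trial`,
#'   `replicate`, `block`, `value`.
#' @export
simulate_validation <- function(genotypes, n_env = 5, n_trials = 2,
                                n_reps = 2, n_blocks = 4,
                                sigma2_env = 30, sigma2_gxe = 3,
                                sigma2_trial = 2, sigma2_rep = 1,
                                sigma2_block = 1.5, sigma2_e = 6,
                                seed = NULL) {
  genotypes <- as_tibble(genotypes)
  stopifnot(all(c("accession_id", "genotypic_value") %in% names(genotypes)))
  local_seed(seed)
  n_g <- nrow(genotypes)
  env <- sprintf("E%02d", seq_len(n_env))
  d <- tidyr::expand_grid(accession_id = genotypes$accession_id,
                          environment = env,
                          trial = sprintf("T%d", seq_len(n_trials)),
                          replicate = sprintf("R%d", seq_len(n_reps)))
  d$block <- sprintf("B%d", sample.int(n_blocks, nrow(d), replace = TRUE))
  ev <- setNames(rnorm(n_env, 0, sqrt(sigma2_env)), env)
  gxe <- matrix(rnorm(n_g * n_env, 0, sqrt(sigma2_gxe)), n_g, n_env,
                dimnames = list(genotypes$accession_id, env))
  tkey <- unique(d[, c("environment", "trial")])
  tv <- setNames(rnorm(nrow(tkey), 0, sqrt(sigma2_trial)),
                 paste(tkey$environment, tkey$trial))
  rkey <- unique(d[, c("environment", "trial", "replicate")])
  rv <- setNames(rnorm(nrow(rkey), 0, sqrt(sigma2_rep)),
                 paste(rkey$environment, rkey$trial, rkey$replicate))
  bkey <- unique(d[, c("environment", "trial", "replicate", "block")])
  bv <- setNames(rnorm(nrow(bkey), 0, sqrt(sigma2_block)),
                 paste(bkey$environment, bkey$trial, bkey$replicate, bkey$block))
  gval <- setNames(genotypes$genotypic_value, genotypes$accession_id)
  d$value <- gval[d$accession_id] +
    ev[d$environment] +
    gxe[cbind(d$accession_id, d$environment)] +
    tv[paste(d$environment, d$trial)] +
    rv[paste(d$environment, d$trial, d$replicate)] +
    bv[paste(d$environment, d$trial, d$replicate, d$block)] +
    rnorm(nrow(d), 0, sqrt(sigma2_e))
  d
}
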