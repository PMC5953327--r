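## Three-step quality control -------------------------------------------------
##
## 1. plausibility rules (taxon, availability, sowing window, physiological
##    trait bounds),
## 2. studentized-residual outlier test with Bonferroni-Holm familywise
##    correction, single flag -> remove -> refit pass,
## 3. year-level screening: coefficient of variation of the year-specific
##    error variances, corroborated by a weather-parameter index fitted by
##    forward stepwise regression on standardized monthly weather variables;
##    a year is excluded only when both signals are anomalous.

#' Plausibility rule set
#'
#' Configurable record-level screening rules. The defaults encode
#' physiological limits for autumn-sown hexaploid winter wheat: flowering
#' time between day 100 and 220 of the year, plant height 20-250 cm,
#' thousand grain weight 5-80 g, sowing between early September and
#' mid-December. Traits present in the data but absent from `trait_bounds`
#' are kept with a warning.
#'
#' @param allowed_taxa Character vector of acceptable taxa, or `NULL` to skip
#'   the taxon rule.
#' @param sowing_window Two days-of-year (earliest, latest; may wrap past
#'   New Year, e.g. `c(244, 350)`), or `NULL` to skip.
#' @param trait_bounds Named list `trait -> c(min, max)` physiological limits.
#' @param require_available Drop records of accessions whose passport marks
#'   them unavailable?
#' @return A list of class `hp_rules`.
#' @export
plausibility_rules <- function(allowed_taxa = "Triticum aestivum",
                               sowing_window = c(244L, 350L),
                               trait_bounds = list(FT = c(100, 220),
                                                   PH = c(20, 250),
                                                   TGW = c(5, 80)),
                               require_available = FALSE) {
  for (tb in trait_bounds) {
    if (length(tb) != 2L || tb[1] >= tb[2]) {
      abort("each trait bound must be c(min, max) with min < max")
    }
  }
  structure(list(allowed_taxa = allowed_taxa, sowing_window = sowing_window,
                 trait_bounds = trait_bounds,
                 require_available = require_available),
            class = "hp_rules")
}

#' Step 1: plausibility filter
#'
#' Applies the rule set record by record; a dropped record carries the id of
#' the first violated rule (checked in the order taxon, availability,
#' sowing window, trait bounds). The pass is idempotent.
#'
#' @param data An `hp_dataset` or records data frame.
#' @param rules A [plausibility_rules()] object.
#' @param passport Passport tibble (taken from the dataset if present);
#'   needed only for `require_available`.
#' @return A list: `records` (kept rows), `report` tibble (`row`, `rule`) of
#'   dropped rows, `n_tested`, `n_dropped`.
#' @export
plausibility_filter <- function(data, rules = plausibility_rules(),
                                passport = NULL) {
  if (inherits(data, "hp_dataset")) {
    passport <- passport %||% data$passport
    records <- data$records
  } else {
    records <- as_tibble(data)
  }
  n <- nrow(records)
  rule <- rep(NA_character_, n)
  if (n) {
    if (!is.null(rules$allowed_taxa) && "taxon" %in% names(records)) {
      bad <- !is.na(records$taxon) & !records$taxon %in% rules$allowed_taxa
      rule[is.na(rule) & bad] <- "taxon"
    }
    if (rules$require_available) {
      if (is.null(passport)) {
        warn("require_available is set but no passport supplied; rule skipped")
      } else {
        avail <- setNames(passport$available, passport$accession_id)
        bad <- !is.na(avail[records$accession_id]) &
          !avail[records$accession_id]
        rule[is.na(rule) & bad] <- "available"
      }
    }
    if (!is.null(rules$sowing_window) && "sowing_date" %in% names(records)) {
      doy <- as.integer(strftime(records$sowing_date, "%j"))
      w <- rules$sowing_window
      inside <- if (w[1] <= w[2]) doy >= w[1] & doy <= w[2] else
        doy >= w[1] | doy <= w[2]
      bad <- !is.na(doy) & !inside
      rule[is.na(rule) & bad] <- "sowing"
    }
    unknown <- setdiff(unique(records$trait), names(rules$trait_bounds))
    if (length(unknown)) {
      warn(paste0("no trait bounds configured for: ",
                  paste(unknown, collapse = ", "), "; records kept"))
    }
    for (tr in intersect(unique(records$trait), names(rules$trait_bounds))) {
      b <- rules$trait_bounds[[tr]]
      bad <- records$trait == tr &
        (records$value < b[1] | records$value > b[2])
      rule[is.na(rule) & bad] <- paste0("bounds:", tr)
    }
  }
  dropped <- which(!is.na(rule))
  list(records = records[setdiff(seq_len(n), dropped), ],
       report = tibble(row = dropped, rule = rule[dropped]),
       n_tested = n, n_dropped = length(dropped))
}

#' Step 2: flag outliers by studentized residuals with Bonferroni-Holm
#'
#' Two-sided p-values from the standard-normal reference for each
#' studentized residual of the fit, corrected by the Holm step-down
#' procedure across all records of the trait (familywise error `alpha`).
#'
#' @param fit An `hp_fit` with studentized residuals.
#' @param alpha Familywise error rate in (0, 1).
#' @return A tibble: `row`, `studentized`, `p_value`, `p_holm`, `flagged`.
#' @export
detect_outliers <- function(fit, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort("alpha must be a single number in (0, 1)")
  }
  st <- studentized_residuals(fit)
  p <- 2 * pnorm(-abs(st$studentized))
  ph <- p.adjust(p, method = "holm")
  tibble(row = st$row, studentized = st$studentized,
         p_value = p, p_holm = ph, flagged = ph < alpha)
}

#' Step 2 as a pass: fit, flag, remove, refit once
#'
#' Fits the historical-data model (fixed accessions, random year,
#' year-specific residual variances unless `heterogeneous = FALSE`), flags
#' outliers via [detect_outliers()], removes them, and refits the same model
#' on the cleaned records — a single pass, as re-testing after removal is
#' deliberately not iterated (set `iterate = TRUE` for repeated passes until
#' no flag remains).
#'
#' @param records Phenotype records of one trait.
#' @param alpha Familywise error rate for the Holm test.
#' @param heterogeneous Year-specific residual variances?
#' @param iterate Repeat flag/remove/refit until no record is flagged.
#' @param max_pass Safety cap on iterated passes.
#' @param ... Passed to [fit_mixed()].
#' @return A list: `records` (cleaned), `flags` (tibble of removed records
#'   with studentized residual and Holm p), `removed_fraction`, `fit_before`,
#'   `fit_after`, `n_passes`.
#' @export
outlier_pass <- function(records, alpha = 0.05, heterogeneous = TRUE,
                         iterate = FALSE, max_pass = 10L, ...) {
  records <- as_tibble(records)
  current <- records
  all_flags <- NULL
  fit_before <- NULL
  fit <- NULL
  n_pass <- 0L
  repeat {
    n_pass <- n_pass + 1L
    fit <- fit_mixed(current, "value", fixed = "accession_id",
                     random = "year",
                     residual_by = if (heterogeneous) "year" else NULL, ...)
    if (is.null(fit_before)) fit_before <- fit
    fl <- detect_outliers(fit, alpha)
    hit <- fl[fl$flagged, ]
    if (!nrow(hit)) break
    flagged_rows <- current[hit$row, ]
    flagged_rows$studentized <- hit$studentized
    flagged_rows$p_holm <- hit$p_holm
    all_flags <- dplyr::bind_rows(all_flags, flagged_rows)
    current <- current[-hit$row, ]
    if (!iterate || n_pass >= max_pass) {
      ## refit once on the cleaned data for the before/after comparison
      fit <- fit_mixed(current, "value", fixed = "accession_id",
                       random = "year",
                       residual_by = if (heterogeneous) "year" else NULL, ...)
      break
    }
  }
  if (is.null(all_flags)) {
    all_flags <- current[0, ]
  }
  list(records = current,
       flags = as_tibble(all_flags),
       removed_fraction = nrow(all_flags) / nrow(records),
       fit_before = fit_before,
       fit_after = fit,
       n_passes = n_pass)
}

#' Coefficient of variation of the year-specific error variances
#'
#' For every year, \eqn{CV_j = \sqrt{\sigma^2_{e^*j}} / YE_j}, where
#' \eqn{YE_j} is the year-level expected trait value (the fixed year estimate
#' when years are fixed in the fit, or intercept + year BLUP when years are
#' random). Requires a heterogeneous fit and positive year levels (the CV is
#' undefined otherwise).
#'
#' @param fit An `hp_fit` with per-year residual variances and year effects.
#' @return A tibble: `year`, `ye` (expected level), `sigma2_e`, `cv`.
#' @export
year_cv <- function(fit) {
  stopifnot(inherits(fit, "hp_fit"))
  if (is.null(fit$residual_by)) {
    abort("year_cv() needs a fit with year-specific residual variances")
  }
  if ("year" %in% fit$fixed) {
    ye <- fit$fixed_effects[fit$fixed_effects$term == "year",
                            c("level", "estimate")]
  } else if ("year" %in% fit$random) {
    mu <- fit$fixed_effects$estimate[1L]
    re <- fit$random_effects[fit$random_effects$term == "year", ]
    ye <- tibble(level = re$level, estimate = mu + re$blup)
  } else {
    abort("fit has no year term")
  }
  rv <- fit$residual_variances
  pooled <- rv$variance[rv$group == ".pooled"]
  s2 <- unname(setNames(rv$variance, rv$group)[ye$level])
  if (length(pooled)) s2[is.na(s2)] <- pooled
  ye_level <- ye$estimate
  if (any(ye_level <= 0)) {
    abort("year-level expected value <= 0; CV undefined on this scale")
  }
  tibble(year = ye$level, ye = ye_level, sigma2_e = s2,
         cv = sqrt(s2) / ye_level)
}

aicc <- function(fit_lm) {
  n <- length(fit_lm$residuals)
  rss <- sum(fit_lm$residuals^2)
  k <- length(coef(fit_lm)) + 1
  if (n - k - 1 <= 0) return(Inf)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Step 3a: fit the weather-parameter index
#'
#' Forward stepwise regression of the per-year effects on standardized
#' monthly weather variables (every month x variable pair is a candidate),
#' selecting by small-sample AIC (AICc). With dozens of candidate
#' month x variable pairs and a few dozen years, unconstrained forward
#' selection overfits by chance, so a term is only admitted when it improves
#' AICc by at least `delta`, and at most one term per five years (never more
#' than `n_years - 2`) is selected. Candidates with missing values in any
#' modeled year, or without variance, are excluded. The fitted linear
#' combination is the weather-parameter index \eqn{W_j} per year.
#'
#' @param year_effects Tibble `year`, `effect` (year-level estimates or
#'   deviations from [year_cv()] / a fixed-year fit).
#' @param weather Monthly weather tibble (`year`, `month`, variables).
#' @param max_terms Optional cap on selected terms; must not exceed
#'   `n_years - 2`; defaults to one term per five years.
#' @param delta Minimum AICc improvement for admitting a term.
#' @param detrend Remove a linear calendar-year trend from the year effects
#'   before selection (default `TRUE`): a secular trend is not a weather
#'   signal, and leaving it in lets spurious weather terms absorb it.
#' @param min_years Minimum number of years required (default 8).
#' @return An object of class `hp_weather_index`: `selected` (tibble
#'   `variable`, `month`, `coefficient` on the standardized predictor),
#'   `intercept`, `r_squared`, `index` (tibble `year`, `w`), `n_years`.
#' @export
fit_weather_index <- function(year_effects, weather, max_terms = NULL,
                              delta = 2, detrend = TRUE, min_years = 8L) {
  year_effects <- as_tibble(year_effects)
  stopifnot(all(c("year", "effect") %in% names(year_effects)))
  weather <- as_tibble(weather)
  yrs <- intersect(year_effects$year, unique(weather$year))
  if (length(yrs) < min_years) {
    abort(paste0("need at least ", min_years,
                 " years with both year effects and weather data (have ",
                 length(yrs), ")"))
  }
  guard <- length(yrs) - 2L
  if (!is.null(max_terms) && max_terms > guard) {
    abort(paste0("max_terms (", max_terms, ") exceeds years - 2 (", guard,
                 "): refusing an overfit index"))
  }
  max_terms <- min(max_terms %||% max(1L, length(yrs) %/% 5L), guard)

  vars <- setdiff(names(weather), c("year", "month"))
  wide <- tidyr::pivot_wider(
    tidyr::pivot_longer(weather[weather$year %in% yrs, ],
                        dplyr::all_of(vars),
                        names_to = "variable", values_to = "x"),
    id_cols = "year", names_from = c("variable", "month"),
    values_from = "x", names_sep = "_m")
  wide <- wide[match(yrs, wide$year), ]
  X <- as.matrix(wide[, -1, drop = FALSE])
  ## candidates: complete across the modeled years and with variance
  ok <- apply(X, 2, function(cc) !anyNA(cc) && stats::sd(cc) > 0)
  X <- X[, ok, drop = FALSE]
  X <- scale(X)
  y <- year_effects$effect[match(yrs, year_effects$year)]
  if (detrend && length(unique(yrs)) > 2L) {
    y <- stats::residuals(lm(y ~ as.numeric(yrs)))
  }

  selected <- integer(0)
  base_fit <- lm(y ~ 1)
  crit <- aicc(base_fit)
  while (length(selected) < max_terms && ncol(X) > length(selected)) {
    cand <- setdiff(seq_len(ncol(X)), selected)
    scores <- vapply(cand, function(j) {
      aicc(lm(y ~ X[, c(selected, j), drop = FALSE]))
    }, numeric(1))
    if (min(scores) >= crit - delta) break
    selected <- c(selected, cand[which.min(scores)])
    crit <- min(scores)
  }
  if (length(selected)) {
    fit <- lm(y ~ X[, selected, drop = FALSE])
    cf <- coef(fit)
    w <- as.numeric(cbind(1, X[, selected, drop = FALSE]) %*% cf)
    r2 <- summary(fit)$r.squared
    nm <- colnames(X)[selected]
    sel <- tibble(
      variable = sub("_m[0-9]+$", "", nm),
      month = as.integer(sub("^.*_m", "", nm)),
      coefficient = unname(cf[-1])
    )
    intercept <- unname(cf[1])
  } else {
    sel <- tibble(variable = character(), month = integer(),
                  coefficient = numeric())
    intercept <- mean(y)
    w <- rep(intercept, length(yrs))
    r2 <- 0
  }
  structure(list(selected = sel, intercept = intercept, r_squared = r2,
                 index = tibble(year = yrs, w = w),
                 n_years = length(yrs)),
            class = "hp_weather_index")
}

#' @exportS3Method base::print
print.hp_weather_index <- function(x, ...) {
  cat("<hp_weather_index> ", nrow(x$selected), " terms, R^2 = ",
      round(x$r_squared, 3), " over ", x$n_years, " years\n", sep = "")
  if (nrow(x$selected)) print(x$selected)
  invisible(x)
}

#' Step 3b: flag anomalous years by the conjunction rule
#'
#' A year is flagged only when both (i) its residual CV exceeds `k_cv` times
#' the mean CV of all other years and (ii) its weather index deviates from
#' the other years' mean by more than `k_w` of their standard deviations.
#' Either signal alone is not sufficient — an inflated CV with unremarkable
#' weather, or vice versa, leaves the year in the data.
#'
#' @param cv Tibble `year`, `cv` from [year_cv()].
#' @param index An `hp_weather_index` (or tibble `year`, `w`).
#' @param k_cv CV inflation threshold (multiplicative).
#' @param k_w Weather-index anomaly threshold (in SDs of the other years).
#' @return A tibble: `year`, `cv_ratio`, `w_z`, `flagged`.
#' @export
flag_outlier_years <- function(cv, index, k_cv = 2, k_w = 3) {
  cv <- as_tibble(cv)
  idx <- if (inherits(index, "hp_weather_index")) index$index else
    as_tibble(index)
  d <- dplyr::inner_join(cv[, c("year", "cv")], idx, by = "year")
  if (nrow(d) < 3L) abort("need at least 3 years to flag outlier years")
  n <- nrow(d)
  cv_ratio <- w_z <- numeric(n)
  for (i in seq_len(n)) {
    others_cv <- d$cv[-i]
    others_w <- d$w[-i]
    cv_ratio[i] <- d$cv[i] / mean(others_cv)
    sw <- stats::sd(others_w)
    w_z[i] <- if (sw > 0) abs(d$w[i] - mean(others_w)) / sw else 0
  }
  tibble(year = d$year, cv_ratio = cv_ratio, w_z = w_z,
         flagged = cv_ratio > k_cv & w_z > k_w)
}

#' Run the full three-step quality control
#'
#' Applies, in order: (1) the plausibility rules, (2) one studentized-
#' residual/Bonferroni-Holm outlier pass, (3) the year screen (residual CV
#' plus weather-parameter index, conjunction rule), removing all records of
#' flagged year x trait combinations. After step 3 the variance components
#' are re-estimated and entry-mean heritabilities before (post-plausibility)
#' and after the full QC are reported. Step 3 is skipped, with a note in the
#' report, when no weather table is available or fewer than `min_years`
#' years remain.
#'
#' @param data An `hp_dataset` (weather taken from it) or records tibble.
#' @param rules Plausibility rule set for step 1.
#' @param alpha Familywise error rate of the Holm outlier test.
#' @param k_cv,k_w Conjunction thresholds for the year screen.
#' @param trait Trait to process (defaults to the single trait present).
#' @param heterogeneous Year-specific residual variances in all model fits.
#' @param weather Monthly weather tibble, overriding the dataset's.
#' @param min_years Minimum years for the weather-index stage.
#' @return A list of class `hp_qc`: `records` (clean), `report` (list with
#'   `step1`, `step2`, `step3` details, per-step counts and fractions),
#'   `components_before`, `components_after` (tibbles incl. h2), `fits`
#'   (selected intermediate fits).
#' @export
qc_pipeline <- function(data, rules = plausibility_rules(), alpha = 0.05,
                        k_cv = 2, k_w = 3, trait = NULL,
                        heterogeneous = TRUE, weather = NULL,
                        min_years = 8L) {
  if (inherits(data, "hp_dataset")) {
    weather <- weather %||% data$weather
    records <- data$records
    passport <- data$passport
  } else {
    records <- as_tibble(data)
    passport <- NULL
  }
  if (!is.null(trait)) records <- records[records$trait == trait, ]
  empty_report <- list(
    step1 = tibble(row = integer(), rule = character()),
    step2 = tibble(), step3 = list(flagged_years = character()),
    counts = tibble(step = c("plausibility", "outliers", "years"),
                    tested = 0L, dropped = 0L, fraction = NA_real_)
  )
  if (!nrow(records)) {
    return(structure(list(records = records, report = empty_report,
                          components_before = NULL, components_after = NULL,
                          fits = list()), class = "hp_qc"))
  }

  ## step 1 -----------------------------------------------------------------
  s1 <- plausibility_filter(records, rules, passport = passport)
  rec1 <- s1$records
  if (!nrow(rec1)) {
    rep0 <- empty_report
    rep0$step1 <- s1$report
    rep0$counts$tested[1] <- s1$n_tested
    rep0$counts$dropped[1] <- s1$n_dropped
    rep0$counts$fraction[1] <- s1$n_dropped / s1$n_tested
    return(structure(list(records = rec1, report = rep0,
                          components_before = NULL, components_after = NULL,
                          fits = list()), class = "hp_qc"))
  }

  comp_before <- estimate_components(rec1, heterogeneous = heterogeneous)

  ## step 2 -----------------------------------------------------------------
  s2 <- outlier_pass(rec1, alpha = alpha, heterogeneous = heterogeneous)
  rec2 <- s2$records

  ## step 3 -----------------------------------------------------------------
  step3 <- list(flagged_years = character(), cv = NULL, index = NULL,
                skipped = FALSE, note = NULL)
  rec3 <- rec2
  n_years_left <- length(unique(rec2$year))
  if (is.null(weather) || n_years_left < min_years || !heterogeneous) {
    step3$skipped <- TRUE
    step3$note <- if (is.null(weather)) "no weather data" else
      if (!heterogeneous) "homogeneous residuals requested" else
        "too few years"
  } else {
    fit_y <- fit_mixed(rec2, "value", fixed = "year",
                       random = "accession_id", residual_by = "year")
    cv <- year_cv(fit_y)
    ye <- tibble(year = as.integer(cv$year), effect = cv$ye)
    idx <- fit_weather_index(ye, weather, min_years = min_years)
    cv$year <- as.integer(cv$year)
    fl <- flag_outlier_years(cv, idx, k_cv = k_cv, k_w = k_w)
    step3$cv <- cv
    step3$index <- idx
    step3$decision <- fl
    step3$flagged_years <- fl$year[fl$flagged]
    if (length(step3$flagged_years)) {
      rec3 <- rec2[!rec2$year %in% step3$flagged_years, ]
    }
  }

  comp_after <- estimate_components(rec3, heterogeneous = heterogeneous)

  counts <- tibble(
    step = c("plausibility", "outliers", "years"),
    tested = c(s1$n_tested, nrow(rec1), nrow(rec2)),
    dropped = c(s1$n_dropped, nrow(s2$flags), nrow(rec2) - nrow(rec3)),
  )
  counts$fraction <- counts$dropped / counts$tested

  structure(list(
    records = rec3,
    report = list(step1 = s1$report, step2 = s2$flags, step3 = step3,
                  counts = counts),
    components_before = comp_before$components,
    components_after = comp_after$components,
    fits = list(outlier_before = s2$fit_before, outlier_after = s2$fit_after,
                components_after = comp_after$fit)
  ), class = "hp_qc")
}

#' @exportS3Method base::print
print.hp_qc <- function(x, ...) {
  cat("<hp_qc> three-step quality control\n")
  if (nrow(x$report$counts) && any(x$report$counts$tested > 0)) {
    print(x$report$counts)
    if (!is.null(x$components_before)) {
      cat(sprintf("  h2 before QC: %.3f   after QC: %.3f\n",
                  x$components_before$h2, x$components_after$h2))
    }
    fy <- x$report$step3$flagged_years
    if (length(fy)) cat("  excluded years:", paste(fy, collapse = ", "), "\n")
    if (isTRUE(x$report$step3$skipped)) {
      cat("  year screen skipped:", x$report$step3$note, "\n")
    }
  } else {
    cat("  (empty dataset)\n")
  }
  invisible(x)
}
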