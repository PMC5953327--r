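## tidy()/glance()/autoplot() methods ----------------------------------------

#' Tidy a REML mixed-model fit
#'
#' @param x An `hp_fit`.
#' @param effects Which part to return: `"var_comp"` (variance components,
#'   including the residual groups), `"fixed"` (BLUEs with standard errors),
#'   or `"ran_vals"` (BLUPs).
#' @param ... Unused.
#' @return A tibble in broom.mixed-like shape.
#' @export
tidy.hp_fit <- function(x, effects = c("var_comp", "fixed", "ran_vals"), ...) {
  effects <- match.arg(effects)
  switch(effects,
    var_comp = dplyr::bind_rows(
      dplyr::transmute(x$variance_components,
                       effect = "ran_pars", group = .data$term,
                       term = "var", estimate = .data$variance,
                       boundary = .data$boundary),
      dplyr::transmute(x$residual_variances,
                       effect = "ran_pars",
                       group = paste0("residual:", .data$group),
                       term = "var", estimate = .data$variance,
                       boundary = FALSE)
    ),
    fixed = dplyr::transmute(x$fixed_effects,
                             effect = "fixed", term = .data$term,
                             level = .data$level,
                             estimate = .data$estimate,
                             std.error = .data$se),
    ran_vals = dplyr::transmute(x$random_effects,
                                effect = "ran_vals", group = .data$term,
                                level = .data$level,
                                estimate = .data$blup)
  )
}

#' Glance at a REML mixed-model fit
#'
#' @param x An `hp_fit`.
#' @param ... Unused.
#' @return One-row tibble: observations, restricted log-likelihood,
#'   iterations, convergence flag, number of residual-variance groups.
#' @export
glance.hp_fit <- function(x, ...) {
  tibble(
    nobs = x$n,
    logLik = x$logLik,
    iterations = x$convergence$iterations,
    converged = x$convergence$converged,
    n_resid_groups = nrow(x$residual_variances),
    sigma2_e_mean = mean_residual_variance(x)
  )
}

#' Tidy a QC pipeline report
#'
#' @param x An `hp_qc`.
#' @param ... Unused.
#' @return The per-step counts table with tested/dropped/fraction, plus the
#'   flagged years pasted into an attribute-free `note` column.
#' @export
tidy.hp_qc <- function(x, ...) {
  out <- x$report$counts
  out$note <- c("", "",
                if (isTRUE(x$report$step3$skipped)) {
                  paste0("skipped: ", x$report$step3$note)
                } else if (length(x$report$step3$flagged_years)) {
                  paste0("excluded years: ",
                         paste(x$report$step3$flagged_years, collapse = ","))
                } else "")
  out
}

#' @export
glance.hp_qc <- function(x, ...) {
  tibble(
    n_in = x$report$counts$tested[1],
    n_out = nrow(x$records),
    h2_before = if (is.null(x$components_before)) NA_real_ else
      x$components_before$h2,
    h2_after = if (is.null(x$components_after)) NA_real_ else
      x$components_after$h2,
    sigma2_e_before = if (is.null(x$components_before)) NA_real_ else
      x$components_before$sigma2_e_mean,
    sigma2_e_after = if (is.null(x$components_after)) NA_real_ else
      x$components_after$sigma2_e_mean,
    n_years_excluded = length(x$report$step3$flagged_years)
  )
}

#' Tidy a missing-pattern scenario result
#'
#' @param x An `hp_scenario`.
#' @param ... Unused.
#' @return The per-replicate variance-component tibble with the scenario
#'   label attached.
#' @export
tidy.hp_scenario <- function(x, ...) {
  dplyr::mutate(x$per_replicate, scenario = x$scenario,
                .before = 1)
}

#' @export
glance.hp_scenario <- function(x, ...) {
  s <- x$per_replicate
  tibble(
    scenario = x$scenario,
    n_replicates = x$n_replicates,
    n_fail = x$n_fail,
    sigma2_G_mean = mean(s$sigma2_G),
    sigma2_G_sd = stats::sd(s$sigma2_G),
    sigma2_G_ref = x$reference$components$sigma2_G
  )
}

#' Diagnostic plot of a mixed-model fit
#'
#' Studentized residuals per residual group (regeneration year), with the
#' standard-normal reference band; the display used to inspect the outlier
#' stage.
#'
#' @param object An `hp_fit`.
#' @param band Reference band half-width in SD units (default 3).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hp_fit <- function(object, band = 3, ...) {
  d <- object$residuals
  ggplot2::ggplot(d, ggplot2::aes(x = .data$resid_group,
                                  y = .data$studentized)) +
    ggplot2::geom_jitter(width = 0.25, height = 0, alpha = 0.4, size = 0.7) +
    ggplot2::geom_hline(yintercept = c(-band, band), linetype = "dashed") +
    ggplot2::labs(x = "residual group (year)", y = "studentized residual") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Incidence plot of the accession-by-year observation structure
#'
#' @param data An `hp_dataset` or records tibble.
#' @param max_accessions Cap on plotted accessions (sampled) to keep the
#'   panel readable.
#' @return A ggplot object (tiles = observed cells).
#' @export
plot_incidence <- function(data, max_accessions = 500L) {
  records <- if (inherits(data, "hp_dataset")) data$records else
    as_tibble(data)
  acc <- unique(records$accession_id)
  if (length(acc) > max_accessions) {
    acc <- sample(acc, max_accessions)
    records <- records[records$accession_id %in% acc, ]
  }
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$year,
                               y = factor(.data$accession_id))) +
    ggplot2::geom_tile(fill = "grey20") +
    ggplot2::labs(x = "year", y = "accession") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
}

#' Precision plot of a set of missing-pattern scenarios
#'
#' Per-replicate genetic-variance estimates by scenario, with the full-data
#' reference as a horizontal line.
#'
#' @param object An `hp_scenario` or list of them.
#' @param parameter Component to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hp_scenario <- function(object, parameter = "sigma2_G", ...) {
  results <- if (inherits(object, "hp_scenario")) list(object) else object
  d <- dplyr::bind_rows(lapply(results, tidy))
  refv <- results[[1L]]$reference$components[[parameter]]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$scenario,
                                  y = .data[[parameter]])) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = refv, linetype = "dashed") +
    ggplot2::labs(y = parameter, x = "scenario") +
    ggplot2::theme_minimal()
}

#' Weather-index and residual-CV year screen plot
#'
#' @param decision Tibble from [flag_outlier_years()].
#' @return A ggplot object with the conjunction thresholds.
#' @export
plot_year_screen <- function(decision) {
  ggplot2::ggplot(decision, ggplot2::aes(x = .data$cv_ratio, y = .data$w_z,
                                         label = .data$year)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$flagged)) +
    ggplot2::geom_text(vjust = -0.6, size = 2.6, check_overlap = TRUE) +
    ggplot2::labs(x = "CV ratio vs. other years",
                  y = "|weather index anomaly| (SD)") +
    ggplot2::theme_minimal()
}
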