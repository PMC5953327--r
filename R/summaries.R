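## Post-estimation summaries: panel comparisons, NRP, temporal trend --------

#' Correlate two BLUE tables over their common accessions
#'
#' Pearson and Spearman correlations between two sets of accession
#' estimates (e.g. historical vs. validation-trial BLUEs), over the
#' intersection of accessions.
#'
#' @param a,b Tibbles with `accession_id` and `blue` (any estimate column
#'   named `blue`).
#' @return A tibble: `n_common`, `pearson`, `spearman`.
#' @export
correlate_blues <- function(a, b) {
  a <- as_tibble(a); b <- as_tibble(b)
  m <- dplyr::inner_join(a[, c("accession_id", "blue")],
                         b[, c("accession_id", "blue")],
                         by = "accession_id", suffix = c("_a", "_b"))
  m <- m[complete.cases(m), ]
  if (nrow(m) < 3L) {
    abort(paste0("only ", nrow(m), " overlapping accessions; need >= 3"))
  }
  tibble(n_common = nrow(m),
         pearson = cor(m$blue_a, m$blue_b, method = "pearson"),
         spearman = cor(m$blue_a, m$blue_b, method = "spearman"))
}

#' Normalized rank product of accessions across observation years
#'
#' Within each year, accessions are ranked on the trait (ties get average
#' ranks) and ranks are scaled to (0, 1] by the number of accessions in that
#' year; an accession's NRP aggregates its scaled ranks across the years in
#' which it was observed — geometric mean by default, arithmetic on request.
#' The NRP is invariant to any monotone within-year transformation of the
#' trait values, which is both its appeal (robustness) and its limitation
#' (the scale information the BLUE retains is discarded).
#'
#' @param records Phenotype records (`accession_id`, `year`, `value`, and
#'   optionally `trait`).
#' @param trait Optional trait filter.
#' @param method `"geometric"` (default) or `"arithmetic"` mean of scaled
#'   ranks.
#' @return A tibble: `accession_id`, `n_years`, `nrp` in (0, 1].
#' @export
normalized_rank_product <- function(records, trait = NULL,
                                    method = c("geometric", "arithmetic")) {
  method <- match.arg(method)
  records <- as_tibble(records)
  if (!is.null(trait)) records <- records[records$trait == trait, ]
  if (!nrow(records)) abort("no records")
  records |>
    dplyr::group_by(.data$year) |>
    dplyr::mutate(scaled_rank = rank(.data$value) / dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::group_by(accession_id = as.character(.data$accession_id)) |>
    dplyr::summarise(
      n_years = dplyr::n(),
      nrp = if (method == "geometric") exp(mean(log(.data$scaled_rank)))
            else mean(.data$scaled_rank),
      .groups = "drop"
    )
}

#' Temporal trend of year effects
#'
#' Ordinary least-squares slope of the year-level estimates on calendar
#' year: the average change of the trait per year (negative slope = earlier
#' flowering over time for flowering-time data). Accepts a fitted model
#' (year effects extracted as in [year_cv()]) or a tibble `year`, `effect`.
#'
#' @param x An `hp_fit` with a year term, or a tibble `year`, `effect`.
#' @param min_years Minimum number of distinct years (default 10).
#' @return A tibble: `slope`, `se`, `p_value`, `n_years`.
#' @export
temporal_trend <- function(x, min_years = 10L) {
  if (inherits(x, "hp_fit")) {
    if ("year" %in% x$fixed) {
      fe <- x$fixed_effects[x$fixed_effects$term == "year", ]
      d <- tibble(year = as.numeric(fe$level), effect = fe$estimate)
    } else if ("year" %in% x$random) {
      re <- x$random_effects[x$random_effects$term == "year", ]
      d <- tibble(year = as.numeric(re$level), effect = re$blup)
    } else {
      abort("fit has no year term")
    }
  } else {
    d <- as_tibble(x)
    stopifnot(all(c("year", "effect") %in% names(d)))
    d$year <- as.numeric(d$year)
  }
  if (length(unique(d$year)) < min_years) {
    abort(paste0("need >= ", min_years, " years for a trend estimate (have ",
                 length(unique(d$year)), ")"))
  }
  fit <- lm(effect ~ year, data = d)
  sm <- summary(fit)$coefficients
  tibble(slope = sm["year", 1], se = sm["year", 2],
         p_value = sm["year", 4], n_years = length(unique(d$year)))
}

#' Compare the phenotypic diversity of a panel against a reference
#'
#' Ratio of REML genetic variances and of BLUE ranges between a panel and a
#' reference set (both as percentages of the reference), quantifying how
#' much of the reference collection's diversity a panel represents.
#'
#' @param panel,reference Lists with `records` (for the variance fits) and
#'   optionally `blues`; plain record tibbles are also accepted.
#' @param heterogeneous Year-specific residual variances in the fits.
#' @return A tibble: `variance_ratio_pct`, `range_ratio_pct`,
#'   `sigma2_G_panel`, `sigma2_G_reference`.
#' @export
panel_variance_ratio <- function(panel, reference, heterogeneous = TRUE) {
  get_records <- function(x) {
    if (is.data.frame(x)) as_tibble(x)
    else if (inherits(x, "hp_dataset")) x$records
    else as_tibble(x$records)
  }
  prec <- get_records(panel)
  rrec <- get_records(reference)
  if (length(unique(prec$accession_id)) < 3L) {
    abort("panel has fewer than 3 accessions; genetic variance inestimable")
  }
  pc <- estimate_components(prec, heterogeneous = heterogeneous)
  rc <- estimate_components(rrec, heterogeneous = heterogeneous)
  if (rc$components$sigma2_G <= 0) {
    abort("reference genetic variance is zero; ratio undefined")
  }
  pb <- estimate_blues(prec, heterogeneous = heterogeneous)$blues$blue
  rb <- estimate_blues(rrec, heterogeneous = heterogeneous)$blues$blue
  tibble(
    variance_ratio_pct = 100 * pc$components$sigma2_G / rc$components$sigma2_G,
    range_ratio_pct = 100 * diff(range(pb)) / diff(range(rb)),
    sigma2_G_panel = pc$components$sigma2_G,
    sigma2_G_reference = rc$components$sigma2_G
  )
}
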