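## Resampling study: block-wise (MAR-violating) vs. random missingness ------
##
## From a complete accession x year reference dataset, repeatedly apply one
## of three observation schedules -- blocks of accessions sharing their
## observed years, defined by origin (A) or at random (B), or fully
## independent per-accession year subsets (C, MCAR) -- refit the
## historical-data model, and summarise bias and precision of the variance
## components and BLUEs against the full-data reference fit.

#' Run one missing-pattern scenario
#'
#' @param records Complete records: every accession observed in every year
#'   (checked; the reference fit requires it).
#' @param scenario `"A"` (blocks by origin), `"B"` (random blocks of the same
#'   sizes, re-randomized each replicate), or `"C"` (MCAR, independent year
#'   subsets per accession).
#' @param blocks Tibble `accession_id`, `block`; required for scenario A and
#'   (for its block sizes) B.
#' @param years_per_block Observed years per block/accession (3 of 6 in the
#'   default design).
#' @param n_replicates Number of resampling runs.
#' @param seed Seed for the replicate masks.
#' @param heterogeneous Year-specific residual variances in the fits.
#' @param blues Also estimate per-replicate accession BLUEs? (doubles the
#'   model fits).
#' @param max_fail Error if more than this fraction of replicates fails to
#'   converge; failures below it are recorded and skipped.
#' @return An object of class `hp_scenario`: `scenario`, `per_replicate`
#'   (tibble of variance components per converged replicate), `blue_mat`
#'   (accessions x replicates matrix or `NULL`), `reference` (full-data
#'   components and BLUEs), `n_fail`.
#' @export
run_scenario <- function(records, scenario = c("A", "B", "C"), blocks = NULL,
                         years_per_block = 3L, n_replicates = 100L, seed = 1L,
                         heterogeneous = TRUE, blues = TRUE,
                         max_fail = 0.05) {
  scenario <- match.arg(scenario)
  records <- as_tibble(records)
  yrs <- sort(unique(records$year))
  acc <- sort(unique(as.character(records$accession_id)))
  if (nrow(records) != length(yrs) * length(acc)) {
    abort("records must be complete over accessions x years for the reference fit")
  }
  if (years_per_block > length(yrs)) {
    abort("years_per_block exceeds the number of years")
  }
  if (scenario %in% c("A", "B")) {
    if (is.null(blocks)) abort(paste0("scenario ", scenario, " needs `blocks`"))
    blocks <- as_tibble(blocks)
    blocks$accession_id <- as.character(blocks$accession_id)
    ## coverage check: unconstrained block-year sampling can leave years empty
    n_blocks <- length(unique(blocks$block))
    if (n_blocks * years_per_block < length(yrs)) {
      warn("blocks x years_per_block cannot cover all years; some replicates will drop years entirely")
    }
  }

  pattern <- switch(scenario, A = "block_by_origin", B = "block_random",
                    C = "mcar")

  ref_comp <- estimate_components(records, heterogeneous = heterogeneous)
  ref_blue <- if (blues) estimate_blues(records,
                                        heterogeneous = heterogeneous) else NULL

  local_seed(seed)
  per_rep <- vector("list", n_replicates)
  blue_mat <- if (blues) matrix(NA_real_, length(acc), n_replicates,
                                dimnames = list(acc, NULL)) else NULL
  n_fail <- 0L
  fail_log <- character(0)
  for (r in seq_len(n_replicates)) {
    sub <- apply_missingness(records, pattern = pattern,
                             years_observed = years_per_block,
                             blocks = blocks, seed = NULL)
    ## block-wise masks can draw disconnected accession x year designs;
    ## that is the phenomenon under study, not a usage error, so the
    ## per-fit connectivity warnings are muted here
    res <- tryCatch(suppressWarnings({
      comp <- estimate_components(sub, heterogeneous = heterogeneous)
      bl <- if (blues) estimate_blues(sub, heterogeneous = heterogeneous) else NULL
      list(comp = comp$components, bl = bl)
    }), error = function(e) e)
    if (inherits(res, "error")) {
      n_fail <- n_fail + 1L
      fail_log <- c(fail_log, paste0("replicate ", r, ": ",
                                     conditionMessage(res)))
      next
    }
    per_rep[[r]] <- dplyr::mutate(res$comp, replicate = r)
    if (blues) {
      blue_mat[res$bl$blues$accession_id, r] <- res$bl$blues$blue
    }
  }
  if (n_fail > max_fail * n_replicates) {
    abort(paste0(n_fail, " of ", n_replicates, " replicates failed to ",
                 "converge (limit ", round(100 * max_fail), "%):\n",
                 paste(utils::head(fail_log, 5), collapse = "\n")))
  }
  structure(list(
    scenario = scenario,
    per_replicate = dplyr::bind_rows(per_rep),
    blue_mat = blue_mat,
    reference = list(components = ref_comp$components,
                     blues = if (blues) ref_blue$blues else NULL),
    n_replicates = n_replicates,
    n_fail = n_fail,
    fail_log = fail_log
  ), class = "hp_scenario")
}

#' @exportS3Method base::print
print.hp_scenario <- function(x, ...) {
  cat("<hp_scenario> scenario", x$scenario, "-",
      nrow(x$per_replicate), "converged replicates",
      if (x$n_fail) paste0("(", x$n_fail, " failed)") else "", "\n")
  s <- x$per_replicate
  for (p in c("sigma2_G", "sigma2_Y", "sigma2_e_mean")) {
    cat(sprintf("  %-14s mean %8.3f  sd %7.3f  (reference %8.3f)\n", p,
                mean(s[[p]]), stats::sd(s[[p]]), x$reference$components[[p]]))
  }
  invisible(x)
}

#' Compare missing-pattern scenarios
#'
#' Summarises per-parameter mean, SD across replicates, mean bias (percent
#' of the full-data reference value) and the SD ratio against the MCAR
#' scenario C (or against the first result if no C is supplied). For BLUEs
#' the per-accession SD across replicates is averaged, and the bias is the
#' mean relative deviation of the replicate-mean BLUE from the reference
#' BLUE. All results must come from the same reference dataset.
#'
#' @param ... `hp_scenario` objects (or a single list of them).
#' @return A tibble: `scenario`, `parameter`, `mean`, `sd`, `bias_pct`,
#'   `sd_ratio_vs_C`.
#' @export
compare_scenarios <- function(...) {
  results <- list(...)
  if (length(results) == 1L && !inherits(results[[1L]], "hp_scenario")) {
    results <- results[[1L]]
  }
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, TRUE, "hp_scenario")))
  ref0 <- results[[1L]]$reference$components
  for (r in results[-1L]) {
    if (max(abs(as.numeric(r$reference$components[1, 1:3]) -
                as.numeric(ref0[1, 1:3]))) > 1e-6) {
      abort("scenario results have mismatched reference fits")
    }
  }
  rows <- purrr::map(results, function(r) {
    s <- r$per_replicate
    out <- purrr::map(c("sigma2_G", "sigma2_Y", "sigma2_e_mean"),
                      function(p) {
      refv <- r$reference$components[[p]]
      tibble(scenario = r$scenario, parameter = p,
             mean = mean(s[[p]]), sd = stats::sd(s[[p]]),
             bias_pct = 100 * (mean(s[[p]]) - refv) / refv)
    })
    out <- dplyr::bind_rows(out)
    if (!is.null(r$blue_mat)) {
      bm <- r$blue_mat
      ref_blue <- r$reference$blues$blue[
        match(rownames(bm), r$reference$blues$accession_id)]
      acc_sd <- apply(bm, 1, stats::sd, na.rm = TRUE)
      acc_mean <- rowMeans(bm, na.rm = TRUE)
      out <- dplyr::bind_rows(out, tibble(
        scenario = r$scenario, parameter = "blue",
        mean = mean(acc_mean), sd = mean(acc_sd),
        bias_pct = 100 * mean((acc_mean - ref_blue) / ref_blue)
      ))
    }
    out
  })
  tab <- dplyr::bind_rows(rows)
  base <- tab[tab$scenario == "C", c("parameter", "sd")]
  if (!nrow(base)) base <- tab[tab$scenario == tab$scenario[1L],
                               c("parameter", "sd")]
  base <- base[!duplicated(base$parameter), ]
  names(base)[2] <- "sd_C"
  tab <- dplyr::left_join(tab, base, by = "parameter")
  tab$sd_ratio_vs_C <- tab$sd / tab$sd_C
  tab$sd_C <- NULL
  tab
}
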