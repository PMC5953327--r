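## Data model and delimited-text IO for historical genebank phenotypes ------

#' Bundle phenotype, passport and weather tables into a historical dataset
#'
#' Light container used throughout the package: a list with `records`
#' (one row per accession x year x trait observation), optional `passport`
#' (one row per accession) and optional `weather` (one row per year x month).
#' Invariants are validated: at most one record per
#' (accession, year, trait) cell, finite trait values, months in 1..12 with
#' at most one weather row per (year, month), and — when a passport is
#' supplied — every recorded accession present in it.
#'
#' @param records Data frame with at least `accession_id`, `year`, `trait`,
#'   `value`; optional `sowing_date`, `taxon`, `plot_id`.
#' @param passport Optional data frame with `accession_id` (unique),
#'   `origin_country`, `acquisition_year`, `available`.
#' @param weather Optional data frame with `year`, `month` and any of
#'   `rainfall`, `humidity`, `t_avg`, `t_min`, `t_max`.
#' @return An object of class `hp_dataset` (a named list of tibbles).
#' @export
historical_dataset <- function(records, passport = NULL, weather = NULL) {
  records <- as_tibble(records)
  need <- c("accession_id", "year", "trait", "value")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    abort(paste0("records are missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(records)) {
    if (any(!is.finite(records$value))) {
      abort("records contain non-finite trait values")
    }
    key <- paste(records$accession_id, records$year, records$trait)
    if (anyDuplicated(key)) {
      abort("duplicate (accession, year, trait) records; see read_phenotypes() for load-time rejection")
    }
  }
  if (!is.null(passport)) {
    passport <- as_tibble(passport)
    if (!"accession_id" %in% names(passport)) {
      abort("passport is missing column 'accession_id'")
    }
    if (anyDuplicated(passport$accession_id)) {
      abort("passport accession_id values must be unique")
    }
    if (nrow(records) &&
        !all(unique(records$accession_id) %in% passport$accession_id)) {
      abort("every recorded accession must appear in the passport table")
    }
  }
  if (!is.null(weather)) {
    weather <- as_tibble(weather)
    if (!all(c("year", "month") %in% names(weather))) {
      abort("weather is missing 'year'/'month' columns")
    }
    if (nrow(weather)) {
      if (any(!weather$month %in% 1:12)) abort("weather months must be in 1..12")
      if (anyDuplicated(paste(weather$year, weather$month))) {
        abort("at most one weather record per (year, month)")
      }
    }
  }
  structure(list(records = records, passport = passport, weather = weather),
            class = "hp_dataset")
}

#' @exportS3Method base::print
print.hp_dataset <- function(x, ...) {
  cat("<hp_dataset>\n")
  cat("  records: ", nrow(x$records), " (",
      length(unique(x$records$accession_id)), " accessions, ",
      length(unique(x$records$year)), " years, traits: ",
      paste(unique(x$records$trait), collapse = ", "), ")\n", sep = "")
  if (!is.null(x$passport)) cat("  passport:", nrow(x$passport), "accessions\n")
  if (!is.null(x$weather)) {
    cat("  weather: ", nrow(x$weather), " monthly rows (",
        length(unique(x$weather$year)), " years)\n", sep = "")
  }
  invisible(x)
}

default_column_map <- function() {
  list(accession_id = "accession_id", year = "year", trait = "trait",
       value = "value", sowing_date = "sowing_date", taxon = "taxon",
       plot_id = "plot_id")
}

#' Read long-format phenotype records from delimited text
#'
#' Reads a CSV of one observation per row, maps legacy column names via
#' `column_map`, validates row by row, and rejects — with a recorded reason
#' rather than an error — rows with unparseable or non-finite values,
#' missing keys, years outside `year_range`, or a duplicate
#' (accession, year, trait) key (first occurrence wins).
#'
#' @param path Path to a delimited text file with a header.
#' @param column_map Named list mapping the canonical names
#'   (`accession_id`, `year`, `trait`, `value`, and optionally
#'   `sowing_date`, `taxon`, `plot_id`) to the file's column names.
#' @param year_range Two integers; records outside are rejected.
#' @param delim Field delimiter.
#' @param duplicates `"reject"` (default: the model has a single residual per
#'   accession x year cell, so later duplicates are rejected) or `"average"`
#'   (cell values averaged, with a warning).
#' @return An `hp_dataset` with a `diagnostics` attribute: a list with
#'   `n_read`, `n_kept`, and `rejected` (tibble `row`, `reason`).
#' @export
read_phenotypes <- function(path, column_map = default_column_map(),
                            year_range = c(1900L, 2100L), delim = ",",
                            duplicates = c("reject", "average")) {
  duplicates <- match.arg(duplicates)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  cmap <- utils::modifyList(default_column_map(), as.list(column_map))
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  for (fld in c("accession_id", "year", "trait", "value")) {
    if (!cmap[[fld]] %in% names(raw)) {
      abort(paste0("mandatory column '", cmap[[fld]], "' (", fld,
                   ") not found in ", path))
    }
  }
  n_read <- nrow(raw)
  rej <- tibble(row = integer(), reason = character())
  if (n_read == 0L) {
    ds <- historical_dataset(tibble(accession_id = character(),
                                    year = integer(), trait = character(),
                                    value = numeric()))
    attr(ds, "diagnostics") <- list(n_read = 0L, n_kept = 0L, rejected = rej)
    return(ds)
  }

  out <- tibble(
    accession_id = as.character(raw[[cmap$accession_id]]),
    year = suppressWarnings(as.integer(raw[[cmap$year]])),
    trait = as.character(raw[[cmap$trait]]),
    value = suppressWarnings(as.numeric(raw[[cmap$value]]))
  )
  if (cmap$sowing_date %in% names(raw)) {
    out$sowing_date <- as.Date(raw[[cmap$sowing_date]], format = "%Y-%m-%d")
  }
  if (cmap$taxon %in% names(raw)) out$taxon <- as.character(raw[[cmap$taxon]])
  if (cmap$plot_id %in% names(raw)) out$plot_id <- as.character(raw[[cmap$plot_id]])

  reason <- rep(NA_character_, n_read)
  bad_key <- is.na(out$accession_id) | out$accession_id == "" |
    is.na(out$trait) | out$trait == ""
  reason[bad_key] <- "missing accession or trait"
  bad_year <- is.na(reason) &
    (is.na(out$year) | out$year < year_range[1] | out$year > year_range[2])
  reason[bad_year] <- "unparseable or out-of-range year"
  bad_val <- is.na(reason) & !is.finite(out$value)
  reason[bad_val] <- "unparseable value"
  key <- paste(out$accession_id, out$year, out$trait)
  dup <- is.na(reason) & duplicated(key)
  if (duplicates == "reject") {
    reason[dup] <- "duplicate"
  }

  keep <- is.na(reason)
  rej <- tibble(row = which(!keep), reason = reason[!keep])
  kept <- out[keep, ]
  if (duplicates == "average" && any(dup)) {
    warn(paste0(sum(dup), " duplicate (accession, year, trait) record(s) ",
                "averaged into their cells"))
    kept <- kept |>
      dplyr::group_by(.data$accession_id, .data$year, .data$trait) |>
      dplyr::summarise(dplyr::across(!dplyr::any_of("value"), dplyr::first),
                       value = mean(.data$value), .groups = "drop")
  }
  ds <- historical_dataset(kept)
  attr(ds, "diagnostics") <- list(n_read = n_read, n_kept = sum(keep),
                                  rejected = rej)
  ds
}

#' Read a passport table (accession origin and availability)
#'
#' @param path CSV with columns `accession_id` and optionally
#'   `origin_country`, `acquisition_year`, `available`.
#' @return A tibble, one row per accession.
#' @export
read_passport <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  pp <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"accession_id" %in% names(pp)) {
    abort("passport file lacks 'accession_id'")
  }
  pp$accession_id <- as.character(pp$accession_id)
  if (anyDuplicated(pp$accession_id)) {
    abort("passport accession_id values must be unique")
  }
  if (!"available" %in% names(pp)) pp$available <- TRUE
  as_tibble(pp)
}

#' Read a monthly weather table
#'
#' @param path CSV with one row per year x month: `year`, `month` and any of
#'   `rainfall` (mm), `humidity` (%), `t_avg`, `t_min`, `t_max` (deg C);
#'   missing cells are allowed.
#' @return A tibble validated for month range and (year, month) uniqueness.
#' @export
read_weather <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  w <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("year", "month") %in% names(w))) {
    abort("weather file needs 'year' and 'month' columns")
  }
  if (any(!w$month %in% 1:12)) abort("weather months must be in 1..12")
  if (anyDuplicated(paste(w$year, w$month))) {
    abort("at most one weather record per (year, month)")
  }
  as_tibble(w)
}

#' Summarise the accession x year incidence structure
#'
#' Reports how densely the accession x year matrix is observed: per-accession
#' and per-year record counts, the overall fill fraction, and the mean number
#' of observation years per accession (the "number of years" entering the
#' entry-mean heritability).
#'
#' @param data An `hp_dataset` or a records data frame.
#' @param trait Optional trait to restrict to; errors if absent from the data.
#' @return A list of class `hp_incidence`: `per_accession`, `per_year`
#'   (tibbles), `n_records`, `n_accessions`, `n_years`, `fill_fraction`,
#'   `mean_obs_per_accession`.
#' @export
incidence_summary <- function(data, trait = NULL) {
  records <- if (inherits(data, "hp_dataset")) data$records else as_tibble(data)
  if (!is.null(trait)) {
    if (!trait %in% records$trait) {
      abort(paste0("trait '", trait, "' not present in the records"))
    }
    records <- records[records$trait == trait, ]
  }
  if (!nrow(records)) abort("no records to summarise")
  per_acc <- records |>
    dplyr::count(.data$accession_id, name = "n_obs") |>
    dplyr::arrange(.data$accession_id)
  per_year <- records |>
    dplyr::count(.data$year, name = "n_obs") |>
    dplyr::arrange(.data$year)
  n_acc <- nrow(per_acc)
  n_yr <- nrow(per_year)
  structure(list(
    per_accession = per_acc,
    per_year = per_year,
    n_records = nrow(records),
    n_accessions = n_acc,
    n_years = n_yr,
    fill_fraction = nrow(records) / (n_acc * n_yr),
    mean_obs_per_accession = mean(per_acc$n_obs)
  ), class = "hp_incidence")
}

#' @exportS3Method base::print
print.hp_incidence <- function(x, ...) {
  cat("<hp_incidence>\n")
  cat(sprintf("  %d records: %d accessions x %d years\n",
              x$n_records, x$n_accessions, x$n_years))
  cat(sprintf("  fill fraction %.3f (%.1f%% of cells empty)\n",
              x$fill_fraction, 100 * (1 - x$fill_fraction)))
  cat(sprintf("  mean observations per accession: %.2f\n",
              x$mean_obs_per_accession))
  invisible(x)
}

#' Write / read a BLUE table as CSV
#'
#' `write_blues()` writes `accession_id`, `trait`, `blue`, `standard_error`,
#' `n_years` with `digits` significant decimals; missing standard errors are
#' written as empty fields, not zeros. `read_blues()` reads the file back
#' into the same shape.
#'
#' @param blues Tibble as returned in `estimate_blues()$blues`.
#' @param path Output path.
#' @param digits Decimal places written.
#' @return `write_blues()` returns `path` invisibly; `read_blues()` a tibble.
#' @export
write_blues <- function(blues, path, digits = 6) {
  blues <- as_tibble(blues)
  if (!nrow(blues)) abort("refusing to write an empty BLUE table")
  se <- if ("se" %in% names(blues)) blues$se else blues$standard_error
  out <- tibble(
    accession_id = as.character(blues$accession_id),
    trait = as.character(blues$trait),
    blue = round(blues$blue, digits),
    standard_error = round(se, digits),
    n_years = blues$n_years
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_blues
#' @export
read_blues <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  readr::read_csv(path, col_types = readr::cols(
    accession_id = readr::col_character(),
    trait = readr::col_character(),
    blue = readr::col_double(),
    standard_error = readr::col_double(),
    n_years = readr::col_integer()
  ), progress = FALSE)
}
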