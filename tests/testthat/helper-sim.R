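# shared fixture builders (everything is generated in code)

# balanced accession x year records with known effects and iid noise
make_balanced <- function(n_acc = 10, n_yr = 4, mu = 100, g = NULL, a = NULL,
                          e_sd = 1, seed = 1, trait = "FT") {
  withr::with_seed(seed, {
    g <- g %||% rnorm(n_acc, 0, 3)
    a <- a %||% rnorm(n_yr, 0, 5)
    d <- tidyr::expand_grid(
      accession_id = sprintf("A%03d", seq_len(n_acc)),
      year = 2000L + seq_len(n_yr)
    )
    ia <- match(d$accession_id, sprintf("A%03d", seq_len(n_acc)))
    iy <- d$year - 2000L
    d$trait <- trait
    d$value <- mu + g[ia] + a[iy] + rnorm(nrow(d), 0, e_sd)
    attr(d, "g") <- g
    attr(d, "a") <- a
    d
  })
}

`%||%` <- rlang::`%||%`

# a minimal hp_fit stand-in carrying only residual information, for testing
# the outlier test in isolation from the REML engine
fake_fit <- function(studentized, group = "all", sigma2 = 1) {
  structure(list(
    residuals = tibble::tibble(
      row = seq_along(studentized),
      fitted = 0, residual = studentized, leverage = 0,
      studentized = studentized,
      resid_group = rep_len(group, length(studentized))
    ),
    residual_variances = tibble::tibble(
      group = unique(rep_len(group, length(studentized))),
      variance = sigma2,
      n = as.integer(table(rep_len(group, length(studentized))))
    )
  ), class = "hp_fit")
}

# independent step-down Holm oracle (direct implementation of the procedure)
holm_oracle <- function(p, alpha) {
  n <- length(p)
  o <- order(p)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    if (p[o[i]] <= alpha / (n - i + 1)) flagged[o[i]] <- TRUE else break
  }
  flagged
}
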