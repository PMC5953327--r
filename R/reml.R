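## number of connected components of the bipartite incidence graph between
## two grouping factors (indices 1..max); union-find over the distinct pairs
n_connected_components <- function(a, b) {
  key <- paste(a, b)
  first <- !duplicated(key)
  a <- a[first]
  b <- b[first] + max(a)
  parent <- seq_len(max(b))
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_along(a)) {
    ra <- find(a[i]); rb <- find(b[i])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(unique(c(a, b)), find, integer(1))
  length(unique(roots))
}

#' Fit a linear mixed model by REML with group-heterogeneous residual variances
#'
#' Fits the Gaussian linear mixed model
#' \deqn{y = X\beta + \sum_k Z_k u_k + e,\qquad u_k \sim N(0, \sigma^2_k I),
#'   \qquad e \sim N(0, R)}
#' where every fixed and random term is a (possibly crossed or nested)
#' grouping factor and the residual covariance \eqn{R} is diagonal with a
#' separate variance per level of `residual_by` (or a single variance when
#' `residual_by = NULL`). Estimation maximises the restricted likelihood via
#' the mixed-model equations: expectation-maximisation steps to warm-start,
#' followed by average-information (AI) updates with step halving. Variance
#' components are constrained non-negative; a component pinned at the lower
#' boundary is reported as such.
#'
#' The first element of `fixed` is coded as cell means (one column per
#' level, no intercept), so for the historical-data model with fixed
#' accessions the fixed-effect estimates are directly the accession BLUEs
#' \eqn{\mu + g_i}. Additional fixed factors are treatment-coded against
#' their first level. When `fixed = NULL` only an intercept is fitted.
#' Nested random terms are written with `:` (e.g. `"trial:replicate"`).
#'
#' Residual-variance groups with fewer than `min_group_size` records are
#' pooled into one shared group, since a per-year variance is not estimable
#' from a single observation.
#'
#' @param data A data frame with one row per observation.
#' @param response Name of the numeric response column.
#' @param fixed Character vector of fixed grouping factors (first one coded
#'   as cell means), or `NULL` for an intercept-only fixed part.
#' @param random Character vector of random grouping factors; interactions
#'   and nesting via `":"`.
#' @param residual_by Optional column name grouping residual variances
#'   (e.g. `"year"` for year-specific error variances); `NULL` for a single
#'   homogeneous residual variance.
#' @param max_iter Maximum REML iterations.
#' @param tol Convergence tolerance on the relative change of the restricted
#'   log-likelihood.
#' @param em_iter Number of initial EM warm-start iterations before switching
#'   to AI updates.
#' @param min_group_size Residual groups smaller than this are pooled.
#' @param verbose Print the iteration trajectory.
#'
#' @return An object of class `hp_fit`: a list with tibbles
#'   `variance_components` (term, variance, boundary flag),
#'   `residual_variances` (group, variance, n), `fixed_effects`
#'   (term, level, estimate, se), `random_effects` (term, level, blup),
#'   `residuals` (per-record fitted value, raw and studentized residual,
#'   leverage, residual group), the restricted log-likelihood `logLik`,
#'   and a `convergence` list (iterations, converged, score norm).
#'
#' @examples
#' sim <- simulate_historical(n_accessions = 40, years = 2001:2006,
#'                            years_observed = 6, seed = 1)
#' fit <- fit_mixed(sim$data$records, "value",
#'                  fixed = "accession_id", random = "year",
#'                  residual_by = "year")
#' tidy(fit)
#' @export
fit_mixed <- function(data, response, fixed = NULL, random = "year",
                      residual_by = NULL, max_iter = 200L, tol = 1e-8,
                      em_iter = 10L, min_group_size = 2L, verbose = FALSE) {
  stopifnot(is.data.frame(data))
  if (!response %in% names(data)) {
    abort(paste0("response column '", response, "' not found"))
  }
  y <- as.numeric(data[[response]])
  n <- length(y)
  if (n < 3L) abort("need at least 3 observations")
  if (any(!is.finite(y))) abort("response contains non-finite values")
  for (v in unique(c(fixed, unlist(strsplit(random %||% character(), ":"))))) {
    if (!v %in% names(data)) abort(paste0("factor column '", v, "' not found"))
  }

  ## ---- design construction: everything is an indicator, value 1 ----------
  ## each record's design row is a set of column indices; index 0 = no column
  idx_list <- list()       # per design block: integer vector length n
  col_names <- character() # column labels, in order
  col_term <- character()  # owning term per column
  p <- 0L

  if (is.null(fixed)) {
    idx_list[["(Intercept)"]] <- rep(1L, n)
    col_names <- "(Intercept)"
    col_term <- "(Intercept)"
    p <- 1L
    fixed_terms <- "(Intercept)"
  } else {
    fixed_terms <- fixed
    f1 <- factor(data[[fixed[1L]]])
    idx_list[[fixed[1L]]] <- as.integer(f1)
    col_names <- paste0(fixed[1L], ":", levels(f1))
    col_term <- rep(fixed[1L], nlevels(f1))
    p <- nlevels(f1)
    for (fx in fixed[-1L]) {
      f <- factor(data[[fx]])
      if (nlevels(f) < 2L) abort(paste0("fixed factor '", fx, "' has a single level"))
      ix <- as.integer(f) - 1L          # reference level -> 0 (no column)
      ix[ix > 0L] <- ix[ix > 0L] + p
      idx_list[[fx]] <- ix
      col_names <- c(col_names, paste0(fx, ":", levels(f)[-1L]))
      col_term <- c(col_term, rep(fx, nlevels(f) - 1L))
      p <- p + nlevels(f) - 1L
    }
  }

  rand_levels <- list()
  q <- integer(0)
  off <- p
  for (rt in random %||% character()) {
    parts <- strsplit(rt, ":", fixed = TRUE)[[1L]]
    f <- if (length(parts) == 1L) factor(data[[parts]]) else
      factor(interaction(data[parts], drop = TRUE, sep = ":"))
    idx_list[[paste0("r_", rt)]] <- as.integer(f) + off
    col_names <- c(col_names, paste0(rt, ":", levels(f)))
    col_term <- c(col_term, rep(rt, nlevels(f)))
    rand_levels[[rt]] <- levels(f)
    q <- c(q, nlevels(f))
    off <- off + nlevels(f)
  }
  names(q) <- names(rand_levels)
  m <- p + sum(q)
  if (length(q) == 0L && is.null(residual_by)) {
    abort("model has neither random terms nor heterogeneous residuals; use lm()")
  }

  ## residual grouping (small groups pooled)
  if (is.null(residual_by)) {
    grp <- factor(rep("all", n))
  } else {
    grp <- factor(data[[residual_by]])
    cnt <- table(grp)
    small <- names(cnt)[cnt < min_group_size]
    if (length(small)) {
      lv <- levels(grp)
      lv2 <- ifelse(lv %in% small, ".pooled", lv)
      grp <- factor(lv2[as.integer(grp)])
    }
  }
  g <- as.integer(grp)
  J <- nlevels(grp)
  n_j <- tabulate(g, J)

  ## sparse W (n x m), all entries 1
  IDX <- do.call(cbind, idx_list)     # n x k matrix of column indices (0 = none)
  keep <- IDX > 0L
  W <- sparseMatrix(i = row(IDX)[keep], j = IDX[keep], x = 1,
                    dims = c(n, m))
  Wt <- t(W)

  ## connectivity report: with a fixed grouping factor, comparisons across
  ## disconnected components of the (fixed factor x first random factor)
  ## incidence graph lean entirely on the random-effect distribution; report
  ## rather than silently estimate
  n_disconnected <- 1L
  if (!is.null(fixed) && length(q)) {
    f1i <- idx_list[[fixed[1L]]]
    r1i <- idx_list[[paste0("r_", names(q)[1L])]] - p
    n_disconnected <- n_connected_components(f1i, r1i)
    if (n_disconnected > 1L) {
      warn(paste0("the ", fixed[1L], " x ", names(q)[1L], " design is ",
                  "disconnected (", n_disconnected, " components); ",
                  "fixed-effect contrasts across components are informed ",
                  "only through the random-effect distribution"))
    }
  }

  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  ## boundary floors: residual-group variances get a much higher floor than
  ## random-term variances — tiny group variances make the mixed-model
  ## equations ill-conditioned enough that likelihood evaluations turn noisy
  floor_r <- 1e-8 * vy
  floor_e <- 1e-4 * vy
  ## ceiling: a variance component orders of magnitude above var(y) only
  ## arises on saturated degenerate designs where the restricted likelihood
  ## is unbounded; estimates are capped there instead of diverging
  cap_v <- 1e3 * vy

  K <- length(q)
  theta_r <- rep(vy / (2 * max(K, 1)), K)       # random-term variances
  theta_e <- rep(vy / 2, J)                      # residual group variances
  rand_block <- rep(seq_len(K), times = q)       # per random column: which term

  pad <- m + 1L                                  # padded zero row/col of Ci
  IDXp <- IDX
  IDXp[IDXp == 0L] <- pad
  kcols <- ncol(IDXp)

  eval_state <- function(theta_r, theta_e) {
    rinv <- 1 / theta_e[g]
    WtRi <- Wt %*% Diagonal(n, rinv)
    C <- WtRi %*% W
    dvec <- c(rep(0, p), if (K) 1 / theta_r[rand_block] else numeric(0))
    C <- C + Diagonal(m, dvec)
    Cd <- as.matrix(C)
    ch <- tryCatch(chol(Cd), error = function(e) NULL)
    if (is.null(ch)) {
      ch <- tryCatch(chol(Cd + diag(1e-8 * max(diag(Cd)), m)),
                     error = function(e) NULL)
      if (is.null(ch)) {
        abort(paste0("singular mixed-model equations: the fixed-effect design ",
                     "is rank-deficient (aliased levels) or a variance collapsed"))
      }
    }
    Ci <- chol2inv(ch)
    b <- as.numeric(WtRi %*% y)
    s <- as.numeric(Ci %*% b)
    ehat <- y - as.numeric(W %*% s)
    ## per-record leverage w_i' Ci w_i via padded index lookups
    Cip <- rbind(cbind(Ci, 0), 0)
    lev <- numeric(n)
    for (a in seq_len(kcols)) for (bb in seq_len(kcols)) {
      lev <- lev + Cip[cbind(IDXp[, a], IDXp[, bb])]
    }
    ypy <- sum(y * rinv * y) - sum(s * b)
    ldC <- 2 * sum(log(diag(ch)))
    ldR <- sum(n_j * log(theta_e))
    ldG <- if (K) sum(q * log(theta_r)) else 0
    ll <- -0.5 * (ldR + ldG + ldC + ypy + (n - p) * log(2 * pi))
    list(Ci = Ci, s = s, ehat = ehat, lev = lev, rinv = rinv, ll = ll)
  }

  em_step <- function(st, theta_r, theta_e) {
    new_r <- theta_r
    if (K) {
      for (k in seq_len(K)) {
        cols <- p + which(rand_block == k)
        uk <- st$s[cols]
        trk <- sum(diag(st$Ci)[cols])
        new_r[k] <- min(max((sum(uk^2) + trk) / q[k], floor_r), cap_v)
      }
    }
    new_e <- theta_e
    se2 <- rowsum(st$ehat^2 + st$lev, g)[, 1L]
    new_e <- pmin(pmax(as.numeric(se2) / n_j, floor_e), cap_v)
    list(theta_r = new_r, theta_e = new_e)
  }

  score_fun <- function(st, theta_r, theta_e) {
    Py <- st$rinv * st$ehat
    sc <- numeric(K + J)
    if (K) {
      for (k in seq_len(K)) {
        cols <- p + which(rand_block == k)
        trCikk <- sum(diag(st$Ci)[cols])
        trPV <- (q[k] - trCikk / theta_r[k]) / theta_r[k]
        ZtPy <- st$s[cols] / theta_r[k]   # u_hat = sigma2 * Z'Py => Z'Py = u/sigma2
        sc[k] <- -0.5 * (trPV - sum(ZtPy^2))
      }
    }
    slev <- rowsum(st$lev, g)[, 1L]
    sPy2 <- rowsum(Py^2, g)[, 1L]
    for (j in seq_len(J)) {
      trPE <- (n_j[j] - slev[j] / theta_e[j]) / theta_e[j]
      sc[K + j] <- -0.5 * (trPE - sPy2[j])
    }
    sc
  }

  ai_matrix <- function(st, theta_r, theta_e) {
    Py <- st$rinv * st$ehat
    nt <- K + J
    Fm <- matrix(0, n, nt)
    if (K) {
      for (k in seq_len(K)) {
        cols <- p + which(rand_block == k)
        ZtPy <- st$s[cols] / theta_r[k]
        ix <- idx_list[[paste0("r_", names(q)[k])]] - (p + c(0, cumsum(q))[k])
        Fm[, k] <- ZtPy[ix]
      }
    }
    for (j in seq_len(J)) Fm[g == j, K + j] <- Py[g == j]
    ## P F = Rinv (F - W Ci W' Rinv F)
    RiF <- Fm * st$rinv
    WtRiF <- as.matrix(Wt %*% RiF)
    PF <- RiF - (as.matrix(W %*% (st$Ci %*% WtRiF)) * st$rinv)
    0.5 * crossprod(Fm, PF)
  }

  st <- eval_state(theta_r, theta_e)
  ll_old <- st$ll
  converged <- FALSE
  it <- 0L
  score_norm <- NA_real_
  used_em <- 0L
  trajectory <- numeric(0)
  while (it < max_iter) {
    it <- it + 1L
    if (it <= em_iter) {
      up <- em_step(st, theta_r, theta_e)
      theta_r <- up$theta_r; theta_e <- up$theta_e
      st <- eval_state(theta_r, theta_e)
      used_em <- used_em + 1L
    } else {
      sc <- score_fun(st, theta_r, theta_e)
      AI <- ai_matrix(st, theta_r, theta_e)
      theta <- c(theta_r, theta_e)
      flo <- c(rep(floor_r, K), rep(floor_e, J))
      ## pin components that are near their floor and still pushed downward:
      ## EM only approaches the boundary geometrically, stalling convergence
      at_floor <- theta <= pmax(1e-5 * vy, flo * 1.001) & sc < 0
      free <- !at_floor
      delta <- rep(0, length(theta))
      ok <- FALSE
      if (any(free)) {
        delta[free] <- tryCatch(
          solve(AI[free, free, drop = FALSE] +
                  diag(1e-10, sum(free)), sc[free]),
          error = function(e) rep(NA_real_, sum(free)))
        if (all(is.finite(delta))) ok <- TRUE
      }
      improved <- FALSE
      if (ok) {
        step <- 1
        for (h in 1:20) {
          cand <- pmin(pmax(theta + step * delta, flo), cap_v)
          cand[at_floor] <- flo[at_floor]
          st2 <- tryCatch(eval_state(cand[seq_len(K)], cand[K + seq_len(J)]),
                          error = function(e) NULL)
          if (!is.null(st2) && is.finite(st2$ll) && st2$ll >= st$ll - 1e-12) {
            theta_r <- cand[seq_len(K)]; theta_e <- cand[K + seq_len(J)]
            st <- st2
            improved <- TRUE
            break
          }
          step <- step / 2
        }
      }
      if (!improved) {      # AI failed: fall back to one EM step
        up <- em_step(st, theta_r, theta_e)
        st2 <- eval_state(up$theta_r, up$theta_e)
        if (st2$ll < st$ll - 1e-9 * (abs(st$ll) + 1)) {
          ## numerically unable to improve any further: stop here
          converged <- TRUE
          score_norm <- sqrt(sum(sc^2))
          break
        }
        theta_r <- up$theta_r; theta_e <- up$theta_e
        st <- st2
      }
      score_norm <- sqrt(sum(score_fun(st, theta_r, theta_e)^2))
    }
    trajectory <- c(trajectory, st$ll)
    if (verbose) {
      cat(sprintf("iter %3d  logREML %.8f\n", it, st$ll))
    }
    if (it > em_iter && abs(st$ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- st$ll
  }
  if (!converged && it >= max_iter) {
    cnd <- rlang::error_cnd(
      "histphen_no_convergence",
      trajectory = trajectory,
      message = paste0("REML did not converge in ", max_iter, " iterations ",
                       "(last restricted logLik ", signif(st$ll, 10), ")"))
    rlang::cnd_signal(cnd)
  }

  ## ---- assemble result ----------------------------------------------------
  at_bound <- c(theta_r, theta_e) <=
    c(rep(floor_r, K), rep(floor_e, J)) * (1 + 1e-9)
  vc <- tibble(
    term = names(q) %||% character(0),
    variance = ifelse(at_bound[seq_len(K)], 0, theta_r),
    boundary = at_bound[seq_len(K)]
  )
  rv <- tibble(
    group = levels(grp),
    variance = theta_e,
    n = as.integer(n_j)
  )

  fe_cols <- seq_len(p)
  fe <- tibble(
    term = col_term[fe_cols],
    level = sub("^[^:]*:", "", col_names[fe_cols]),
    estimate = st$s[fe_cols],
    se = sqrt(pmax(diag(st$Ci)[fe_cols], 0))
  )
  if (is.null(fixed)) fe$level <- "(Intercept)"

  re <- if (K) tibble(
    term = col_term[p + seq_len(sum(q))],
    level = sub("^[^:]*:", "", col_names[p + seq_len(sum(q))]),
    blup = st$s[p + seq_len(sum(q))]
  ) else tibble(term = character(), level = character(), blup = numeric())

  sig2_i <- theta_e[g]
  cond_var <- sig2_i - st$lev
  bad <- cond_var <= 1e-10 * sig2_i
  if (any(bad & n_j[g] > 1L)) {
    cond_var[bad] <- pmax(cond_var[bad], 1e-10 * sig2_i[bad])
  }
  cond_var <- pmax(cond_var, 1e-12 * vy)
  resid_tbl <- tibble(
    row = seq_len(n),
    fitted = y - st$ehat,
    residual = st$ehat,
    leverage = st$lev / sig2_i,
    studentized = st$ehat / sqrt(cond_var),
    resid_group = as.character(grp)
  )

  structure(list(
    variance_components = vc,
    residual_variances = rv,
    fixed_effects = fe,
    random_effects = re,
    residuals = resid_tbl,
    logLik = st$ll,
    convergence = list(iterations = it, converged = converged,
                       em_iterations = min(used_em, it),
                       score_norm = score_norm,
                       trajectory = trajectory,
                       n_design_components = n_disconnected),
    n = n,
    response = response,
    fixed = fixed_terms,
    random = names(q),
    residual_by = residual_by
  ), class = "hp_fit")
}

#' @exportS3Method base::print
print.hp_fit <- function(x, ...) {
  cat("<hp_fit> REML linear mixed model\n")
  cat("  n =", x$n, " response:", x$response, "\n")
  cat("  fixed:", paste(x$fixed, collapse = " + "),
      " random:", paste(x$random, collapse = " + "), "\n")
  if (nrow(x$variance_components)) {
    cat("  variance components:\n")
    for (i in seq_len(nrow(x$variance_components))) {
      cat(sprintf("    %-24s %10.4f%s\n", x$variance_components$term[i],
                  x$variance_components$variance[i],
                  if (x$variance_components$boundary[i]) " (boundary)" else ""))
    }
  }
  if (nrow(x$residual_variances) == 1L) {
    cat(sprintf("  residual variance: %.4f\n", x$residual_variances$variance))
  } else {
    cat(sprintf("  residual variances: %d groups, mean %.4f (min %.4f, max %.4f)\n",
                nrow(x$residual_variances), mean(x$residual_variances$variance),
                min(x$residual_variances$variance), max(x$residual_variances$variance)))
  }
  cat(sprintf("  restricted logLik: %.4f (%d iterations%s)\n", x$logLik,
              x$convergence$iterations,
              if (x$convergence$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Mean residual variance of a fit
#'
#' Record-weighted average of the (possibly year-specific) residual
#' variances, the \eqn{\bar\sigma^2_e} entering the entry-mean heritability.
#'
#' @param fit An `hp_fit`.
#' @return A single number.
#' @export
mean_residual_variance <- function(fit) {
  stopifnot(inherits(fit, "hp_fit"))
  with(fit$residual_variances, sum(variance * n) / sum(n))
}

#' Studentized residuals of a mixed-model fit
#'
#' Each conditional residual is scaled by its estimated standard deviation
#' under the fitted model, \eqn{\sqrt{\sigma^2_{e^*j} - w_i' C^{-1} w_i}},
#' i.e. the residual-group variance minus the leverage of the record in the
#' mixed-model equations, so that under the model the values are
#' approximately standard normal.
#'
#' @param fit An `hp_fit`.
#' @return A tibble with `row`, `studentized`, `resid_group`.
#' @export
studentized_residuals <- function(fit) {
  stopifnot(inherits(fit, "hp_fit"))
  zero_grp <- fit$residual_variances$variance <= 0 &
    fit$residual_variances$n > 1L
  if (any(zero_grp)) {
    abort(paste0("residual variance estimated as zero in group(s) ",
                 paste(fit$residual_variances$group[zero_grp], collapse = ", "),
                 " with more than one record; studentization is degenerate"))
  }
  fit$residuals[, c("row", "studentized", "resid_group")]
}

#' Entry-mean heritability
#'
#' \deqn{h^2 = \sigma^2_G / (\sigma^2_G + \bar\sigma^2_e / \bar{n}_{yr})}
#' where \eqn{\bar\sigma^2_e} is the average residual variance and
#' \eqn{\bar{n}_{yr}} the average number of years each accession was tested.
#'
#' @param sigma2_G Genetic (accession) variance, >= 0.
#' @param sigma2_e_mean Average residual variance, >= 0.
#' @param mean_years Average number of observation years per accession, > 0.
#' @return Heritability in [0, 1].
#' @examples
#' heritability(15.62, 6.48, 5.09)  # ~0.92
#' @export
heritability <- function(sigma2_G, sigma2_e_mean, mean_years) {
  if (any(sigma2_G < 0) || any(sigma2_e_mean < 0)) {
    abort("variance components must be non-negative")
  }
  if (any(mean_years <= 0)) abort("mean_years must be positive")
  denom <- sigma2_G + sigma2_e_mean / mean_years
  ifelse(denom == 0, 0, sigma2_G / denom)
}

#' Estimate accession BLUEs from historical records
#'
#' Fits the historical-data model with fixed accession effects and a random
#' year effect (residual variances year-specific when
#' `heterogeneous = TRUE`) and returns one best linear unbiased estimate per
#' accession on the trait scale, with its standard error and the number of
#' observation years.
#'
#' @param records Data frame of phenotype records with columns
#'   `accession_id`, `year`, `trait`, `value`.
#' @param trait Trait to analyse (records are filtered to it). `NULL` uses
#'   all records as a single trait.
#' @param heterogeneous Year-specific residual variances?
#' @param ... Passed on to [fit_mixed()].
#' @return A list with `blues` (tibble: accession_id, trait, blue, se,
#'   n_years) and `fit` (the underlying `hp_fit`).
#' @export
estimate_blues <- function(records, trait = NULL, heterogeneous = TRUE, ...) {
  records <- as_tibble(records)
  if (!is.null(trait)) {
    records <- dplyr::filter(records, .data$trait == !!trait)
    if (!nrow(records)) abort(paste0("no records for trait '", trait, "'"))
  }
  fit <- fit_mixed(records, "value", fixed = "accession_id", random = "year",
                   residual_by = if (heterogeneous) "year" else NULL, ...)
  nyr <- records |>
    dplyr::distinct(.data$accession_id, .data$year) |>
    dplyr::count(.data$accession_id, name = "n_years") |>
    dplyr::mutate(accession_id = as.character(.data$accession_id))
  blues <- fit$fixed_effects |>
    dplyr::transmute(accession_id = .data$level,
                     trait = trait %||% NA_character_,
                     blue = .data$estimate, se = .data$se) |>
    dplyr::left_join(nyr, by = "accession_id")
  list(blues = blues, fit = fit)
}

#' Estimate phenotypic variance components from historical records
#'
#' Fits the historical-data model with both accession and year random
#' (intercept-only fixed part), the parameterisation used for second-degree
#' statistics: genetic variance, year variance, and (possibly year-specific)
#' residual variances.
#'
#' @inheritParams estimate_blues
#' @return A list: `components` (tibble with sigma2_G, sigma2_Y,
#'   sigma2_e_mean, mean_years, h2) and `fit`.
#' @export
estimate_components <- function(records, trait = NULL, heterogeneous = TRUE, ...) {
  records <- as_tibble(records)
  if (!is.null(trait)) {
    records <- dplyr::filter(records, .data$trait == !!trait)
    if (!nrow(records)) abort(paste0("no records for trait '", trait, "'"))
  }
  fit <- fit_mixed(records, "value", fixed = NULL,
                   random = c("accession_id", "year"),
                   residual_by = if (heterogeneous) "year" else NULL, ...)
  s2G <- fit$variance_components$variance[
    fit$variance_components$term == "accession_id"]
  s2Y <- fit$variance_components$variance[
    fit$variance_components$term == "year"]
  s2e <- mean_residual_variance(fit)
  myr <- records |>
    dplyr::distinct(.data$accession_id, .data$year) |>
    dplyr::count(.data$accession_id) |>
    dplyr::pull(.data$n) |>
    mean()
  comps <- tibble(
    sigma2_G = s2G, sigma2_Y = s2Y, sigma2_e_mean = s2e,
    mean_years = myr, h2 = heritability(s2G, s2e, myr)
  )
  list(components = comps, fit = fit)
}
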