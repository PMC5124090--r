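#' @export
print.ipm_fit <- function(x, ...) {
  cfg <- x$config
  cat("<ipm_fit> region '", x$region, "': ", length(x$years), " years, ",
      nrow(x$draws), " retained draws (", cfg$n_chains, " chains x ",
      (cfg$n_iter - cfg$n_burnin) %/% cfg$thin, ")\n", sep = "")
  mx <- suppressWarnings(max(x$rhat$rhat, na.rm = TRUE))
  cat(sprintf("  max split-Rhat %.3f (%s) | runtime %.1f s\n", mx,
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              x$runtime))
  invisible(x)
}

#' @export
print.ipm_draws <- function(x, ...) {
  cat("<ipm_draws> region '", x$region, "': ", nrow(x$draws), " draws, ",
      length(x$years), " years\n", sep = "")
  invisible(x)
}

param_year_label <- function(x, name, j) {
  # transitions are labelled by the later year; N by its own year
  if (name == "N") x$years[j] else x$years[j + 1L]
}

#' Tidy posterior summaries of an IPM fit
#'
#' One row per scalar parameter (yearly parameters get one row per year
#' index) with posterior mean, s.d., median and the 95% credible interval,
#' plus the split Gelman-Rubin statistic when available.
#'
#' @param x An `ipm_fit` or `ipm_draws`.
#' @param ... Unused.
#' @return A tibble `term, year_index, year, mean, sd, q2.5, median, q97.5,
#'   rhat`.
#' @export
tidy.ipm_draws <- function(x, ...) {
  pars <- setdiff(names(x$draws), c(".chain", ".iteration", ".draw"))
  base <- sub("\\[\\d+\\]$", "", pars)
  idx <- suppressWarnings(as.integer(sub(".*\\[(\\d+)\\]$", "\\1", pars)))
  idx[!grepl("\\[", pars)] <- NA_integer_
  rh <- if (inherits(x, "ipm_fit") && !is.null(x$rhat)) {
    setNames(x$rhat$rhat, x$rhat$parameter)
  } else NULL
  rows <- purrr::map(seq_along(pars), function(i) {
    v <- x$draws[[pars[i]]]
    tibble(
      term = base[i], year_index = idx[i],
      year = if (is.na(idx[i])) NA_integer_
             else param_year_label(x, base[i], idx[i]),
      mean = mean(v), sd = sd(v),
      `q2.5` = quantile(v, 0.025, names = FALSE),
      median = median(v),
      `q97.5` = quantile(v, 0.975, names = FALSE),
      rhat = if (is.null(rh)) NA_real_ else unname(rh[pars[i]])
    )
  })
  list_rbind(rows)
}

#' @export
tidy.ipm_fit <- tidy.ipm_draws

#' One-row fit summary
#'
#' @param x An `ipm_fit`.
#' @param ... Unused.
#' @return A tibble with region, draw counts, convergence summary and the
#'   number of imputed (unsurveyed) years.
#' @export
glance.ipm_fit <- function(x, ...) {
  tibble(
    region = x$region,
    n_years = length(x$years),
    n_chains = x$config$n_chains,
    n_draws = nrow(x$draws),
    max_rhat = suppressWarnings(max(x$rhat$rhat, na.rm = TRUE)),
    converged = x$converged,
    n_missing_years = sum(is.na(x$data$counts)),
    runtime_s = x$runtime
  )
}

#' Posterior population index
#'
#' The latent population scaled by its first-year value (`N_t / N_1`), the
#' conventional presentation of a relative abundance series.
#'
#' @param x An `ipm_fit` or `ipm_draws` containing `N` draws.
#' @return A tibble `year, mean, q2.5, median, q97.5`.
#' @export
posterior_index <- function(x) {
  nmat <- param_matrix(x, "N")
  idx <- nmat / nmat[, 1]
  tibble(
    year = x$years,
    mean = colMeans(idx),
    `q2.5` = apply(idx, 2, quantile, 0.025),
    median = apply(idx, 2, median),
    `q97.5` = apply(idx, 2, quantile, 0.975)
  )
}
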