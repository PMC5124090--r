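#' Demographic-rates report table
#'
#' Mirrors the conventional IPM results table: one row per region and
#' demographic rate (adult survival, brood size, egg- and chick-stage
#' period survival, productivity, recruitment scaling) with the mean and
#' spread of its annual variation and the posterior correlation of the
#' rate with annual population growth. The "annual variation" columns
#' summarise the yearly posterior means (their average and 0.025/0.975
#' quantiles across years).
#'
#' @param fits Named list of `ipm_fit`/`ipm_draws` objects, one per region.
#' @param path Optional CSV path to write the table to.
#' @return A tibble `region, rate, mean, cri_low, cri_high, r_mean,
#'   r_cri_low, r_cri_high, p_positive`.
#' @export
write_rates_report <- function(fits, path = NULL) {
  if (is.null(names(fits))) {
    names(fits) <- vapply(fits, function(f) f$region, "")
  }
  rates <- c("phi_ad", "brood", "phi_egg_period", "phi_chick_period",
             "fpba", "rho")
  out <- list_rbind(purrr::imap(fits, function(fit, region) {
    list_rbind(purrr::map(rates, function(rn) {
      m <- colMeans(rate_matrix(fit, rn))
      cr <- growth_rate_correlation(fit, rn)
      tibble(
        region = region, rate = rn,
        mean = mean(m),
        cri_low = quantile(m, 0.025, names = FALSE),
        cri_high = quantile(m, 0.975, names = FALSE),
        r_mean = cr$mean_r,
        r_cri_low = cr$cri_low,
        r_cri_high = cr$cri_high,
        p_positive = cr$p_positive
      )
    }))
  }))
  if (!is.null(path)) readr::write_csv(out, path)
  out
}

#' Serialize posterior draws to plain files
#'
#' Writes one columnar CSV of retained draws (with chain/iteration
#' metadata) and one JSON sidecar of fit metadata, so downstream analyses
#' can run without refitting.
#'
#' @param x An `ipm_fit` or `ipm_draws`.
#' @param prefix Path prefix; `<prefix>_draws.csv` and `<prefix>_meta.json`
#'   are created.
#' @return `prefix`, invisibly.
#' @export
write_ipm_draws <- function(x, prefix) {
  stopifnot(inherits(x, "ipm_draws"))
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(x$draws, paste0(prefix, "_draws.csv"))
  meta <- list(region = x$region, years = x$years, ep = x$ep, yp = x$yp)
  if (inherits(x, "ipm_fit")) {
    meta$converged <- x$converged
    meta$max_rhat <- suppressWarnings(max(x$rhat$rhat, na.rm = TRUE))
    meta$seed <- x$config$seed
  }
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_ipm_draws
#' @export
read_ipm_draws <- function(prefix) {
  draws <- readr::read_csv(paste0(prefix, "_draws.csv"),
                           col_types = readr::cols(.default = readr::col_double()))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  ipm_draws(draws, years = meta$years, region = meta$region,
            ep = meta$ep, yp = meta$yp)
}
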