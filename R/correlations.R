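rate_choices <- c("phi_ad", "brood", "phi_egg_period", "phi_chick_period",
                  "fpba", "rho", "lambda")

rate_matrix <- function(x, rate_name) {
  switch(
    rate_name,
    phi_egg_period = param_matrix(x, "phi_egg")^x$ep,
    phi_chick_period = param_matrix(x, "phi_chick")^x$yp,
    param_matrix(x, rate_name)
  )
}

#' Transition-aligned posterior table
#'
#' Applies the package's single alignment convention: the growth rate
#' `lambda[j] = N[j+1] / N[j]` is paired with the demographic rates
#' governing the same transition -- adult survival over interval
#' `j -> j+1` and the productivity of breeding season `j`. Transitions are
#' labelled by the later year, so a 19-year study yields 18 aligned rows
#' per draw.
#'
#' @param x An `ipm_draws` or `ipm_fit`.
#' @return A long tibble with one row per draw and transition: `.draw`,
#'   `transition`, `year`, `lambda` and every available demographic rate
#'   (egg/chick survival on the period scale).
#' @export
align_transitions <- function(x) {
  stopifnot(inherits(x, "ipm_draws"))
  lam <- param_matrix(x, "lambda")
  k <- ncol(lam)
  out <- tibble(
    .draw = rep(x$draws$.draw, k),
    transition = rep(seq_len(k), each = nrow(lam)),
    year = rep(x$years[seq_len(k) + 1L], each = nrow(lam)),
    lambda = as.vector(lam)
  )
  for (rn in c("phi_ad", "brood", "phi_egg_period", "phi_chick_period",
               "fpba", "rho")) {
    m <- tryCatch(rate_matrix(x, rn), error = function(e) NULL)
    if (!is.null(m) && ncol(m) == k) out[[rn]] <- as.vector(m)
  }
  arrange(out, .data$.draw, .data$transition)
}

rowwise_cor <- function(a, b, method = "pearson") {
  if (method == "spearman") {
    a <- t(apply(a, 1, rank))
    b <- t(apply(b, 1, rank))
  }
  ac <- a - rowMeans(a)
  bc <- b - rowMeans(b)
  num <- rowSums(ac * bc)
  den <- sqrt(rowSums(ac^2) * rowSums(bc^2))
  ifelse(den > 0, num / den, NA_real_)
}

summarise_r <- function(r, rate_name, n_years) {
  degenerate <- sum(!is.finite(r))
  r <- r[is.finite(r)]
  if (!length(r)) abort("All draws have a degenerate (constant) rate.")
  tibble(
    rate = rate_name,
    mean_r = mean(r),
    cri_low = quantile(r, 0.025, names = FALSE),
    cri_high = quantile(r, 0.975, names = FALSE),
    p_positive = mean(r > 0),
    n_draws = length(r),
    n_years = n_years,
    n_degenerate = degenerate
  )
}

#' Posterior correlation between growth rate and a demographic rate
#'
#' For every retained MCMC draw, the Pearson correlation between the annual
#' growth rates `lambda` and the named demographic rate is computed across
#' the aligned transitions, yielding a posterior distribution of
#' correlation coefficients. Reported are its mean, 95% credible interval
#' (0.025 and 0.975 quantiles) and the probability of a positive
#' correlation. Draws in which the rate is constant (undefined correlation)
#' are dropped and counted in `n_degenerate`.
#'
#' @param x An `ipm_draws`/`ipm_fit`.
#' @param rate_name One of `"phi_ad"`, `"brood"`, `"phi_egg_period"`,
#'   `"phi_chick_period"`, `"fpba"`, `"rho"`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A one-row tibble: `rate, mean_r, cri_low, cri_high, p_positive,
#'   n_draws, n_years, n_degenerate`.
#' @export
growth_rate_correlation <- function(x, rate_name,
                                    method = c("pearson", "spearman")) {
  stopifnot(inherits(x, "ipm_draws"))
  method <- match.arg(method)
  rate_name <- match.arg(rate_name, setdiff(rate_choices, "lambda"))
  lam <- param_matrix(x, "lambda")
  rt <- rate_matrix(x, rate_name)
  if (ncol(rt) != ncol(lam)) {
    abort("Rate and lambda must cover the same transitions.")
  }
  r <- rowwise_cor(lam, rt, method)
  summarise_r(r, rate_name, ncol(lam))
}

#' Cross-region posterior correlation of a demographic rate
#'
#' Pairs draws from two independently fitted regions by retained-draw index
#' and computes, per paired draw, the Pearson correlation of the yearly
#' rate between the regions. If draw counts differ, the longer set is
#' thinned to evenly spaced indices.
#'
#' @param x_a,x_b `ipm_draws`/`ipm_fit` objects spanning the same years.
#' @param rate_name Rate to correlate (see [growth_rate_correlation()]);
#'   `"lambda"` is also allowed here.
#' @param method `"pearson"` or `"spearman"`.
#' @return A one-row tibble as for [growth_rate_correlation()].
#' @export
cross_region_correlation <- function(x_a, x_b, rate_name,
                                     method = c("pearson", "spearman")) {
  stopifnot(inherits(x_a, "ipm_draws"), inherits(x_b, "ipm_draws"))
  method <- match.arg(method)
  rate_name <- match.arg(rate_name, rate_choices)
  if (length(x_a$years) != length(x_b$years) ||
      !all(x_a$years == x_b$years)) {
    abort("The two regions must span identical year ranges.")
  }
  ra <- rate_matrix(x_a, rate_name)
  rb <- rate_matrix(x_b, rate_name)
  na <- nrow(ra)
  nb <- nrow(rb)
  n <- min(na, nb)
  ra <- ra[round(seq(1, na, length.out = n)), , drop = FALSE]
  rb <- rb[round(seq(1, nb, length.out = n)), , drop = FALSE]
  r <- rowwise_cor(ra, rb, method)
  summarise_r(r, rate_name, ncol(ra))
}
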