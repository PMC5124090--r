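#' Simulated growth-rate surface over demographic space
#'
#' Expected annual population growth across the observed range of adult
#' survival and productivity, holding the recruitment scaling factor at its
#' grand posterior mean over both regions and years. In `"expected"` mode
#' each cell is the closed form `lambda = phi + 0.5 * F * rho_bar`; in
#' `"stochastic"` mode it is the Monte-Carlo mean of one-step
#' [step_population()] ratios from a reference population. The grid spans
#' the union of the two regions' posterior-mean yearly (phi, FPBA) ranges,
#' and those yearly points are returned for overplotting.
#'
#' @param x_a,x_b Fitted `ipm_draws` for the two regions.
#' @param grid_resolution Cells per axis (default 50).
#' @param mode `"expected"` (closed form) or `"stochastic"` (simulation).
#' @param n_reps Replicates per cell in stochastic mode.
#' @param n_ref Reference population size for stochastic replicates.
#' @param seed Optional seed for stochastic mode.
#' @return An `ipm_growth_surface`: a tibble `phi_ad, fpba, lambda` with
#'   attributes `rho_fixed` (the grand mean), `points` (per-region yearly
#'   posterior means) and `mode`.
#' @export
growth_surface <- function(x_a, x_b, grid_resolution = 50L,
                           mode = c("expected", "stochastic"),
                           n_reps = 10000L, n_ref = 1000L, seed = NULL) {
  mode <- match.arg(mode)
  grid_resolution <- check_count(grid_resolution, "grid_resolution", min = 2L)
  pts <- list_rbind(purrr::imap(list(a = x_a, b = x_b), function(x, nm) {
    tibble(region = if (is.null(x$region)) nm else x$region,
           year = x$years[seq_len(length(x$years) - 1L) + 1L],
           phi_ad = colMeans(param_matrix(x, "phi_ad")),
           fpba = colMeans(param_matrix(x, "fpba")))
  }))
  rho_bar <- mean(c(colMeans(param_matrix(x_a, "rho")),
                    colMeans(param_matrix(x_b, "rho"))))
  phi_grid <- seq(min(pts$phi_ad), max(pts$phi_ad),
                  length.out = grid_resolution)
  fpba_grid <- seq(min(pts$fpba), max(pts$fpba),
                   length.out = grid_resolution)
  grid <- tidyr::expand_grid(phi_ad = phi_grid, fpba = fpba_grid)
  if (mode == "expected") {
    grid$lambda <- grid$phi_ad + 0.5 * grid$fpba * rho_bar
  } else {
    grid$lambda <- with_seed(seed, map_dbl(seq_len(nrow(grid)), function(i) {
      stp <- step_population(rep(n_ref, n_reps), grid$phi_ad[i],
                             grid$fpba[i], rho_bar)
      mean((stp$n_a + stp$n_r) / n_ref)
    }))
  }
  structure(grid, class = c("ipm_growth_surface", class(grid)),
            rho_fixed = rho_bar, points = pts, mode = mode)
}

#' Counterfactual trajectory with a substituted demographic rate
#'
#' Re-projects a fitted region's population from a chosen year onward with
#' one demographic rate (annual survival or productivity) taken from a
#' donor region's paired posterior draw, all other rates (including the
#' yearly recruitment scaling) kept from the target draw, and no density
#' dependence. By default each draw restarts from its own fitted latent
#' population at `from_year` and the projection is stochastic (binomial
#' survivors, Poisson recruits), so parameter and demographic uncertainty
#' are both carried; `mode = "expected"` propagates the deterministic
#' expectation instead. Indices are scaled by the target's year-1
#' population.
#'
#' @param target,donor Fitted `ipm_draws` over identical years.
#' @param rate `"survival"` or `"productivity"` (FPBA).
#' @param from_year Calendar year of the first substituted transition.
#' @param n_start_rule `"draw"` (each draw's own latent N at `from_year`,
#'   default) or `"posterior_mean"`.
#' @param mode `"stochastic"` or `"expected"`.
#' @param seed Optional seed for the stochastic projection.
#' @return An `ipm_substitution`: a tibble of per-year baseline and
#'   substituted index summaries (medians and 95% intervals) with the
#'   per-draw index matrices in attributes `baseline_draws` and
#'   `substituted_draws`.
#' @export
substitute_trajectory <- function(target, donor,
                                  rate = c("survival", "productivity"),
                                  from_year,
                                  n_start_rule = c("draw", "posterior_mean"),
                                  mode = c("stochastic", "expected"),
                                  seed = NULL) {
  rate <- match.arg(rate)
  n_start_rule <- match.arg(n_start_rule)
  mode <- match.arg(mode)
  stopifnot(inherits(target, "ipm_draws"), inherits(donor, "ipm_draws"))
  if (length(target$years) != length(donor$years) ||
      !all(target$years == donor$years)) {
    abort("Target and donor must span identical years.")
  }
  years <- target$years
  tt <- length(years)
  f <- match(from_year, years)
  if (is.na(f)) abort("`from_year` must be one of the fitted years.")
  if (f >= tt) abort("`from_year` must precede the final study year.")
  nmat_t <- param_matrix(target, "N")
  phi_t <- param_matrix(target, "phi_ad")
  fpba_t <- param_matrix(target, "fpba")
  rho_t <- param_matrix(target, "rho")
  phi_d <- param_matrix(donor, "phi_ad")
  fpba_d <- param_matrix(donor, "fpba")
  nd <- min(nrow(nmat_t), nrow(phi_d))
  pick <- function(m, n) m[round(seq(1, nrow(m), length.out = n)), , drop = FALSE]
  nmat_t <- pick(nmat_t, nd); phi_t <- pick(phi_t, nd)
  fpba_t <- pick(fpba_t, nd); rho_t <- pick(rho_t, nd)
  phi_d <- pick(phi_d, nd); fpba_d <- pick(fpba_d, nd)
  phi_use <- if (rate == "survival") phi_d else phi_t
  fpba_use <- if (rate == "productivity") fpba_d else fpba_t
  n0 <- nmat_t[, 1]
  proj <- matrix(NA_real_, nd, tt)
  proj[, seq_len(f)] <- nmat_t[, seq_len(f), drop = FALSE]
  if (n_start_rule == "posterior_mean") {
    proj[, f] <- round(mean(nmat_t[, f]))
  }
  with_seed(seed, {
    for (t in (f + 1L):tt) {
      j <- t - 1L
      if (mode == "stochastic") {
        stp <- step_population(round(proj[, j]), phi_use[, j], fpba_use[, j],
                               rho_t[, j])
        proj[, t] <- stp$n_a + stp$n_r
      } else {
        proj[, t] <- proj[, j] * (phi_use[, j] + 0.5 * fpba_use[, j] * rho_t[, j])
      }
    }
  })
  base_idx <- nmat_t / n0
  sub_idx <- proj / n0
  qs <- function(m, p) unname(apply(m, 2, quantile, p, names = FALSE))
  out <- tibble(
    year = years,
    baseline_median = qs(base_idx, 0.5),
    baseline_lo = qs(base_idx, 0.025),
    baseline_hi = qs(base_idx, 0.975),
    substituted_median = qs(sub_idx, 0.5),
    substituted_lo = qs(sub_idx, 0.025),
    substituted_hi = qs(sub_idx, 0.975)
  )
  structure(out, class = c("ipm_substitution", class(out)),
            substituted_rate = rate, from_year = from_year,
            baseline_draws = base_idx, substituted_draws = sub_idx,
            target_region = target$region, donor_region = donor$region)
}

#' Did the counterfactual trajectory recover?
#'
#' A substituted trajectory "recovers" when its median index reaches the
#' threshold (default 1, the index value at the start of the study) in any
#' year at or after the substitution year.
#'
#' @param trajectory An [substitute_trajectory()] result.
#' @param threshold Index level defining recovery.
#' @return A one-row tibble `recovered, recovery_year` (`NA` year when the
#'   threshold is never reached).
#' @export
recovery_test <- function(trajectory, threshold = 1) {
  stopifnot(inherits(trajectory, "ipm_substitution"))
  from <- attr(trajectory, "from_year")
  sel <- trajectory$year >= from
  hit <- sel & trajectory$substituted_median >= threshold
  tibble(
    recovered = any(hit),
    recovery_year = if (any(hit)) min(trajectory$year[hit]) else NA_integer_
  )
}
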