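#' Demographic parameters for one region
#'
#' Bundles the per-transition demographic rates that drive both simulation and
#' inference. A study of `T` years has `T - 1` transitions; all yearly vectors
#' are indexed by transition `j` (from year `j` to year `j + 1`).
#'
#' @param phi_ad Annual adult apparent-survival probability, one value per
#'   transition (scalars are recycled).
#' @param brood_size Mean number of young per successful nest (`B`), per
#'   breeding season.
#' @param phi_egg_daily Daily nest survival probability during incubation.
#' @param phi_chick_daily Daily nest survival probability during brooding.
#' @param rho Recruitment scaling factor absorbing unmeasured processes
#'   (juvenile survival, dispersal, multi-brooding, non-breeders), per
#'   transition.
#' @param sigma_obs Log-scale standard deviation of the count observation
#'   error (single value per region).
#' @param p_recapture Per-occasion recapture probability at constant-effort
#'   ringing sites (single value per region).
#' @param ep,yp Number of days a nest contains eggs / nestlings. Defaults of
#'   13 days each are typical for a small open-nesting passerine.
#' @param mu_log_rho,sd_log_rho Hyperparameters of the exchangeable
#'   log-normal distribution of `rho` across years. Defaults are the moments
#'   of `log(rho)` (used by [joint_loglik()] when evaluating the hierarchical
#'   prior).
#'
#' @return An object of class `ipm_params`: a list with the validated fields
#'   plus `n_transitions` and `n_years`.
#' @examples
#' demographic_params(
#'   phi_ad = 0.46, brood_size = 5.78,
#'   phi_egg_daily = 0.71^(1 / 13), phi_chick_daily = 0.76^(1 / 13),
#'   rho = 0.39, sigma_obs = 0.1, p_recapture = 0.25
#' )
#' @export
demographic_params <- function(phi_ad, brood_size, phi_egg_daily,
                               phi_chick_daily, rho, sigma_obs, p_recapture,
                               ep = 13L, yp = 13L,
                               mu_log_rho = NULL, sd_log_rho = NULL) {
  k <- max(length(phi_ad), length(brood_size), length(phi_egg_daily),
           length(phi_chick_daily), length(rho))
  phi_ad <- recycle_to(phi_ad, k, "phi_ad")
  brood_size <- recycle_to(brood_size, k, "brood_size")
  phi_egg_daily <- recycle_to(phi_egg_daily, k, "phi_egg_daily")
  phi_chick_daily <- recycle_to(phi_chick_daily, k, "phi_chick_daily")
  rho <- recycle_to(rho, k, "rho")
  check_probability(phi_ad, "phi_ad")
  check_probability(phi_egg_daily, "phi_egg_daily")
  check_probability(phi_chick_daily, "phi_chick_daily")
  check_probability(p_recapture, "p_recapture")
  check_nonneg(brood_size, "brood_size")
  check_nonneg(rho, "rho")
  check_nonneg(sigma_obs, "sigma_obs")
  ep <- check_count(ep, "ep", min = 1L)
  yp <- check_count(yp, "yp", min = 1L)
  if (length(sigma_obs) != 1L || length(p_recapture) != 1L) {
    abort("`sigma_obs` and `p_recapture` must be single values.")
  }
  lr <- log(pmax(rho, 1e-12))
  if (is.null(mu_log_rho)) mu_log_rho <- mean(lr)
  if (is.null(sd_log_rho)) sd_log_rho <- max(sd(lr), 0.05)
  if (is.na(sd_log_rho)) sd_log_rho <- 0.05
  structure(
    list(
      phi_ad = phi_ad, brood_size = brood_size,
      phi_egg_daily = phi_egg_daily, phi_chick_daily = phi_chick_daily,
      rho = rho, sigma_obs = sigma_obs, p_recapture = p_recapture,
      ep = ep, yp = yp,
      mu_log_rho = mu_log_rho, sd_log_rho = sd_log_rho,
      n_transitions = k, n_years = k + 1L
    ),
    class = "ipm_params"
  )
}

#' @export
print.ipm_params <- function(x, ...) {
  cat("<ipm_params> ", x$n_years, " years (", x$n_transitions,
      " transitions)\n", sep = "")
  cat(sprintf("  phi_ad mean %.3f | brood %.2f | phi_egg_daily %.3f | phi_chick_daily %.3f | rho mean %.3f\n",
              mean(x$phi_ad), mean(x$brood_size), mean(x$phi_egg_daily),
              mean(x$phi_chick_daily), mean(x$rho)))
  cat(sprintf("  sigma_obs %.3f | p_recapture %.3f | ep %d | yp %d\n",
              x$sigma_obs, x$p_recapture, x$ep, x$yp))
  invisible(x)
}

#' @describeIn demographic_params One row per transition with every yearly
#'   rate plus the implied fledglings per breeding attempt.
#' @param x An `ipm_params` object.
#' @param ... Unused.
#' @export
tidy.ipm_params <- function(x, ...) {
  tibble(
    transition = seq_len(x$n_transitions),
    phi_ad = x$phi_ad,
    brood_size = x$brood_size,
    phi_egg_daily = x$phi_egg_daily,
    phi_chick_daily = x$phi_chick_daily,
    phi_egg_period = x$phi_egg_daily^x$ep,
    phi_chick_period = x$phi_chick_daily^x$yp,
    rho = x$rho,
    fpba = productivity_fpba(x$brood_size, x$phi_egg_daily,
                             x$phi_chick_daily, x$ep, x$yp)
  )
}
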