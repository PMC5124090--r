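#' Zero-truncated Poisson density
#'
#' Probability mass of a Poisson distribution conditioned on being at least
#' one, used for brood sizes (a "successful" nest has at least one young).
#' Parameterised by the rate `lambda` of the untruncated Poisson.
#'
#' @param x Integer counts (>= 1).
#' @param lambda Poisson rate (> 0).
#' @param log Return log density?
#' @return Density values; zero (or `-Inf`) for `x < 1`.
#' @export
dztpois <- function(x, lambda, log = FALSE) {
  check_nonneg(lambda, "lambda")
  out <- dpois(x, lambda, log = TRUE) - log1p(-exp(-lambda))
  out[x < 1] <- -Inf
  if (log) out else exp(out)
}

rztpois <- function(n, lambda) {
  # inverse-cdf draw restricted to x >= 1
  qpois(runif(n, ppois(0, lambda), 1), lambda)
}

#' Log-normal observation log likelihood for an abundance index
#'
#' Each observed count `y_t` is log-normally distributed around the latent
#' population `N_t` (median `N_t`, log-scale s.d. `sigma_obs`). Missing
#' counts contribute zero: the latent state is still propagated by the
#' process model, which is how survey gap years are imputed.
#'
#' @param y Observed counts (positive; `NA` = missing year).
#' @param n Latent population sizes (same length as `y`).
#' @param sigma_obs Log-scale observation standard deviation.
#' @return Scalar log likelihood summed over years; `-Inf` if any observed
#'   year has `n = 0`.
#' @export
observation_loglik <- function(y, n, sigma_obs) {
  check_nonneg(sigma_obs, "sigma_obs")
  check_count(n, "n")
  if (length(y) != length(n)) abort("`y` and `n` must have equal length.")
  obs <- !is.na(y)
  if (!any(obs)) return(0)
  if (any(y[obs] <= 0)) abort("Observed counts must be positive (use NA for missing years).")
  if (any(n[obs] == 0)) return(-Inf)
  sum(dlnorm(y[obs], meanlog = log(n[obs]), sdlog = sigma_obs, log = TRUE))
}

encounter_matrix <- function(histories, n_occasions) {
  if (is.matrix(histories)) {
    x <- histories
  } else {
    if (!is.data.frame(histories) || !"encounter_string" %in% names(histories)) {
      abort("`histories` must be a 0/1 matrix or a data frame with an `encounter_string` column.")
    }
    s <- as.character(histories$encounter_string)
    if (any(nchar(s) != n_occasions)) {
      abort(sprintf("Encounter strings must have one character per study year (%d).", n_occasions))
    }
    if (any(grepl("[^01]", s))) abort("Encounter strings may contain only 0 and 1.")
    x <- matrix(as.integer(unlist(strsplit(s, ""))), nrow = length(s),
                ncol = n_occasions, byrow = TRUE)
  }
  if (ncol(x) != n_occasions) {
    abort(sprintf("Capture histories span %d occasions but %d are expected.",
                  ncol(x), n_occasions))
  }
  first <- apply(x, 1, function(r) which(r == 1)[1])
  if (anyNA(first)) abort("Every capture history must contain at least one encounter (its release).")
  attr(x, "first") <- as.integer(first)
  x
}

#' Cormack-Jolly-Seber log likelihood
#'
#' Standard CJS likelihood over individual encounter histories, conditioning
#' on first capture, with time-varying annual survival and a constant
#' recapture probability. The unobserved tail after the last encounter is
#' marginalised with the usual `chi` recursion
#' (`chi_t = (1 - phi_t) + phi_t (1 - p) chi_{t+1}`).
#'
#' @param histories Either a 0/1 matrix (rows = individuals, columns =
#'   occasions) or a data frame with an `encounter_string` column of 0/1
#'   strings spanning all study years.
#' @param phi_ad Survival probabilities, one per interval
#'   (`n_occasions - 1`).
#' @param p_recapture Constant per-occasion recapture probability.
#' @return Scalar log likelihood, additive over independent histories.
#' @export
cjs_loglik <- function(histories, phi_ad, p_recapture) {
  check_probability(phi_ad, "phi_ad")
  check_probability(p_recapture, "p_recapture")
  tt <- length(phi_ad) + 1L
  x <- encounter_matrix(histories, tt)
  first <- attr(x, "first")
  p <- p_recapture
  chi <- numeric(tt)
  chi[tt] <- 1
  if (tt > 1) {
    for (t in (tt - 1):1) {
      chi[t] <- (1 - phi_ad[t]) + phi_ad[t] * (1 - p) * chi[t + 1]
    }
  }
  lphi <- log(phi_ad)
  lp <- log(p)
  lq <- log1p(-p)
  ll <- 0
  for (i in seq_len(nrow(x))) {
    f <- first[i]
    occ <- which(x[i, ] == 1)
    l <- max(occ)
    if (l > f) {
      for (t in f:(l - 1L)) {
        ll <- ll + lphi[t] + if (x[i, t + 1L] == 1L) lp else lq
      }
    }
    ll <- ll + log(chi[l])
  }
  ll
}

validate_nests <- function(records) {
  if (!is.data.frame(records)) abort("`records` must be a data frame of nest records.")
  needed <- c("year", "brood", "egg_days", "egg_survived", "chick_days",
              "chick_survived")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    abort(paste0("Nest records lack columns: ", paste(missing_cols, collapse = ", ")))
  }
  check_nonneg(records$egg_days, "egg_days")
  check_nonneg(records$chick_days, "chick_days")
  egg_ok <- records$egg_survived %in% c(0, 1)
  chick_ok <- records$chick_survived %in% c(0, 1)
  if (!all(egg_ok) || !all(chick_ok)) abort("Survival flags must be 0/1.")
  # exposure includes the failure day, so a failure implies >= 1 exposure day
  if (any(records$egg_survived == 0 & records$egg_days == 0)) {
    abort("Egg-stage failures must have at least one exposure day.")
  }
  # a nest enters the chick stage only if it hatched and has chick exposure;
  # a flagged chick failure with no exposure days is contradictory
  if (any(records$chick_survived == 0 & records$chick_days == 0 &
            records$egg_survived == 1 & records$brood >= 1)) {
    abort("Chick-stage failures must have at least one exposure day.")
  }
  if (any(records$egg_survived == 0 & records$chick_days > 0)) {
    abort("Nests that failed at the egg stage cannot have chick-stage exposure.")
  }
  if (any(records$egg_survived == 1 & records$chick_days > 0 & records$brood < 1)) {
    abort("Nests entering the chick stage must have brood >= 1.")
  }
  invisible(records)
}

stage_index <- function(records, season_years, k) {
  if (is.null(season_years)) {
    if (k == 1L) return(rep(1L, nrow(records)))
    season_years <- sort(unique(records$year))
  }
  idx <- match(records$year, season_years)
  if (anyNA(idx) || any(idx > k)) {
    abort("Nest record years must match the supplied season years.")
  }
  idx
}

#' Mayfield-type nest survival log likelihood
#'
#' Exposure-day likelihood for daily nest survival: every survived exposure
#' day contributes `log(phi)` and a failure contributes `log(1 - phi)` on its
#' final day. `egg_days`/`chick_days` count total exposure days *including*
#' the failure day, so a record surviving `d` days contributes `d log(phi)`
#' and a record failing after `d` survived days has `d + 1` exposure days.
#' The maximum-likelihood estimate of `phi` is the classical Mayfield ratio
#' (survived exposure days) / (total exposure days).
#'
#' @param records Nest-record data frame (see [simulate_region()] for the
#'   dialect).
#' @param phi_egg_daily,phi_chick_daily Daily survival probabilities, either
#'   single values or one per breeding season.
#' @param season_years Year labels matching the elements of the `phi`
#'   vectors; defaults to the sorted unique record years.
#' @return Scalar log likelihood.
#' @export
nest_loglik <- function(records, phi_egg_daily, phi_chick_daily,
                        season_years = NULL) {
  validate_nests(records)
  if (nrow(records) == 0) return(0)
  check_probability(phi_egg_daily, "phi_egg_daily")
  check_probability(phi_chick_daily, "phi_chick_daily")
  k <- max(length(phi_egg_daily), length(phi_chick_daily))
  phi_egg_daily <- recycle_to(phi_egg_daily, k, "phi_egg_daily")
  phi_chick_daily <- recycle_to(phi_chick_daily, k, "phi_chick_daily")
  idx <- stage_index(records, season_years, k)
  pe <- phi_egg_daily[idx]
  pc <- phi_chick_daily[idx]
  ef <- 1 - records$egg_survived
  chick_stage <- records$egg_survived == 1 & records$chick_days > 0
  cf <- ifelse(chick_stage, 1 - records$chick_survived, 0)
  fail_term <- function(f, phi) ifelse(f > 0, f * log1p(-phi), 0)
  sum((records$egg_days - ef) * log(pe) + fail_term(ef, pe)) +
    sum((records$chick_days - cf) * log(pc) + fail_term(cf, pc))
}

#' Brood-size log likelihood
#'
#' Zero-truncated Poisson likelihood for observed brood sizes of nests that
#' reached the chick stage, with a per-season mean parameter.
#'
#' @inheritParams nest_loglik
#' @param brood_mean Zero-truncated-Poisson rate(s), one per season or a
#'   single value.
#' @return Scalar log likelihood (0 for an empty record set).
#' @export
brood_loglik <- function(records, brood_mean, season_years = NULL) {
  validate_nests(records)
  hatched <- records[records$egg_survived == 1 & records$chick_days > 0, , drop = FALSE]
  if (nrow(hatched) == 0) return(0)
  if (any(hatched$brood != round(hatched$brood))) {
    abort("Brood counts must be integers.")
  }
  check_nonneg(brood_mean, "brood_mean")
  k <- length(brood_mean)
  idx <- stage_index(hatched, season_years, k)
  sum(dztpois(hatched$brood, brood_mean[idx], log = TRUE))
}

#' Prior specification for the IPM
#'
#' All probabilities carry Uniform(0, 1) priors, the brood mean
#' Uniform(0, 10), and the observation s.d. half-Normal(0, 1). The yearly
#' recruitment scaling factors `rho_t` are exchangeable: by default
#' `log(rho_t) ~ Normal(mu_rho, sd_rho)` with `mu_rho ~ Normal(0, 2)` and
#' `sd_rho ~ half-Normal(0, 1)`; set `rho_prior = "uniform"` for independent
#' Uniform(0, 5) priors instead.
#'
#' @param rho_prior `"hierarchical"` (default) or `"uniform"`.
#' @param phi_ad,phi_egg,phi_chick,p,brood Uniform bounds `c(lo, hi)`.
#' @param sigma_sd Scale of the half-Normal prior on `sigma_obs`.
#' @param rho_bounds Uniform bounds when `rho_prior = "uniform"`.
#' @param rho_mu_mean,rho_mu_sd Normal hyperprior on `mu_rho`.
#' @param rho_sd_scale Half-Normal scale of `sd_rho`.
#' @return A list of class `ipm_priors`.
#' @export
default_priors <- function(rho_prior = c("hierarchical", "uniform"),
                           phi_ad = c(0, 1), phi_egg = c(0, 1),
                           phi_chick = c(0, 1), p = c(0, 1),
                           brood = c(0, 10), sigma_sd = 1,
                           rho_bounds = c(0, 5),
                           rho_mu_mean = 0, rho_mu_sd = 2,
                           rho_sd_scale = 1) {
  rho_prior <- match.arg(rho_prior)
  structure(
    list(phi_ad = phi_ad, phi_egg = phi_egg, phi_chick = phi_chick, p = p,
         brood = brood, sigma_sd = sigma_sd, rho_prior = rho_prior,
         rho_bounds = rho_bounds, rho_mu_mean = rho_mu_mean,
         rho_mu_sd = rho_mu_sd, rho_sd_scale = rho_sd_scale),
    class = "ipm_priors"
  )
}

dunif_log <- function(x, bounds) {
  ifelse(x >= bounds[1] & x <= bounds[2],
         -log(bounds[2] - bounds[1]), -Inf)
}

dhalfnorm_log <- function(x, sd) {
  ifelse(x >= 0, log(2) + dnorm(x, 0, sd, log = TRUE), -Inf)
}

log_prior <- function(params, priors = default_priors()) {
  stopifnot(inherits(params, "ipm_params"), inherits(priors, "ipm_priors"))
  lp <- sum(dunif_log(params$phi_ad, priors$phi_ad)) +
    sum(dunif_log(params$phi_egg_daily, priors$phi_egg)) +
    sum(dunif_log(params$phi_chick_daily, priors$phi_chick)) +
    sum(dunif_log(params$brood_size, priors$brood)) +
    dunif_log(params$p_recapture, priors$p) +
    dhalfnorm_log(params$sigma_obs, priors$sigma_sd)
  if (priors$rho_prior == "uniform") {
    lp <- lp + sum(dunif_log(params$rho, priors$rho_bounds))
  } else {
    # log-normal density of rho given hyperparameters, plus hyperpriors
    lp <- lp +
      sum(dlnorm(params$rho, params$mu_log_rho, params$sd_log_rho, log = TRUE)) +
      dnorm(params$mu_log_rho, priors$rho_mu_mean, priors$rho_mu_sd, log = TRUE) +
      dhalfnorm_log(params$sd_log_rho, priors$rho_sd_scale)
  }
  lp
}

#' Joint log posterior kernel of the integrated population model
#'
#' Sum of the observation, mark-recapture, nest-survival and brood-size log
#' likelihoods, the latent-process log densities (binomial survivors and
#' Poisson recruits) and the log priors, evaluated at a fixed parameter set
#' and latent trajectory. Returns `-Inf` for any latent configuration
#' outside the model's support (e.g. more surviving adults than were alive
#' the year before, or `N != N_a + N_r`).
#'
#' @param data An [ipm_data()] object.
#' @param params An [demographic_params()] object with `n_years` matching
#'   `data`.
#' @param latent A data frame with columns `n`, `n_a`, `n_r` (one row per
#'   year, as produced by [simulate_latent()]).
#' @param priors An [default_priors()] specification.
#' @return Scalar log posterior kernel.
#' @export
joint_loglik <- function(data, params, latent, priors = default_priors()) {
  stopifnot(inherits(data, "ipm_data"), inherits(params, "ipm_params"))
  tt <- params$n_years
  if (length(data$years) != tt || nrow(latent) != tt) {
    abort("`data`, `params` and `latent` must span the same number of years.")
  }
  n <- latent$n
  n_a <- latent$n_a
  n_r <- latent$n_r
  if (any(n < 0 | n_a < 0 | n_r < 0)) return(-Inf)
  if (any(n[-1] != n_a[-1] + n_r[-1])) return(-Inf)
  if (any(n_a[-1] > n[-tt])) return(-Inf)
  fpba <- productivity_fpba(params$brood_size, params$phi_egg_daily,
                            params$phi_chick_daily, params$ep, params$yp)
  proc <- sum(dbinom(n_a[-1], n[-tt], params$phi_ad, log = TRUE)) +
    sum(dpois(n_r[-1], n[-tt] * 0.5 * fpba * params$rho, log = TRUE))
  if (!is.finite(proc)) return(-Inf)
  season_years <- data$years[seq_len(tt - 1L)]
  proc +
    observation_loglik(data$counts, n, params$sigma_obs) +
    cjs_loglik(data$histories, params$phi_ad, params$p_recapture) +
    nest_loglik(data$nests, params$phi_egg_daily, params$phi_chick_daily,
                season_years) +
    brood_loglik(data$nests, params$brood_size, season_years) +
    log_prior(params, priors)
}
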