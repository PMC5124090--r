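#' Fledglings per breeding attempt
#'
#' Productivity of a single nesting attempt: the expected number of fledged
#' young is the brood size discounted by survival through the egg
#' (incubation) and chick (brooding) stages, each expressed as a daily
#' survival probability raised to the number of exposure days:
#' `B * phi_egg^ep * phi_chick^yp`.
#'
#' @param brood_size Mean young per successful nest.
#' @param phi_egg_daily,phi_chick_daily Daily nest survival probabilities.
#' @param ep,yp Days of exposure at the egg / chick stage.
#' @return Numeric vector of expected fledglings per breeding attempt.
#' @examples
#' productivity_fpba(5.78, 0.71^(1 / 13), 0.76^(1 / 13)) # ~ 5.78 * .71 * .76
#' @export
productivity_fpba <- function(brood_size, phi_egg_daily, phi_chick_daily,
                              ep = 13L, yp = 13L) {
  check_nonneg(brood_size, "brood_size")
  check_probability(phi_egg_daily, "phi_egg_daily")
  check_probability(phi_chick_daily, "phi_chick_daily")
  check_count(ep, "ep", min = 0L)
  check_count(yp, "yp", min = 0L)
  brood_size * phi_egg_daily^ep * phi_chick_daily^yp
}

#' Advance the female population by one year
#'
#' Stochastic one-year update of the latent female population. Survivors are
#' binomial, `N_a ~ Binomial(N_prev, phi_ad)`; recruits are Poisson,
#' `N_r ~ Poisson(N_prev * 0.5 * fpba * rho)` (the 0.5 keeps only the female
#' half of production). Extinction (`N_prev = 0`) is absorbing. Uses the
#' current R RNG stream, so results are reproducible under `set.seed()`.
#'
#' @param n_prev Female population size(s) in the previous year.
#' @param phi_ad Annual adult survival probability.
#' @param fpba Fledglings per breeding attempt ([productivity_fpba()]).
#' @param rho Recruitment scaling factor.
#' @return A tibble with integer columns `n_a` (surviving adults) and `n_r`
#'   (recruits); rows follow the longest input.
#' @examples
#' set.seed(1)
#' step_population(1000, phi_ad = 0.45, fpba = 3.0, rho = 0.40)
#' @export
step_population <- function(n_prev, phi_ad, fpba, rho) {
  k <- max(length(n_prev), length(phi_ad), length(fpba), length(rho))
  n_prev <- check_count(recycle_to(n_prev, k, "n_prev"), "n_prev")
  phi_ad <- recycle_to(phi_ad, k, "phi_ad")
  fpba <- recycle_to(fpba, k, "fpba")
  rho <- recycle_to(rho, k, "rho")
  check_probability(phi_ad, "phi_ad")
  check_nonneg(fpba, "fpba")
  check_nonneg(rho, "rho")
  tibble(
    n_a = rbinom(k, n_prev, phi_ad),
    n_r = rpois(k, n_prev * 0.5 * fpba * rho)
  )
}

#' Simulate a latent population trajectory
#'
#' Iterates [step_population()] from an initial female population `n0` over
#' all transitions in `params`.
#'
#' @param params An [demographic_params()] object.
#' @param n0 Initial female population (year 1).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return A tibble with columns `year_index`, `n`, `n_a`, `n_r` (year 1 has
#'   `n_a = n`, `n_r = 0` by convention).
#' @export
simulate_latent <- function(params, n0 = 1000L, seed = NULL) {
  stopifnot(inherits(params, "ipm_params"))
  n0 <- check_count(n0, "n0")
  with_seed(seed, {
    tt <- params$n_years
    fpba <- productivity_fpba(params$brood_size, params$phi_egg_daily,
                              params$phi_chick_daily, params$ep, params$yp)
    n <- n_a <- n_r <- integer(tt)
    n[1] <- n0
    n_a[1] <- n0
    for (t in 2:tt) {
      stp <- step_population(n[t - 1], params$phi_ad[t - 1],
                             fpba[t - 1], params$rho[t - 1])
      n_a[t] <- stp$n_a
      n_r[t] <- stp$n_r
      n[t] <- n_a[t] + n_r[t]
    }
    tibble(year_index = seq_len(tt), n = n, n_a = n_a, n_r = n_r)
  })
}
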