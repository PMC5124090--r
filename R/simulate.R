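simulate_nests <- function(params, n_per_year, years, region) {
  k <- params$n_transitions
  season_years <- years[seq_len(k)]
  rows <- purrr::map(seq_len(k), function(j) {
    pe <- params$phi_egg_daily[j]
    pc <- params$phi_chick_daily[j]
    n <- n_per_year
    # day of first failure (geometric); beyond the stage length = survived
    fail_e <- rgeom(n, max(1 - pe, 1e-12)) + 1L
    egg_survived <- as.integer(fail_e > params$ep)
    egg_days <- ifelse(egg_survived == 1L, params$ep, fail_e)
    brood <- integer(n)
    chick_days <- integer(n)
    chick_survived <- integer(n)
    h <- egg_survived == 1L
    nh <- sum(h)
    if (nh > 0) {
      brood[h] <- as.integer(rztpois(nh, params$brood_size[j]))
      fail_c <- rgeom(nh, max(1 - pc, 1e-12)) + 1L
      cs <- as.integer(fail_c > params$yp)
      chick_survived[h] <- cs
      chick_days[h] <- ifelse(cs == 1L, params$yp, fail_c)
    }
    tibble(region = region, year = season_years[j], brood = brood,
           egg_days = as.integer(egg_days), egg_survived = egg_survived,
           chick_days = as.integer(chick_days),
           chick_survived = chick_survived)
  })
  list_rbind(rows)
}

simulate_histories <- function(params, n_releases, years, region) {
  tt <- params$n_years
  p <- params$p_recapture
  rows <- purrr::map(seq_len(tt - 1L), function(f) {
    mat <- matrix(0L, n_releases, tt)
    mat[, f] <- 1L
    alive <- rep(TRUE, n_releases)
    for (t in (f + 1L):tt) {
      alive <- alive & (runif(n_releases) < params$phi_ad[t - 1L])
      seen <- alive & (runif(n_releases) < p)
      mat[seen, t] <- 1L
    }
    tibble(region = region, first_year = years[f],
           encounter_string = apply(mat, 1, paste0, collapse = ""))
  })
  list_rbind(rows)
}

#' Simulate a complete regional dataset with known truth
#'
#' Generates the three observation streams the IPM consumes from known
#' demographic parameters: a latent female population propagated by
#' binomial survival and Poisson recruitment, log-normally perturbed counts
#' (with the preset's missing survey years masked), nest records with
#' day-by-day Bernoulli fates over the egg and chick stages and
#' zero-truncated-Poisson broods, and capture histories with Bernoulli
#' survival and recapture.
#'
#' @param preset An [scenario_preset()].
#' @param seed Integer seed; the whole scenario is reproducible from it.
#' @return An object of class `ipm_scenario`: a list with `truth` (the drawn
#'   [demographic_params()]), `latent` (tibble of true `N`, `N_a`, `N_r`),
#'   `data` (an [ipm_data()]), `preset`, `seed`, and an `extinct` flag set
#'   when the population hit zero before the final year.
#' @examples
#' sc <- simulate_region(scenario_preset("northwest-like", n_years = 6,
#'                                       n_nests_per_year = 20,
#'                                       n_releases_per_year = 20),
#'                       seed = 1)
#' sc$data
#' @export
simulate_region <- function(preset, seed = NULL) {
  stopifnot(inherits(preset, "ipm_preset"))
  region <- sub("-like$|-recovery$", "", preset$name)
  with_seed(seed, {
    params <- draw_yearly_params(preset)
    tt <- preset$n_years
    years <- preset$start_year + seq_len(tt) - 1L
    latent <- simulate_latent(params, n0 = preset$n0)
    extinct <- any(latent$n == 0)
    counts <- rlnorm(tt, meanlog = log(pmax(latent$n, 1e-9)),
                     sdlog = max(params$sigma_obs, 1e-12))
    counts <- round(counts, 3) # survey indices carry finite precision
    counts[latent$n == 0] <- NA_real_
    mi <- preset$missing_years
    mi <- mi[mi >= 1 & mi <= tt]
    counts[mi] <- NA_real_
    nests <- simulate_nests(params, preset$n_nests_per_year, years, region)
    histories <- simulate_histories(params, preset$n_releases_per_year,
                                    years, region)
    data <- ipm_data(region = region, years = years, counts = counts,
                     nests = nests, histories = histories)
    structure(
      list(truth = params, latent = latent, data = data, preset = preset,
           seed = seed, extinct = extinct),
      class = "ipm_scenario"
    )
  })
}

#' @export
print.ipm_scenario <- function(x, ...) {
  cat("<ipm_scenario> preset '", x$preset$name, "'",
      if (isTRUE(x$extinct)) " (extinct before final year)", "\n", sep = "")
  print(x$data)
  invisible(x)
}
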