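#' MCMC configuration for fitting the IPM
#'
#' Desk-scale defaults: 4 chains of 20,000 iterations, 10,000 burn-in
#' (including 1,000 adaptive iterations), thinning by 10, i.e. 1,000
#' retained draws per chain. [study_scale_config()] mirrors the original
#' study's heavier protocol (10 chains of 200,000, half discarded, thin 50).
#'
#' @param n_chains Number of chains (>= 2; the Gelman-Rubin diagnostic needs
#'   several).
#' @param n_iter Total iterations per chain.
#' @param n_burnin Discarded initial iterations per chain (< `n_iter`).
#' @param thin Thinning interval (>= 1).
#' @param n_adapt Adaptive iterations (sampler tuning), counted as part of
#'   the burn-in; proposal tuning is frozen afterwards.
#' @param seed Integer seed controlling every chain's RNG.
#' @param priors An [default_priors()] specification.
#' @param quiet Suppress sampler progress output.
#' @return A list of class `ipm_fit_config`.
#' @export
fit_config <- function(n_chains = 4L, n_iter = 20000L, n_burnin = 10000L,
                       thin = 10L, n_adapt = 1000L, seed = 1L,
                       priors = default_priors(), quiet = TRUE) {
  n_chains <- check_count(n_chains, "n_chains", min = 2L)
  n_iter <- check_count(n_iter, "n_iter", min = 2L)
  n_burnin <- check_count(n_burnin, "n_burnin", min = 0L)
  thin <- check_count(thin, "thin", min = 1L)
  n_adapt <- check_count(n_adapt, "n_adapt", min = 100L)
  if (n_burnin >= n_iter) abort("`n_burnin` must be smaller than `n_iter`.")
  if (n_adapt > n_burnin) abort("`n_adapt` cannot exceed `n_burnin`.")
  stopifnot(inherits(priors, "ipm_priors"))
  structure(
    list(n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
         thin = thin, n_adapt = n_adapt, seed = as.integer(seed),
         priors = priors, quiet = isTRUE(quiet)),
    class = "ipm_fit_config"
  )
}

#' @rdname fit_config
#' @param ... Passed on to [fit_config()].
#' @export
study_scale_config <- function(...) {
  fit_config(n_chains = 10L, n_iter = 200000L, n_burnin = 100000L,
             thin = 50L, ...)
}

# m-array from individual encounter histories: every capture before the
# final occasion is a release; cell (j, k) counts first recaptures at
# occasion k + 1, last column = never seen again.
build_m_array <- function(histories, n_occasions) {
  x <- encounter_matrix(histories, n_occasions)
  tt <- n_occasions
  marr <- matrix(0L, tt - 1L, tt)
  rel <- integer(tt - 1L)
  for (i in seq_len(nrow(x))) {
    occ <- which(x[i, ] == 1L)
    for (a in seq_along(occ)) {
      f <- occ[a]
      if (f == tt) next
      rel[f] <- rel[f] + 1L
      if (a < length(occ)) {
        marr[f, occ[a + 1L] - 1L] <- marr[f, occ[a + 1L] - 1L] + 1L
      } else {
        marr[f, tt] <- marr[f, tt] + 1L
      }
    }
  }
  list(marr = marr, rel = rel)
}

ipm_model_string <- function(priors) {
  rho_block <- if (priors$rho_prior == "hierarchical") {
    "
  # non-centred parameterisation: keeps the sampler off the funnel when a
  # year's recruitment is weakly informed (e.g. around unsurveyed years)
  for (j in 1:Tm1) {
    z_rho[j] ~ dnorm(0, 1)
    rho[j] <- exp(mu_log_rho + sd_log_rho * z_rho[j])
  }
  mu_log_rho ~ dnorm(rho_mu_mean, rho_mu_prec)
  sd_log_rho ~ dnorm(0, rho_sd_prec) T(0,)"
  } else {
    "
  for (j in 1:Tm1) { rho[j] ~ dunif(rho_lo, rho_hi) }"
  }
  paste0("
model {
  for (j in 1:Tm1) {
    phi_ad[j] ~ dunif(phi_ad_lo, phi_ad_hi)
    brood[j] ~ dunif(brood_lo, brood_hi)
    phi_egg[j] ~ dunif(phi_egg_lo, phi_egg_hi)
    phi_chick[j] ~ dunif(phi_chick_lo, phi_chick_hi)
    fpba[j] <- brood[j] * pow(phi_egg[j], ep) * pow(phi_chick[j], yp)
  }", rho_block, "
  p ~ dunif(p_lo, p_hi)
  sigma ~ dnorm(0, sigma_prec) T(0,)
  tau <- pow(sigma, -2)

  # state process: binomial survivors + Poisson recruits (females only)
  N[1] <- N1
  for (t in 2:T) {
    Na[t] ~ dbin(phi_ad[t-1], N[t-1])
    Nr[t] ~ dpois(N[t-1] * 0.5 * fpba[t-1] * rho[t-1])
    N[t] <- Na[t] + Nr[t]
  }

  # log-normal observation of the index (missing years stay unobserved)
  for (t in 1:T) { logy[t] ~ dnorm(log(N[t]), tau) }

  # CJS mark-recapture likelihood via the m-array; first-recapture cell
  # probabilities built recursively along each release cohort's row
  q <- 1 - p
  for (j in 1:Tm1) {
    marr[j, 1:T] ~ dmulti(pr[j, 1:T], rel[j])
    pr[j, j] <- phi_ad[j] * p
    for (k in (j+1):Tm1) { pr[j, k] <- pr[j, k-1] * q * phi_ad[k] }
    for (k in 1:(j-1)) { pr[j, k] <- 0 }
    pr[j, T] <- 1 - sum(pr[j, 1:Tm1])
  }

  # Mayfield exposure-day likelihoods (binomial in failure counts)
  for (j in 1:Tm1) {
    egg_fail[j] ~ dbin(1 - phi_egg[j], egg_trials[j])
    chick_fail[j] ~ dbin(1 - phi_chick[j], chick_trials[j])
  }

  # zero-truncated Poisson brood sizes via the zeros trick
  for (j in 1:Tm1) {
    zero[j] ~ dpois(zero_c - brood_ll[j])
    brood_ll[j] <- brood_sum[j] * log(brood[j]) -
      brood_n[j] * log(exp(brood[j]) - 1) - brood_lfact[j]
  }
}")
}

ipm_jags_data <- function(data, priors, n0) {
  tt <- length(data$years)
  k <- tt - 1L
  season_years <- data$years[seq_len(k)]
  nests <- data$nests
  j_idx <- match(nests$year, season_years)
  agg <- function(v, idx) as.vector(tapply(v, factor(idx, levels = seq_len(k)),
                                           sum, default = 0))
  egg_fail <- agg(1 - nests$egg_survived, j_idx)
  egg_trials <- agg(nests$egg_days, j_idx)
  hatched <- nests$egg_survived == 1 & nests$chick_days > 0
  chick_fail <- agg(ifelse(hatched, 1 - nests$chick_survived, 0), j_idx)
  chick_trials <- agg(nests$chick_days, j_idx)
  brood_n <- agg(as.numeric(hatched), j_idx)
  brood_sum <- agg(ifelse(hatched, nests$brood, 0), j_idx)
  brood_lfact <- agg(ifelse(hatched, lfactorial(nests$brood), 0), j_idx)
  ma <- build_m_array(data$histories, tt)
  jd <- list(
    T = tt, Tm1 = k, N1 = n0,
    ep = attr(data, "ep") %||% 13L, yp = attr(data, "yp") %||% 13L,
    logy = log(data$counts),
    marr = ma$marr, rel = ma$rel,
    egg_fail = egg_fail, egg_trials = egg_trials,
    chick_fail = chick_fail, chick_trials = chick_trials,
    brood_n = brood_n, brood_sum = brood_sum, brood_lfact = brood_lfact,
    zero = rep(0L, k), zero_c = 10000,
    phi_ad_lo = priors$phi_ad[1], phi_ad_hi = priors$phi_ad[2],
    phi_egg_lo = priors$phi_egg[1], phi_egg_hi = priors$phi_egg[2],
    phi_chick_lo = priors$phi_chick[1], phi_chick_hi = priors$phi_chick[2],
    brood_lo = priors$brood[1], brood_hi = priors$brood[2],
    p_lo = priors$p[1], p_hi = priors$p[2],
    sigma_prec = 1 / priors$sigma_sd^2
  )
  if (priors$rho_prior == "hierarchical") {
    jd$rho_mu_mean <- priors$rho_mu_mean
    jd$rho_mu_prec <- 1 / priors$rho_mu_sd^2
    jd$rho_sd_prec <- 1 / priors$rho_sd_scale^2
  } else {
    jd$rho_lo <- priors$rho_bounds[1]
    jd$rho_hi <- priors$rho_bounds[2]
  }
  jd
}

ipm_inits <- function(data, config, n0) {
  tt <- length(data$years)
  k <- tt - 1L
  priors <- config$priors
  # latent N at the observed counts, missing years interpolated on log scale
  obs <- which(!is.na(data$counts))
  logn <- approx(obs, log(data$counts[obs]), xout = seq_len(tt), rule = 2)$y
  n_init <- pmax(round(exp(logn)), 1)
  n_init[1] <- n0
  na_init <- nr_init <- rep(NA_real_, tt)
  for (t in 2:tt) {
    na_init[t] <- min(round(0.45 * n_init[t - 1]), n_init[t], n_init[t - 1])
    nr_init[t] <- n_init[t] - na_init[t]
  }
  mid <- function(b) mean(b)
  base <- list(
    phi_ad = rep(mid(priors$phi_ad), k),
    brood = rep(mid(priors$brood), k),
    # start nest daily survival high: passerine daily nest survival is
    # close to 1 and a mid-range start puts the Poisson recruits far into
    # the tail of their initial mean
    phi_egg = rep(0.9 * priors$phi_egg[2], k),
    phi_chick = rep(0.9 * priors$phi_chick[2], k),
    p = mid(priors$p),
    sigma = qnorm(0.75) * priors$sigma_sd,
    Na = na_init, Nr = nr_init
  )
  if (priors$rho_prior == "hierarchical") {
    base$z_rho <- rep(0, k)
    base$mu_log_rho <- priors$rho_mu_mean - 1
    base$sd_log_rho <- qnorm(0.75) * priors$rho_sd_scale
  } else {
    base$rho <- rep(mid(priors$rho_bounds), k)
  }
  lapply(seq_len(config$n_chains), function(ch) {
    c(base, list(.RNG.name = "base::Mersenne-Twister",
                 .RNG.seed = (config$seed %% 1000000L) * 1000L + ch))
  })
}

#' Fit the integrated population model by MCMC
#'
#' Joins the four component likelihoods (log-normal observation of the
#' index, m-array Cormack-Jolly-Seber, Mayfield exposure-day nest survival,
#' zero-truncated-Poisson brood size) with the binomial/Poisson latent
#' process and the priors of `config$priors`, and samples the joint
#' posterior with JAGS. Fledglings per breeding attempt (`fpba`) and annual
#' growth rates (`lambda[j] = N[j+1] / N[j]`) are appended to every draw.
#' Convergence is assessed with the split Gelman-Rubin statistic; a maximum
#' above 1.1 flags the fit (with a warning) but does not error.
#'
#' @param data An [ipm_data()] object.
#' @param config An [fit_config()].
#' @param n0 Latent female population fixed in year 1 (the index scale is
#'   arbitrary, so this value just anchors it).
#' @param ep,yp Egg- and chick-stage exposure lengths (days).
#' @return An object of class `ipm_fit` (also `ipm_draws`): retained
#'   posterior draws plus data, config, per-parameter `rhat` and a
#'   `converged` flag.
#' @export
fit_ipm <- function(data, config = fit_config(), n0 = 1000L,
                    ep = 13L, yp = 13L) {
  stopifnot(inherits(data, "ipm_data"), inherits(config, "ipm_fit_config"))
  t0 <- Sys.time()
  tt <- length(data$years)
  k <- tt - 1L
  attr(data, "ep") <- ep
  attr(data, "yp") <- yp
  jd <- ipm_jags_data(data, config$priors, n0)
  inits <- ipm_inits(data, config, n0)
  monitors <- c("phi_ad", "brood", "phi_egg", "phi_chick", "rho", "p",
                "sigma", "N")
  if (config$priors$rho_prior == "hierarchical") {
    monitors <- c(monitors, "mu_log_rho", "sd_log_rho")
  }
  pb <- if (config$quiet) "none" else "text"
  model <- tryCatch(
    rjags::jags.model(textConnection(ipm_model_string(config$priors)),
                      data = jd, inits = inits,
                      n.chains = config$n_chains, n.adapt = config$n_adapt,
                      quiet = config$quiet),
    error = function(e) {
      abort(paste0("IPM initialisation failed (non-finite posterior or ",
                   "invalid data in a component likelihood): ",
                   conditionMessage(e)))
    }
  )
  if (config$n_burnin > config$n_adapt) {
    update(model, config$n_burnin - config$n_adapt, progress.bar = pb)
  }
  samples <- rjags::coda.samples(model, monitors,
                                 n.iter = config$n_iter - config$n_burnin,
                                 thin = config$thin, progress.bar = pb)
  n_keep <- nrow(samples[[1]])
  mat <- do.call(rbind, lapply(samples, as.matrix))
  # order columns by parameter group and year index
  ord <- function(nm) {
    cols <- grep(paste0("^", nm, "\\["), colnames(mat), value = TRUE)
    cols[order(as.integer(sub(".*\\[(\\d+)\\]", "\\1", cols)))]
  }
  cols <- c(ord("phi_ad"), ord("brood"), ord("phi_egg"), ord("phi_chick"),
            ord("rho"), intersect(c("p", "sigma", "mu_log_rho", "sd_log_rho"),
                                  colnames(mat)), ord("N"))
  mat <- mat[, cols, drop = FALSE]
  draws <- as_tibble(mat)
  nmat <- mat[, ord("N"), drop = FALSE]
  fpba <- sapply(seq_len(k), function(j) {
    mat[, sprintf("brood[%d]", j)] *
      mat[, sprintf("phi_egg[%d]", j)]^ep *
      mat[, sprintf("phi_chick[%d]", j)]^yp
  })
  lambda <- sapply(seq_len(k), function(j) nmat[, j + 1] / nmat[, j])
  colnames(fpba) <- sprintf("fpba[%d]", seq_len(k))
  colnames(lambda) <- sprintf("lambda[%d]", seq_len(k))
  draws <- bind_cols(
    tibble(.chain = rep(seq_len(config$n_chains), each = n_keep),
           .iteration = rep(seq_len(n_keep), config$n_chains),
           .draw = seq_len(n_keep * config$n_chains)),
    draws, as_tibble(fpba), as_tibble(lambda)
  )
  fit <- structure(
    list(draws = draws, years = data$years, region = data$region,
         ep = ep, yp = yp, n0 = n0, data = data, config = config,
         rhat = NULL, converged = NA,
         runtime = as.numeric(Sys.time() - t0, units = "secs")),
    class = c("ipm_fit", "ipm_draws")
  )
  rh <- gelman_rubin(fit)
  fit$rhat <- rh
  fit$converged <- isTRUE(attr(rh, "all_converged"))
  if (!fit$converged) {
    warn(sprintf("Fit for region '%s' has max split-Rhat %.3f >= 1.1.",
                 data$region, max(rh$rhat, na.rm = TRUE)))
  }
  fit
}

#' Construct a posterior-draws object directly
#'
#' Low-level constructor used to build `ipm_draws` objects from externally
#' generated draws (e.g. analytically constructed posteriors in tests, or
#' draws read back from disk with [read_ipm_draws()]).
#'
#' @param draws Tibble of draws; yearly parameters use `name[j]` columns.
#'   `.chain`/`.iteration`/`.draw` columns are added if absent (single
#'   chain).
#' @param years Calendar years spanned.
#' @param region Region label.
#' @param ep,yp Exposure lengths used for period-scale conversions.
#' @return An object of class `ipm_draws`.
#' @export
ipm_draws <- function(draws, years, region = "synthetic", ep = 13L, yp = 13L) {
  draws <- as_tibble(draws)
  if (!".draw" %in% names(draws)) draws$.draw <- seq_len(nrow(draws))
  if (!".chain" %in% names(draws)) draws$.chain <- 1L
  if (!".iteration" %in% names(draws)) {
    draws$.iteration <- stats::ave(seq_len(nrow(draws)), draws$.chain,
                                   FUN = seq_along)
  }
  structure(
    list(draws = draws, years = check_count(years, "years"), region = region,
         ep = ep, yp = yp),
    class = "ipm_draws"
  )
}

#' Extract a draws-by-year matrix for one parameter
#'
#' @param x An `ipm_draws` or `ipm_fit`.
#' @param name Parameter base name (e.g. `"phi_ad"`, `"lambda"`, `"N"`).
#' @return Matrix with one row per draw, columns in year-index order.
#' @export
param_matrix <- function(x, name) {
  stopifnot(inherits(x, "ipm_draws"))
  cols <- grep(paste0("^", name, "\\[\\d+\\]$"), names(x$draws), value = TRUE)
  if (!length(cols)) {
    if (name %in% names(x$draws)) {
      return(matrix(x$draws[[name]], ncol = 1, dimnames = list(NULL, name)))
    }
    abort(sprintf("No columns found for parameter '%s'.", name))
  }
  cols <- cols[order(as.integer(sub(".*\\[(\\d+)\\]", "\\1", cols)))]
  as.matrix(x$draws[cols])
}

#' Split Gelman-Rubin convergence diagnostic
#'
#' Split-chain potential scale reduction factor: every retained chain is
#' split in half and the classical Gelman-Rubin statistic is computed over
#' the resulting sequences, per parameter. Constant parameters (e.g. the
#' anchored `N[1]`) get `NA`.
#'
#' @param x An `ipm_fit`/`ipm_draws` with at least two chains and at least
#'   10 retained draws per chain.
#' @return A tibble `parameter, rhat`, with attribute `all_converged`
#'   (`TRUE` iff all finite values are below 1.1).
#' @export
gelman_rubin <- function(x) {
  stopifnot(inherits(x, "ipm_draws"))
  d <- x$draws
  chains <- unique(d$.chain)
  if (length(chains) < 2) abort("The Gelman-Rubin diagnostic needs >= 2 chains.")
  if (min(table(d$.chain)) < 10) abort("Need >= 10 retained draws per chain.")
  pars <- setdiff(names(d), c(".chain", ".iteration", ".draw"))
  rhat <- map_dbl(pars, function(pn) {
    split_rhat(split(d[[pn]], d$.chain))
  })
  out <- tibble(parameter = pars, rhat = rhat)
  attr(out, "all_converged") <- all(is.na(rhat) | rhat < 1.1) &&
    any(is.finite(rhat))
  out
}

split_rhat <- function(chain_list) {
  halves <- unlist(lapply(chain_list, function(v) {
    n2 <- floor(length(v) / 2)
    list(v[seq_len(n2)], v[seq_len(n2) + n2])
  }), recursive = FALSE)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  w <- mean(vars)
  if (!is.finite(w) || w == 0) return(NA_real_)
  b <- n * var(means)
  # floored at 1: with zero between-sequence variance the ratio estimator
  # dips below 1 by the (n-1)/n factor, which is sampling slack, not signal
  sqrt(max(((n - 1) / n * w + b / n) / w, 1))
}

#' Posterior summaries of latent population size in unsurveyed years
#'
#' The latent process propagates `N_t` through years with no count, so
#' their posterior is already in the draws; this extracts and labels it.
#'
#' @param fit An [fit_ipm()] result.
#' @return A tibble `year, mean, sd, q2.5, median, q97.5`, one row per
#'   missing count year (zero rows when none are missing).
#' @export
impute_missing_counts <- function(fit) {
  stopifnot(inherits(fit, "ipm_fit"))
  miss <- which(is.na(fit$data$counts))
  nmat <- param_matrix(fit, "N")
  rows <- purrr::map(miss, function(i) {
    v <- nmat[, i]
    tibble(year = fit$years[i], mean = mean(v), sd = sd(v),
           `q2.5` = quantile(v, 0.025, names = FALSE), median = median(v),
           `q97.5` = quantile(v, 0.975, names = FALSE))
  })
  if (!length(rows)) {
    return(tibble(year = integer(), mean = double(), sd = double(),
                  `q2.5` = double(), median = double(), `q97.5` = double()))
  }
  list_rbind(rows)
}
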