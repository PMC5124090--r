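# Independent oracles used across test files. These deliberately avoid the
# package's own likelihood code paths.

# CJS probability of one encounter history by exhaustive enumeration of the
# latent death time: the individual is alive at occasions first..d and dead
# afterwards; detections after first capture are Bernoulli(p) while alive.
cjs_brute_force_one <- function(x, phi, p) {
  tt <- length(x)
  f <- which(x == 1)[1]
  total <- 0
  for (d in f:tt) {
    # alive exactly through occasion d
    pr <- 1
    if (d > f) for (t in f:(d - 1)) pr <- pr * phi[t]
    if (d < tt) pr <- pr * (1 - phi[d])
    if (d < tt && any(x[(d + 1):tt] == 1)) next # seen while dead: impossible
    if (d > f) {
      for (t in (f + 1):d) pr <- pr * if (x[t] == 1) p else (1 - p)
    }
    total <- total + pr
  }
  total
}

cjs_brute_force <- function(mat, phi, p) {
  sum(log(apply(mat, 1, cjs_brute_force_one, phi = phi, p = p)))
}

# all encounter histories of a given length containing at least one 1
all_histories <- function(tt) {
  g <- as.matrix(expand.grid(rep(list(0:1), tt)))[, tt:1, drop = FALSE]
  g <- g[rowSums(g) > 0, , drop = FALSE]
  dimnames(g) <- NULL
  g
}

# zero-truncated Poisson pmf from first principles
ztp_pmf_oracle <- function(x, lambda) {
  dpois(x, lambda) / (1 - dpois(0, lambda))
}

# m-array multinomial log likelihood (standard CJS sufficient statistics),
# written independently of the package's JAGS code
marray_loglik <- function(marr, rel, phi, p) {
  tt <- ncol(marr)
  k <- tt - 1
  ll <- 0
  for (j in seq_len(k)) {
    pr <- numeric(tt)
    for (kk in j:k) {
      pr[kk] <- prod(phi[j:kk]) * (1 - p)^(kk - j) * p
    }
    pr[tt] <- 1 - sum(pr[1:k])
    ll <- ll + dmultinom(marr[j, ], size = rel[j], prob = pr, log = TRUE)
  }
  ll
}

# Build a synthetic posterior-draws object with given per-draw correlation
# r between lambda and a named rate across k transitions.
make_correlated_draws <- function(n_draws, k, r, rate_name = "phi_ad",
                                  years = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(years)) years <- 2000 + seq_len(k + 1)
  z1 <- matrix(rnorm(n_draws * k), n_draws, k)
  z2 <- matrix(rnorm(n_draws * k), n_draws, k)
  rate <- z1
  lam <- r * z1 + sqrt(1 - r^2) * z2
  draws <- tibble::as_tibble(
    cbind(
      matrix(1 + 0.1 * lam, n_draws, k,
             dimnames = list(NULL, sprintf("lambda[%d]", seq_len(k)))),
      matrix(0.45 + 0.05 * rate, n_draws, k,
             dimnames = list(NULL, sprintf("%s[%d]", rate_name, seq_len(k))))
    )
  )
  ipm_draws(draws, years = years, region = "synthetic")
}

# brute-force re-simulation of the same construction, summarised with plain
# loops (the oracle growth_rate_correlation is compared against)
correlated_draws_oracle <- function(n_draws, k, r, seed = 99) {
  set.seed(seed)
  rs <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    z1 <- rnorm(k)
    z2 <- rnorm(k)
    rs[i] <- cor(1 + 0.1 * (r * z1 + sqrt(1 - r^2) * z2), 0.45 + 0.05 * z1)
  }
  list(mean_r = mean(rs), p_positive = mean(rs > 0))
}

# Synthetic "fitted" draws for substitution tests: a latent N path
# propagated deterministically from the rate paths, with draw-level noise
# on the rates.
make_synth_fit <- function(n_draws, years, phi, fpba, rho, n0 = 1000,
                           noise = 0.02, seed = 1) {
  set.seed(seed)
  k <- length(years) - 1
  stopifnot(length(phi) == k, length(fpba) == k, length(rho) == k)
  cols <- list()
  phim <- pmin(pmax(matrix(rep(phi, each = n_draws), n_draws, k) +
                      rnorm(n_draws * k, 0, noise), 0.01), 0.99)
  fpbam <- pmax(matrix(rep(fpba, each = n_draws), n_draws, k) +
                  rnorm(n_draws * k, 0, noise), 0)
  rhom <- pmax(matrix(rep(rho, each = n_draws), n_draws, k) +
                 rnorm(n_draws * k, 0, noise / 2), 0.01)
  nmat <- matrix(0, n_draws, k + 1)
  nmat[, 1] <- n0
  for (t in seq_len(k)) {
    nmat[, t + 1] <- round(nmat[, t] * (phim[, t] + 0.5 * fpbam[, t] * rhom[, t]))
  }
  lam <- nmat[, -1, drop = FALSE] / nmat[, -(k + 1), drop = FALSE]
  nm <- function(base, m) {
    colnames(m) <- sprintf("%s[%d]", base, seq_len(ncol(m)))
    m
  }
  draws <- tibble::as_tibble(cbind(
    nm("phi_ad", phim), nm("fpba", fpbam), nm("rho", rhom),
    nm("N", nmat), nm("lambda", lam)
  ))
  ipm_draws(draws, years = years, region = "synthetic")
}

# one small simulated scenario + fit, cached per test session
tiny_fit_cache <- new.env(parent = emptyenv())

get_tiny_fit <- function() {
  if (is.null(tiny_fit_cache$fit)) {
    preset <- scenario_preset("northwest-like", n_years = 8,
                              n_nests_per_year = 40,
                              n_releases_per_year = 60,
                              missing_years = 4L)
    sc <- simulate_region(preset, seed = 42)
    cfg <- fit_config(n_chains = 2L, n_iter = 3000L, n_burnin = 1500L,
                      thin = 3L, n_adapt = 500L, seed = 7L)
    fit <- suppressWarnings(fit_ipm(sc$data, cfg))
    tiny_fit_cache$scenario <- sc
    tiny_fit_cache$fit <- fit
  }
  list(scenario = tiny_fit_cache$scenario, fit = tiny_fit_cache$fit)
}

build_m_array_for_test <- function(histories, n_occasions) {
  ipmdemog:::build_m_array(histories, n_occasions)
}
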