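test_that("fit configuration is validated", {
  expect_error(fit_config(n_chains = 1), ">= 2")
  expect_error(fit_config(n_iter = 1000, n_burnin = 2000), "smaller than")
  expect_error(fit_config(thin = 0), "integer")
  cfg <- study_scale_config()
  expect_equal(cfg$n_chains, 10L)
  expect_equal(cfg$n_iter, 200000L)
})

test_that("a fitted model exposes coherent, reproducible draws", {
  tf <- get_tiny_fit()
  fit <- tf$fit
  cfg <- fit$config
  n_expected <- cfg$n_chains * (cfg$n_iter - cfg$n_burnin) %/% cfg$thin
  expect_equal(nrow(fit$draws), n_expected)
  # growth rates stored per draw must be exactly recomputable from N
  nmat <- param_matrix(fit, "N")
  lam <- param_matrix(fit, "lambda")
  expect_equal(lam, nmat[, -1] / nmat[, -ncol(nmat)],
               ignore_attr = TRUE, tolerance = 1e-12)
  # posterior mean of lambda is the mean of ratios, not the ratio of means
  expect_equal(colMeans(lam), colMeans(nmat[, -1] / nmat[, -ncol(nmat)]),
               ignore_attr = TRUE)
  # probabilities stay in [0, 1], no NaN anywhere
  for (nm in c("phi_ad", "phi_egg", "phi_chick", "p")) {
    m <- param_matrix(fit, nm)
    expect_true(all(m >= 0 & m <= 1))
  }
  expect_false(anyNA(fit$draws))
  # the anchored first-year population is constant
  expect_true(all(nmat[, 1] == 1000))
  # determinism: same data, same config, bit-identical draws
  fit2 <- suppressWarnings(fit_ipm(tf$scenario$data, cfg))
  expect_identical(fit$draws, fit2$draws)
  # derived fpba matches its definition on every draw
  fp <- param_matrix(fit, "fpba")
  expect_equal(fp,
               param_matrix(fit, "brood") *
                 param_matrix(fit, "phi_egg")^fit$ep *
                 param_matrix(fit, "phi_chick")^fit$yp,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("tidy and glance summarise a fit", {
  fit <- get_tiny_fit()$fit
  td <- tidy(fit)
  expect_true(all(c("term", "year", "mean", "q2.5", "q97.5", "rhat") %in%
                    names(td)))
  expect_true(all(td$`q2.5` <= td$mean & td$mean <= td$`q97.5`))
  expect_equal(sum(td$term == "phi_ad"), 7)
  gl <- glance(fit)
  expect_equal(gl$n_draws, nrow(fit$draws))
  expect_equal(gl$n_missing_years, 1L)
})

test_that("parameters are recovered from highly informative data", {
  # near-asymptotic information: noise-free counts, many nests, many
  # releases and a high recapture rate so the CJS stream pins survival
  preset <- scenario_preset("northwest-like", n_years = 6,
                            n_nests_per_year = 400,
                            n_releases_per_year = 1000,
                            p_recapture = 0.6,
                            sigma_obs = 1e-3, missing_years = integer())
  sc <- simulate_region(preset, seed = 77)
  cfg <- fit_config(n_chains = 2L, n_iter = 8000L, n_burnin = 4000L,
                    thin = 4L, n_adapt = 1000L, seed = 5L)
  fit <- suppressWarnings(fit_ipm(sc$data, cfg))
  est <- colMeans(param_matrix(fit, "phi_ad"))
  expect_true(all(abs(est - sc$truth$phi_ad) < 0.05))
  est_f <- colMeans(param_matrix(fit, "fpba"))
  truth_f <- tidy(sc$truth)$fpba
  expect_true(all(abs(est_f - truth_f) < 0.05 + 0.1 * truth_f))
})

test_that("invalid prior bounds surface as an initialisation error", {
  sc <- get_tiny_fit()$scenario
  bad <- fit_config(priors = default_priors(phi_ad = c(0.5, 0.5)))
  expect_error(fit_ipm(sc$data, bad), "initialisation failed")
})

test_that("split Gelman-Rubin flags divergence and passes iid draws", {
  # halves and chains identical: zero between-sequence variance, Rhat = 1
  x <- rnorm(50)
  d1 <- tibble::tibble(`theta[1]` = rep(c(x, x), 2),
                       .chain = rep(1:2, each = 100),
                       .iteration = rep(1:100, 2),
                       .draw = 1:200)
  gr <- gelman_rubin(ipm_draws(d1, years = 2000:2001))
  expect_equal(gr$rhat, 1)
  # chains sampling disjoint distributions are caught
  d2 <- tibble::tibble(`theta[1]` = c(rnorm(100, 0, 0.1), rnorm(100, 10, 0.1)),
                       .chain = rep(1:2, each = 100),
                       .iteration = rep(1:100, 2),
                       .draw = 1:200)
  gr2 <- gelman_rubin(ipm_draws(d2, years = 2000:2001))
  expect_gt(gr2$rhat, 5)
  expect_false(attr(gr2, "all_converged"))
  # iid normal draws: Rhat within [1, 1.02] and close to the coda reference
  set.seed(12)
  nc <- 4; nd <- 5000
  d3 <- tibble::tibble(`theta[1]` = rnorm(nc * nd),
                       .chain = rep(1:nc, each = nd),
                       .iteration = rep(1:nd, nc),
                       .draw = 1:(nc * nd))
  gr3 <- gelman_rubin(ipm_draws(d3, years = 2000:2001))
  expect_gte(gr3$rhat, 1)
  expect_lt(gr3$rhat, 1.02)
  ml <- coda::mcmc.list(lapply(split(d3$`theta[1]`, d3$.chain), coda::mcmc))
  ref <- unname(coda::gelman.diag(ml)$psrf[1, 1])
  expect_lt(abs(gr3$rhat - ref), 0.01)
  # single chains are rejected
  d4 <- d3[d3$.chain == 1, ]
  expect_error(gelman_rubin(ipm_draws(d4, years = 2000:2001)), ">= 2 chains")
})

test_that("missing count years are labelled and extracted", {
  tf <- get_tiny_fit()
  imp <- impute_missing_counts(tf$fit)
  expect_equal(nrow(imp), 1)
  expect_equal(imp$year, tf$fit$years[4])
  expect_true(imp$`q2.5` < imp$median && imp$median < imp$`q97.5`)
  # a fit with no gaps yields an empty, correctly-typed table
  preset <- scenario_preset("northwest-like", n_years = 5,
                            n_nests_per_year = 10, n_releases_per_year = 20,
                            missing_years = integer())
  sc <- simulate_region(preset, seed = 12)
  cfg <- fit_config(n_chains = 2L, n_iter = 1500L, n_burnin = 1000L,
                    thin = 1L, n_adapt = 500L, seed = 3L)
  fit <- suppressWarnings(fit_ipm(sc$data, cfg))
  imp0 <- impute_missing_counts(fit)
  expect_equal(nrow(imp0), 0)
  expect_named(imp0, c("year", "mean", "sd", "q2.5", "median", "q97.5"))
})
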