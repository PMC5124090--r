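test_that("productivity is brood size discounted by stage survival", {
  # perfect survival returns the brood size unchanged
  expect_equal(productivity_fpba(6, 1, 1, 13, 13), 6)
  # half survival at each stage quarters it
  phi_half <- 0.5^(1 / 13)
  expect_equal(productivity_fpba(6, phi_half, phi_half, 13, 13), 1.5)
  # dailies re-expressing period survivals 0.71 / 0.76 recover the product
  expect_equal(
    productivity_fpba(5.78, 0.71^(1 / 13), 0.76^(1 / 13), 13, 13),
    5.78 * 0.71 * 0.76,
    tolerance = 1e-12
  )
  expect_equal(5.78 * 0.71 * 0.76, 3.119, tolerance = 1e-3)
  # zero survival with positive exposure kills productivity
  expect_equal(productivity_fpba(6, 0, 0.9, 13, 13), 0)
  expect_equal(productivity_fpba(6, 0, 0.9, 0, 13), 6 * 0.9^13)
})

test_that("productivity is monotone and invariant to exposure splitting", {
  base <- productivity_fpba(5, 0.95, 0.96, 13, 13)
  expect_gt(productivity_fpba(5.5, 0.95, 0.96, 13, 13), base)
  expect_gt(productivity_fpba(5, 0.96, 0.96, 13, 13), base)
  expect_lt(productivity_fpba(5, 0.95, 0.96, 14, 13), base)
  expect_lt(productivity_fpba(5, 0.95, 0.96, 13, 14), base)
  # phi^(a+b) equals the sequential phi^a * phi^b path
  expect_equal(
    productivity_fpba(5, 0.95, 1, 13, 0),
    productivity_fpba(5, 0.95, 1, 6, 0) / 5 *
      productivity_fpba(5, 0.95, 1, 7, 0)
  )
})

test_that("productivity rejects invalid arguments", {
  expect_error(productivity_fpba(5, 1.2, 0.9), "\\[0, 1\\]")
  expect_error(productivity_fpba(5, 0.9, -0.1), "\\[0, 1\\]")
  expect_error(productivity_fpba(5, 0.9, 0.9, ep = -1), "integer")
  expect_error(productivity_fpba(-2, 0.9, 0.9), "non-negative")
})

test_that("population step has absorbing extinction and correct expectation", {
  set.seed(1)
  z <- step_population(0, 0.5, 3, 0.4)
  expect_identical(c(z$n_a, z$n_r), c(0L, 0L))
  # pure survival: everyone lives, nobody recruits
  z <- step_population(1000, 1, 3, 0)
  expect_identical(c(z$n_a, z$n_r), c(1000L, 0L))
  # E[(N_a + N_r) / N_prev] = phi + 0.5 * F * rho
  n_reps <- 20000
  stp <- step_population(rep(1000L, n_reps), 0.45, 3.0, 0.40)
  lam <- (stp$n_a + stp$n_r) / 1000
  se <- sd(lam) / sqrt(n_reps)
  expect_lt(abs(mean(lam) - 1.05), 3 * se)
})

test_that("log-normal observation likelihood matches a density oracle", {
  expect_equal(observation_loglik(1100, 1000L, 0.1),
               dlnorm(1100, log(1000), 0.1, log = TRUE))
  # missing years contribute exactly zero
  expect_identical(observation_loglik(NA_real_, 500L, 0.1), 0)
  expect_equal(observation_loglik(c(NA, 1100), c(500L, 1000L), 0.1),
               dlnorm(1100, log(1000), 0.1, log = TRUE))
  # density peaks at the true latent size
  at_truth <- observation_loglik(1000, 1000L, 0.01)
  expect_gt(at_truth, observation_loglik(1000, 1010L, 0.01))
  expect_gt(at_truth, observation_loglik(1000, 990L, 0.01))
  # an observed count with an extinct latent state is impossible
  expect_identical(observation_loglik(5, 0L, 0.1), -Inf)
  expect_error(observation_loglik(-3, 10L, 0.1), "positive")
})

test_that("CJS likelihood reproduces hand-computed two-occasion cases", {
  m11 <- matrix(c(1L, 1L), 1)
  m10 <- matrix(c(1L, 0L), 1)
  expect_equal(cjs_loglik(m11, 0.5, 0.5), log(0.25))
  expect_equal(cjs_loglik(m10, 0.5, 0.5), log(0.75))
  # additive over independent histories
  expect_equal(cjs_loglik(rbind(m11, m10)[, , drop = FALSE], 0.5, 0.5),
               log(0.25) + log(0.75))
})

test_that("CJS likelihood equals exhaustive fate enumeration", {
  set.seed(3)
  for (tt in 2:4) {
    phi <- runif(tt - 1, 0.2, 0.9)
    p <- 0.37
    hs <- all_histories(tt)
    expect_equal(cjs_loglik(hs, phi, p), cjs_brute_force(hs, phi, p),
                 tolerance = 1e-12)
    for (i in seq_len(nrow(hs))) {
      expect_lt(abs(cjs_loglik(hs[i, , drop = FALSE], phi, p) -
                      log(cjs_brute_force_one(hs[i, ], phi, p))), 1e-10)
    }
  }
})

test_that("CJS rejects malformed histories", {
  expect_error(cjs_loglik(matrix(0L, 1, 3), runif(2), 0.5), "at least one")
  expect_error(cjs_loglik(tibble::tibble(encounter_string = "102"),
                          runif(2), 0.5), "only 0 and 1")
  expect_error(cjs_loglik(tibble::tibble(encounter_string = "10"),
                          runif(3), 0.5), "one character per study year")
})

test_that("individual CJS and m-array likelihoods agree up to constants", {
  preset <- scenario_preset("northwest-like", n_years = 6,
                            n_nests_per_year = 5, n_releases_per_year = 40)
  sc <- simulate_region(preset, seed = 11)
  h <- sc$data$histories
  ma <- build_m_array_for_test(h, 6)
  phi1 <- rep(0.5, 5); phi2 <- runif(5, 0.3, 0.7)
  d_ind <- cjs_loglik(h, phi2, 0.3) - cjs_loglik(h, phi1, 0.3)
  d_marr <- marray_loglik(ma$marr, ma$rel, phi2, 0.3) -
    marray_loglik(ma$marr, ma$rel, phi1, 0.3)
  expect_equal(d_ind, d_marr, tolerance = 1e-8)
})

test_that("nest likelihood follows the exposure-day formula", {
  rec <- tibble::tibble(region = "x", year = 2000L, brood = 0L,
                        egg_days = 10L, egg_survived = 1L,
                        chick_days = 0L, chick_survived = 0L)
  expect_equal(nest_loglik(rec, 1, 1), 0)
  # failure after 3 survived days: 4 exposure days including the failure day
  rec$egg_days <- 4L
  rec$egg_survived <- 0L
  expect_equal(nest_loglik(rec, 0.9, 0.9), 3 * log(0.9) + log(0.1))
})

test_that("nest daily-survival MLE equals the Mayfield closed form", {
  preset <- scenario_preset("northwest-like", n_years = 3,
                            n_nests_per_year = 200, n_releases_per_year = 5)
  sc <- simulate_region(preset, seed = 5)
  nests <- sc$data$nests
  egg_fail <- sum(1 - nests$egg_survived)
  egg_total <- sum(nests$egg_days)
  mayfield <- (egg_total - egg_fail) / egg_total
  mle <- optimise(function(phi) nest_loglik(nests, phi, 0.9),
                  c(0.5, 0.999999), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(mle, mayfield, tolerance = 1e-7)
})

test_that("nest records are validated", {
  bad <- tibble::tibble(region = "x", year = 2000L, brood = 0L,
                        egg_days = 0L, egg_survived = 0L,
                        chick_days = 0L, chick_survived = 0L)
  expect_error(nest_loglik(bad, 0.9, 0.9), "at least one exposure day")
  bad2 <- tibble::tibble(region = "x", year = 2000L, brood = 4L,
                         egg_days = 3L, egg_survived = 0L,
                         chick_days = 5L, chick_survived = 1L)
  expect_error(nest_loglik(bad2, 0.9, 0.9), "failed at the egg stage")
})

test_that("brood likelihood is zero-truncated Poisson", {
  rec <- tibble::tibble(region = "x", year = 2000L, brood = 5L,
                        egg_days = 13L, egg_survived = 1L,
                        chick_days = 13L, chick_survived = 1L)
  expect_equal(brood_loglik(rec, 5), log(ztp_pmf_oracle(5L, 5)))
  # empty record sets contribute nothing
  expect_identical(brood_loglik(rec[0, ], 5), 0)
  # egg-stage failures carry no brood information
  fail <- rec
  fail$egg_survived <- 0L; fail$egg_days <- 2L
  fail$chick_days <- 0L; fail$chick_survived <- 0L; fail$brood <- 0L
  expect_identical(brood_loglik(fail, 5), 0)
  rec$brood <- 5.5
  expect_error(brood_loglik(rec, 5), "integers")
})

test_that("brood MLE sits at the truncation-corrected mean", {
  set.seed(8)
  k <- 6L
  broods <- rep(k, 40)
  rec <- tibble::tibble(region = "x", year = 2000L, brood = broods,
                        egg_days = 13L, egg_survived = 1L,
                        chick_days = 13L, chick_survived = 1L)
  mle <- optimise(function(m) brood_loglik(rec, m), c(0.1, 10),
                  maximum = TRUE, tol = 1e-10)$maximum
  # independent oracle: the ZTP mean equals k at the root of m/(1-e^-m)=k
  root <- uniroot(function(m) m / (1 - exp(-m)) - k, c(1, 10),
                  tol = 1e-12)$root
  expect_equal(mle, root, tolerance = 1e-6)
  expect_lt(abs(mle - k), 0.02) # truncation correction is tiny at mean 6
})
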