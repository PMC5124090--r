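test_that("yearly parameter draws respect spreads and seeds", {
  zero_sd <- list(phi_ad = 0, brood = 0, phi_egg = 0, phi_chick = 0, rho = 0)
  preset <- scenario_preset("northwest-like", sds = zero_sd)
  p <- draw_yearly_params(preset, seed = 1)
  expect_true(all(p$phi_ad == 0.46))
  expect_true(all(p$brood_size == 5.78))
  expect_equal(unique(p$phi_egg_daily)^13, 0.71, tolerance = 1e-12)
  expect_true(all(p$rho == 0.39))
  # reproducibility under a fixed seed
  preset2 <- scenario_preset("southeast-like")
  expect_identical(draw_yearly_params(preset2, seed = 9),
                   draw_yearly_params(preset2, seed = 9))
  expect_false(identical(draw_yearly_params(preset2, seed = 9),
                         draw_yearly_params(preset2, seed = 10)))
})

test_that("drawn rates centre on the preset mean on the transformed scale", {
  preset <- scenario_preset("northwest-like", n_years = 3)
  set.seed(31)
  draws <- replicate(5000, draw_yearly_params(preset)$phi_ad)
  lg <- qlogis(draws)
  se <- sd(lg) / sqrt(length(lg))
  expect_lt(abs(mean(lg) - qlogis(0.46)), 3 * se)
})

test_that("counts equal the latent population in the noise-free limit", {
  preset <- scenario_preset("northwest-like", n_years = 6,
                            n_nests_per_year = 5, n_releases_per_year = 5,
                            sigma_obs = 1e-12, missing_years = integer())
  sc <- simulate_region(preset, seed = 2)
  expect_equal(sc$data$counts, sc$latent$n, tolerance = 1e-9)
})

test_that("zero survival and zero recruitment drive extinction from year 2", {
  zero_sd <- list(phi_ad = 0, brood = 0, phi_egg = 0, phi_chick = 0, rho = 0)
  preset <- scenario_preset("custom", n_years = 5, n_nests_per_year = 5,
                            n_releases_per_year = 5, sds = zero_sd,
                            means = list(phi_ad = 0, rho = 0),
                            missing_years = integer())
  sc <- simulate_region(preset, seed = 3)
  expect_true(sc$extinct)
  expect_true(all(sc$latent$n[-1] == 0))
  expect_equal(sc$latent$n[1], 1000)
})

test_that("realised productivity matches the drawn parameters", {
  sc <- simulate_region(scenario_preset("northwest-like"), seed = 4)
  nests <- sc$data$nests
  fledged <- ifelse(nests$chick_survived == 1, nests$brood, 0)
  # truncation of the brood distribution inflates the realised mean a touch
  tr <- tidy(sc$truth)
  expected <- mean(tr$fpba / (1 - exp(-tr$brood_size)))
  se <- sd(fledged) / sqrt(length(fledged))
  expect_lt(abs(mean(fledged) - expected), 3 * se)
})

test_that("recaptures of known survivors occur at the recapture rate", {
  # with survival pinned at 1 every post-release occasion is an independent
  # Bernoulli(p) detection of a known-alive bird
  zero_sd <- list(phi_ad = 0, brood = 0, phi_egg = 0, phi_chick = 0, rho = 0)
  preset <- scenario_preset("custom", n_years = 10, n_nests_per_year = 5,
                            n_releases_per_year = 100, sds = zero_sd,
                            means = list(phi_ad = 1, rho = 0.4))
  sc <- simulate_region(preset, seed = 6)
  enc <- ipmdemog:::encounter_matrix(sc$data$histories, 10)
  first <- attr(enc, "first")
  post <- unlist(lapply(seq_len(nrow(enc)), function(i) {
    if (first[i] < 10) enc[i, (first[i] + 1):10]
  }))
  se <- sqrt(0.25 * 0.75 / length(post))
  expect_lt(abs(mean(post) - 0.25), 3 * se)
})

test_that("count log-residuals have the configured observation spread", {
  preset <- scenario_preset("northwest-like", n_years = 150,
                            n_nests_per_year = 1, n_releases_per_year = 1,
                            missing_years = integer())
  sc <- simulate_region(preset, seed = 7)
  ok <- sc$latent$n > 0
  resid <- log(sc$data$counts[ok] / sc$latent$n[ok])
  expect_lt(abs(sd(resid) - 0.1), 3 * 0.1 / sqrt(2 * sum(ok)))
})

test_that("scenario files round-trip and flag missing years as empty", {
  dir <- withr::local_tempdir()
  sc <- simulate_region(scenario_preset("southeast-like", n_years = 8,
                                        n_nests_per_year = 20,
                                        n_releases_per_year = 20,
                                        missing_years = 4L), seed = 8)
  write_scenario(sc, dir)
  back <- read_scenario(dir)
  expect_identical(back$counts, sc$data$counts)
  expect_identical(as.data.frame(back$nests), as.data.frame(sc$data$nests))
  expect_identical(as.data.frame(back$histories),
                   as.data.frame(sc$data$histories))
  # the masked year's count field is empty, not zero
  raw <- readLines(file.path(dir, "counts.csv"))
  expect_true(any(grepl("^southeast,1997,$", raw)))
  expect_false(any(grepl(",0$", raw)))
  # the truth file names every generating parameter
  truth <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_true(all(c("phi_ad", "brood_size", "phi_egg_daily",
                    "phi_chick_daily", "rho", "sigma_obs", "p_recapture",
                    "ep", "yp") %in% names(truth$params)))
  expect_length(truth$params$phi_ad, 7)
})

test_that("MARK-style .inp histories are parsed with comments and counts", {
  f <- withr::local_tempfile(fileext = ".inp")
  writeLines(c("/* ringing site A */",
               "10100 2;",
               "01100 1; /* trailing note */",
               "00011 3;"), f)
  h <- read_inp_histories(f, years = 2000:2004, region = "test")
  expect_equal(nrow(h), 6)
  expect_equal(sum(h$encounter_string == "10100"), 2)
  expect_equal(h$first_year[h$encounter_string == "00011"], rep(2003, 3))
  # malformed strings are rejected
  f2 <- withr::local_tempfile(fileext = ".inp")
  writeLines("1021 1;", f2)
  expect_error(read_inp_histories(f2, years = 2000:2003), "Invalid encounter")
})

test_that("observed-data container enforces its invariants", {
  sc <- simulate_region(scenario_preset("northwest-like", n_years = 5,
                                        n_nests_per_year = 5,
                                        n_releases_per_year = 5), seed = 10)
  d <- sc$data
  expect_error(ipm_data(d$region, d$years, rep(NA_real_, 5), d$nests,
                        d$histories), "At least one count")
  cz <- d$counts; cz[2] <- 0
  expect_error(ipm_data(d$region, d$years, cz, d$nests, d$histories),
               "NA, not zero")
  expect_error(ipm_data(d$region, d$years[-1], d$counts[-1], d$nests,
                        d$histories), "study years|one character")
})
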