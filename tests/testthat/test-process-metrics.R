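test_that("growth rate on exact exponential data is exact and window-invariant", {
  s <- make_exp_series(mu = 0.5)
  expect_equal(fit_growth_rate(s)$rate, 0.5, tolerance = 1e-10)
  for (w in list(c(0, 2), c(1, 4), c(2.5, 6)))
    expect_equal(fit_growth_rate(s, w)$rate, 0.5, tolerance = 1e-10)
  # endpoint average equals the OLS slope on exact exponentials
  expect_equal(fit_growth_rate(s)$average_rate, 0.5, tolerance = 1e-10)
  flat <- make_exp_series(mu = 0)
  expect_equal(fit_growth_rate(flat)$rate, 0, tolerance = 1e-12)
})

test_that("growth rate estimator errors on bad input", {
  s <- make_exp_series()
  expect_error(fit_growth_rate(s, c(0, 0.6)), "3 points")
  d <- data.frame(time_h = 0:4, cdm_g_per_L = c(1, 2, 0, 4, 5),
                  glucose_g_per_L = 5, acetate_g_per_L = 0)
  expect_error(fit_growth_rate(process_series(d)), "cdm")
})

test_that("growth rate recovered from the simulator matches mu_max within 2%", {
  for (preset in c("K12_HMS_like", "K12_RV_like", "B_like")) {
    k <- strain_preset(preset)
    sim <- simulate_batch(batch_scenario(k, noise_cv = 0))
    st <- sim$state
    expo <- st$time_h >= k$lag_duration + 0.2 & st$glucose_g_per_L > 10
    fit <- fit_growth_rate(process_series(st), range(st$time_h[expo]))
    expect_lt(abs(fit$rate - k$mu_max) / k$mu_max, 0.02)
  }
})

test_that("replicate summaries reproduce known means and SEMs", {
  s <- summarize_replicates(c(13.33, 14.41, 13.43))
  expect_equal(round_report(s$mean), 13.72)
  expect_equal(round_report(s$sem), 0.34)
  s2 <- summarize_replicates(c(6.25, 6.00, 5.54))
  expect_equal(round_report(s2$mean), 5.93)
  expect_equal(round_report(s2$sem), 0.21)
  s3 <- summarize_replicates(c(5, 5, 5))
  expect_equal(s3$mean, 5)
  expect_equal(s3$sem, 0)
  expect_error(summarize_replicates(numeric()), "insufficient")
})

test_that("replicate summaries are permutation-invariant", {
  set.seed(11)
  for (i in 1:5) {
    v <- rnorm(6, 10)
    a <- summarize_replicates(v)
    b <- summarize_replicates(sample(v))
    expect_equal(a$mean, b$mean)
    expect_equal(a$sem, b$sem)
  }
})

test_that("carbon fractions match hand molar-mass computations", {
  expect_equal(carbon_fraction(elemental_composition(C = 1)), 1.0)
  # 12.011 / 24.9964 and 24.022 / 59.044, computed by hand
  expect_equal(carbon_fraction(composition_biomass()), 0.48051,
               tolerance = 1e-4)
  expect_equal(carbon_fraction(composition_acetate()), 0.40685,
               tolerance = 1e-4)
  expect_error(elemental_composition(C = 0), "C")
})

test_that("acetate-to-glucose equivalent follows homoacetate stoichiometry", {
  expect_equal(glucose_equivalent(6), 9, tolerance = 1e-3)
  expect_equal(glucose_equivalent(1.3), 1.95, tolerance = 1e-3)
  expect_equal(glucose_equivalent(0), 0)
  expect_error(glucose_equivalent(-1), "domain")
})

test_that("corrected yields reproduce the three strain benchmarks", {
  expect_equal(round_report(yield_coefficients(15.84, 40, 6)$yxs_corrected),
               0.51)
  expect_equal(round_report(yield_coefficients(17.41, 40, 1.3)$yxs_corrected),
               0.46)
  expect_equal(round_report(yield_coefficients(13.72, 40, 6)$yxs_corrected),
               0.44)
  y0 <- yield_coefficients(15, 40, 0)
  expect_equal(y0$yxs_corrected, y0$yxs_raw)
  expect_error(yield_coefficients(15, 9, 6.5), "domain")
})

test_that("corrected yield increases strictly with by-product acetate", {
  ac <- seq(0, 8, by = 1)
  y <- vapply(ac, function(a)
    yield_coefficients(14, 40, a)$yxs_corrected, numeric(1))
  expect_true(all(diff(y) > 0))
})

test_that("off-gas integration is trapezoidal and volume-scaled", {
  d <- data.frame(time_h = 0:5, cdm_g_per_L = 1, glucose_g_per_L = 5,
                  acetate_g_per_L = 0, co2_rate_gC_per_L_h = 0.8)
  expect_equal(integrate_offgas(process_series(d, volume = 4)),
               0.8 * 5 * 4)
  sim <- simulate_batch(batch_scenario(strain_preset("K12_HMS_like"),
                                       noise_cv = 0))
  got <- integrate_offgas(process_series(sim$state, volume = 4))
  want <- sim$state$co2_cum_gC_per_L[nrow(sim$state)] * 4
  expect_lt(abs(got - want) / want, 1e-3)
  d$co2_rate_gC_per_L_h <- NA_real_
  expect_error(integrate_offgas(process_series(d)), "missing data")
})

test_that("carbon balance percentages are consistent shares of the input", {
  # biomass pool of 32.81 g defined as 59.68% fixes the input carbon;
  # a CO2 pool of 16.16 g must then be 29.40%
  total <- 100 * 32.81 / 59.68
  cdm_end <- 32.81 / (4 * carbon_fraction(composition_biomass()))
  d <- data.frame(time_h = 0:4, cdm_g_per_L = cdm_end, glucose_g_per_L = 0,
                  acetate_g_per_L = 0, co2_rate_gC_per_L_h = 16.16 / 16)
  cb <- carbon_balance(process_series(d, volume = 4), total)
  expect_equal(round_report(cb$pools_pct[["biomass"]]), 59.68)
  expect_equal(cb$pools_pct[["co2"]], 29.40, tolerance = 5e-4)
  expect_equal(cb$recovery, sum(cb$pools_pct))
})

test_that("zero metabolite concentrations leave only biomass and CO2 pools", {
  d <- data.frame(time_h = 0:4, cdm_g_per_L = 10, glucose_g_per_L = 0,
                  acetate_g_per_L = 0, co2_rate_gC_per_L_h = 1)
  cb <- carbon_balance(process_series(d, volume = 4), 40)
  nz <- names(cb$pools_g)[cb$pools_g > 0]
  expect_setequal(nz, c("biomass", "co2"))
  expect_error(carbon_balance(process_series(d), 0), "domain")
})

test_that("recovery scales linearly with the reciprocal input carbon", {
  sim <- simulate_batch(batch_scenario(strain_preset("B_like"),
                                       noise_cv = 0))
  s <- process_series(sim$state, volume = 4)
  r1 <- carbon_balance(s, 50)$recovery
  r2 <- carbon_balance(s, 100)$recovery
  expect_equal(r1, 2 * r2, tolerance = 1e-12)
})

test_that("noiseless simulations close their carbon balance at 100%", {
  for (preset in c("K12_HMS_like", "B_like")) {
    sim <- simulate_batch(batch_scenario(strain_preset(preset),
                                         noise_cv = 0))
    st <- sim$state
    sc <- sim$scenario
    consumed <- (sc$S0 - st$glucose_g_per_L[nrow(st)]) * sc$volume
    total <- consumed * carbon_fraction(composition_glucose()) +
      sc$X0 * sc$volume * carbon_fraction(composition_biomass())
    cb <- carbon_balance(process_series(st, volume = sc$volume), total)
    expect_equal(cb$recovery, 100, tolerance = 0.5 / 100)
  }
})

test_that("process series TSV round-trips losslessly enough for analysis", {
  sim <- simulate_batch(batch_scenario(strain_preset("B_like"),
                                       noise_cv = 0.03, seed = 5))
  path <- tempfile(fileext = ".tsv")
  write_process_series(sim$measured, path)
  back <- read_process_series(path, volume = 4)
  expect_equal(back$cdm_g_per_L, sim$measured$cdm_g_per_L,
               tolerance = 1e-6)
  expect_s3_class(back, "process_series")
})
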