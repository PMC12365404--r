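test_that("forcing the zero component yields all-zero rates", {
  truth <- zoib_params(n_populations = 4, gamma0 = c(20, 20),
                       sigma_b0 = c(0.1, 0.1), sigma_u0 = c(0.1, 0.1))
  sim <- simulate_rates(sim_config(n_populations = 4, n_years = 6,
                                   spec = zoib_spec(), params = truth, seed = 2))
  expect_true(all(sim$rates$donor_rate == 0))
  expect_true(all(sim$rates$recipient_rate == 0))
})

test_that("huge dispersion concentrates positive rates at mu", {
  truth <- zoib_params(n_populations = 5, beta0 = rep(qlogis(0.2), 2),
                       gamma0 = c(-20, -20), log_phi = rep(log(1e6), 2))
  sim <- simulate_rates(sim_config(n_populations = 5, n_years = 40,
                                   spec = zoib_spec(), params = truth,
                                   draw_random_effects = FALSE, seed = 3))
  y <- c(sim$rates$donor_rate, sim$rates$recipient_rate)
  expect_true(all(y > 0))
  expect_lt(sd(y), 0.002)
  expect_lt(abs(mean(y) - 0.2), 0.001)
})

test_that("the zero fraction matches the generative p within Monte Carlo error", {
  p_true <- 0.35
  truth <- zoib_params(n_populations = 25, beta0 = rep(qlogis(0.1), 2),
                       gamma0 = rep(qlogis(p_true), 2), log_phi = rep(log(10), 2))
  sim <- simulate_rates(sim_config(n_populations = 25, n_years = 200,
                                   spec = zoib_spec(), params = truth,
                                   draw_random_effects = FALSE, seed = 4))
  y <- c(sim$rates$donor_rate, sim$rates$recipient_rate)
  n <- length(y)
  expect_gte(n, 1e4)
  mc_sd <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(mean(y == 0) - p_true), 3 * mc_sd)
})

test_that("simulation is seed-deterministic and never produces rates of one", {
  cfg <- sim_config(n_populations = 7, n_years = 9, seed = 12)
  s1 <- simulate_rates(cfg)
  s2 <- simulate_rates(cfg)
  expect_identical(s1$rates, s2$rates)
  expect_identical(s1$params, s2$params)
  expect_true(all(s1$rates$donor_rate < 1 & s1$rates$recipient_rate < 1))
  s3 <- simulate_rates(sim_config(n_populations = 7, n_years = 9, seed = 13))
  expect_false(identical(s1$rates, s3$rates))
  expect_error(sim_config(n_populations = 2, n_years = 2), "seed")
})

test_that("target rates are realized exactly by integer construction", {
  rates <- data.frame(hatchery = "H", year = 2000L,
                      donor_rate = 0.10, recipient_rate = 0.25)
  f <- simulate_recovery_files(rates, recoveries_per_cell = 100)
  # 100 home-or-stray fish at donor rate 0.10: exactly 10 strays generated
  stray_rows <- f$recoveries$recovery_site == "stray sink"
  expect_equal(sum(stray_rows), 10)
  expect_equal(f$realized$donor_rate, 0.10)
  expect_equal(f$realized$recipient_rate, 0.25)  # 30/(90+30)
  expect_equal(sum(grepl("^X-", f$recoveries$tag_code)), 30)
})

test_that("round trip reproduces rates and honours the exclusion rules", {
  sim <- simulate_rates(sim_config(n_populations = 5, n_years = 4, seed = 6))
  f <- simulate_recovery_files(sim$rates, recoveries_per_cell = 400)
  run <- function(files) {
    cls <- classify_recoveries(files$recoveries, files$releases, files$rivers)
    rate_table(expand_recoveries(cls), files$rivers)
  }
  rt <- run(f)
  m <- merge(rt, f$realized, by = c("hatchery", "year"))
  expect_equal(nrow(m), nrow(f$realized))
  expect_equal(m$donor_rate.x, m$donor_rate.y)
  expect_equal(m$recipient_rate.x, m$recipient_rate.y)
  # uniform sampling fraction and tagging changes leave rates untouched
  f2 <- simulate_recovery_files(sim$rates, recoveries_per_cell = 400,
                                sampling_fraction = 0.5, tagged_fraction = 0.25)
  rt2 <- run(f2)
  expect_equal(rt2$donor_rate, rt$donor_rate)
  expect_equal(rt2$recipient_rate, rt$recipient_rate)
  # injected ambiguous and experimental fish change nothing either
  f3 <- simulate_recovery_files(sim$rates, recoveries_per_cell = 400,
                                ambiguous_per_cell = 7, n_experimental = 5)
  rt3 <- run(f3)
  expect_true(all(rt3$donor_ambiguous[rt3$donor_ambiguous > 0] > 0))
  expect_equal(rt3$donor_rate, rt$donor_rate)
  expect_equal(rt3$recipient_rate, rt$recipient_rate)
})
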