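test_that("log-linear fit recovers exact doubling and flags degenerate input", {
  s <- count_series(0:3, c(100, 200, 400, 800))
  fit <- fit_log_linear(s)
  expect_equal(fit$rate, log(2))
  expect_equal(fit$r_squared, 1)
  expect_equal(doubling_time(fit$rate), 1)

  flat <- count_series(0:3, rep(500, 4))
  ffit <- fit_log_linear(flat)
  expect_equal(ffit$rate, 0)
  expect_equal(ffit$r_squared, 0)

  expect_error(fit_log_linear(count_series(0:1, c(1, 2))), "at least 3")
  expect_error(count_series(0:2, c(10, 0, 5)), "timepoint")
})

test_that("exponential-window selection finds the linear part deterministically", {
  # pure exponential: the full range qualifies
  s <- count_series(0:7, 100 * 2^(0:7))
  expect_identical(select_exponential_window(s), c(1L, 8L))

  # exponential for 6 points then a flat plateau: window stops at point 6
  s2 <- count_series(0:9, c(100 * 2^(0:5), rep(100 * 2^5, 4)))
  expect_identical(select_exponential_window(s2), c(1L, 6L))

  expect_error(select_exponential_window(count_series(0:2, c(1, 2, 4))),
               "min_points")
  noisy <- count_series(0:4, c(100, 1000, 50, 2000, 80))
  expect_error(select_exponential_window(noisy, r2_threshold = 0.999),
               "relaxing")
})

test_that("doubling time matches the reported batch-culture range", {
  expect_equal(doubling_time(0.16), log(2) / 0.16)
  expect_true(doubling_time(0.16) > 4.2 && doubling_time(0.16) < 4.6)
  expect_error(doubling_time(0), "positive")
  expect_error(doubling_time(-1), "positive")
})

test_that("mean abundance implements both conventions and their ordering", {
  expect_equal(mean_abundance(25e6, 3.5e6, "geometric"), 9354143.467,
               tolerance = 1e-9)
  expect_equal(mean_abundance(25e6, 3.5e6, "integral"), 10935282.749,
               tolerance = 1e-9)
  expect_equal(mean_abundance(7, 7, "geometric"), 7)
  expect_equal(mean_abundance(7, 7, "integral"), 7)
  expect_error(mean_abundance(-1, 5), "positive")

  # geometric <= logarithmic (integral) mean for unequal positive endpoints,
  # both converging as the endpoints approach each other
  set.seed(1)
  for (i in 1:50) {
    x <- runif(2, 0.1, 1e7)
    if (x[1] == x[2]) next
    expect_lt(mean_abundance(x[1], x[2], "geometric"),
              mean_abundance(x[1], x[2], "integral"))
  }
  expect_equal(mean_abundance(1000, 1000 + 1e-8, "integral"), 1000,
               tolerance = 1e-6)
})

test_that("grazing estimate reproduces the worked batch-culture arithmetic", {
  fx <- exact_exponential_pair()
  # prey decay from the printed endpoints: g = ln(25/3.5)/34
  gi <- grazing_estimate(fx$prey, fx$predator, predator_growth_rate = 0.1575,
                         mean_method_prey = "integral")
  expect_equal(gi$prey_decay_rate, 0.057826849, tolerance = 1e-8)
  expect_equal(gi$predator_mean, 14870.398, tolerance = 1e-4)
  expect_equal(gi$ingestion_rate, 42.524, tolerance = 1e-4)

  gg <- grazing_estimate(fx$prey, fx$predator, predator_growth_rate = 0.1575,
                         mean_method_prey = "geometric")
  expect_equal(gg$ingestion_rate, 36.376, tolerance = 1e-4)
  expect_equal(gg$clearance_rate, 3.889e-6, tolerance = 1e-3)

  # internal identities hold to machine precision
  for (g in list(gi, gg)) {
    expect_equal(g$ingestion_rate * g$predator_mean,
                 g$prey_decay_rate * g$prey_mean)
    expect_equal(g$clearance_rate * g$prey_mean, g$ingestion_rate)
  }

  growing <- count_series(c(0, 17, 34), c(1e6, 2e6, 4e6))
  expect_error(grazing_estimate(growing, fx$predator,
                                predator_growth_rate = 0.1575),
               "no net grazing")
  expect_error(grazing_estimate(fx$prey, fx$predator,
                                predator_growth_rate = 0,
                                mean_method_predator = "integral"),
               "positive 'predator_growth_rate'")
})

test_that("cell carbon follows the allometric volume conversion", {
  # unit volume: ESD = (6/pi)^(1/3) gives carbon = a
  esd1 <- (6 / pi)^(1 / 3)
  expect_equal(cell_carbon_from_esd(esd1), 0.216, tolerance = 1e-12)
  expect_equal(cell_carbon_from_esd(2), 0.8290772, tolerance = 1e-6)
  m <- carbon_model(coefficient_a = 0.12, exponent_b = 1)
  expect_equal(cell_carbon_from_esd(2, m), 0.12 * pi / 6 * 8)
  expect_error(cell_carbon_from_esd(-1), "positive")
  expect_error(carbon_model(coefficient_a = 0), "positive")
})

test_that("growth efficiency follows the carbon balance", {
  expect_equal(growth_efficiency(0.1, 10, predator_carbon = 100,
                                 prey_carbon = 1), 1)
  expect_equal(growth_efficiency(0.1575, 42.5, 108, 1), 0.4002353,
               tolerance = 1e-6)
  expect_equal(growth_efficiency(0, 42.5, 108, 1), 0)
  expect_error(growth_efficiency(0.1, 0, 1, 1), "positive ingestion")
})

test_that("half-life estimation inverts exact exponential decay", {
  tt <- seq(0, 520, by = 130)
  s <- count_series(tt, 8e4 * 0.5^(tt / 130))
  expect_equal(decay_half_life(s), 130)
  growing <- count_series(0:3, c(1, 2, 4, 8))
  expect_error(decay_half_life(growing), "not declining")
})

test_that("noiseless simulation round-trips the generating rates to 6+ digits", {
  p <- batch_culture_params(
    count_noise_cv = 0,
    sampling_times = c(seq(0, 34, length.out = 9),
                       seq(60, 400, length.out = 8)))
  sim <- simulate_batch_culture(p)
  exp_win <- c(1L, 9L)
  mu_hat <- fit_log_linear(sim$predator, exp_win)$rate
  g_hat <- -fit_log_linear(sim$prey, exp_win)$rate
  d_hat <- -fit_log_linear(sim$predator, c(10L, 17L))$rate
  expect_equal(mu_hat, p$predator_growth_rate, tolerance = 1e-9)
  expect_equal(g_hat, p$prey_decay_rate, tolerance = 1e-9)
  expect_equal(d_hat, p$stationary_decay_rate, tolerance = 1e-9)
  expect_equal(decay_half_life(sim$predator, c(10L, 17L)), 130,
               tolerance = 1e-9)
})

test_that("rate estimates are nearly unbiased under moderate counting noise", {
  # 9 timepoints over 34 h, CV = 0.1, many replicate cultures
  mus <- gs <- numeric(200)
  for (i in seq_len(200)) {
    p <- batch_culture_params(count_noise_cv = 0.1, seed = i)
    sim <- simulate_batch_culture(p)
    mus[i] <- fit_log_linear(sim$predator)$rate
    gs[i] <- -fit_log_linear(sim$prey)$rate
  }
  expect_lt(abs(mean(mus) - 0.16) / 0.16, 0.02)
  expect_lt(abs(mean(gs) - log(25 / 3.5) / 34) / (log(25 / 3.5) / 34), 0.02)
})
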