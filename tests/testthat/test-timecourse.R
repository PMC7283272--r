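test_that("single-exponential model evaluates correctly at its anchors", {
  expect_equal(eval_single_exponential(0, A = 5, k_obs = 0.5), 0)
  expect_equal(eval_single_exponential(1e9, A = 5, k_obs = 0.5), 5)
  expect_equal(eval_single_exponential(log(2) / 0.1, A = 2, k_obs = 0.1), 1)
  expect_error(eval_single_exponential(NaN, 5, 0.5), "non-finite")
  expect_error(eval_single_exponential(-1, 5, 0.5), ">= 0")
  expect_error(eval_single_exponential(1, -5, 0.5), "> 0")
})

test_that("burst model reduces to the single exponential when k_ss = 0", {
  tgrid <- seq(0, 100, by = 0.25)
  expect_identical(eval_burst(tgrid, A = 3, k_burst = 0.4, k_ss = 0),
                   eval_single_exponential(tgrid, A = 3, k_obs = 0.4))
  expect_equal(eval_burst(0, 2, 0.1, 0.01), 0)
})

test_that("burst steady-state slope equals A * k_ss (finite-difference oracle)", {
  A <- 8; kb <- 0.15; kss <- 9.9e-3
  # well past the burst phase the exponential is exhausted; slope from a
  # dense difference quotient must equal A * k_ss
  t <- seq(250, 350, by = 0.01)
  y <- eval_burst(t, A, kb, kss)
  slope <- diff(y) / diff(t)
  expect_equal(max(abs(slope - A * kss)), 0, tolerance = 1e-8)
})

test_that("noiseless time courses are recovered exactly by both fitters", {
  tc <- simulate_timecourse("single_turnover", times = exp_times(),
                            k_obs = 0.2, A = 3)
  f <- fit_single_exponential(tc)
  expect_lt(abs(f$amplitude_A - 3) / 3, 1e-6)
  expect_lt(abs(f$k_obs - 0.2) / 0.2, 1e-6)
  expect_lt(f$rss, 1e-12)

  # generating values as printed for the wild-type burst row
  tb <- simulate_timecourse("burst", times = burst_times(),
                            k_burst = 0.15, k_ss = 9.9e-3, A = 8)
  fb <- fit_burst(tb)
  expect_lt(abs(fb$amplitude_A - 8) / 8, 1e-6)
  expect_lt(abs(fb$k_burst - 0.15) / 0.15, 1e-6)
  expect_lt(abs(fb$k_ss - 9.9e-3) / 9.9e-3, 1e-6)
  expect_false(fb$ill_conditioned)
})

test_that("noisy time courses recover the truth within 3 standard errors", {
  tc <- simulate_timecourse("single_turnover", times = exp_times(),
                            k_obs = 0.2, A = 3, noise_sd = 0.02, seed = 42)
  f <- fit_single_exponential(tc)
  expect_lt(abs(f$amplitude_A - 3), 3 * f$se_A)
  expect_lt(abs(f$k_obs - 0.2), 3 * f$se_kobs)

  tb <- simulate_timecourse("burst", times = burst_times(),
                            k_burst = 0.15, k_ss = 9.9e-3, A = 8,
                            noise_sd = 0.03, seed = 43)
  fb <- fit_burst(tb)
  expect_lt(abs(fb$amplitude_A - 8), 3 * fb$se_A)
  expect_lt(abs(fb$k_burst - 0.15), 3 * fb$se_kburst)
  expect_lt(abs(fb$k_ss - 9.9e-3), 3 * fb$se_kss)
})

test_that("fitted RSS beats a 200x200 brute-force parameter lattice", {
  tc <- simulate_timecourse("single_turnover",
                            times = c(1, 3, 6, 10, 15, 25),
                            k_obs = 0.3, A = 2, noise_sd = 0.03, seed = 7)
  f <- fit_single_exponential(tc)
  A_grid <- seq(1, 3, length.out = 200)
  k_grid <- seq(0.05, 1, length.out = 200)
  rss_lattice <- outer(A_grid, k_grid, function(a, k) {
    vapply(seq_along(a), function(i) {
      sum((tc$data$product - a[i] * (1 - exp(-k[i] * tc$data$times)))^2)
    }, 0)
  })
  expect_gte(min(rss_lattice), f$rss)
})

test_that("rates scale inversely under uniform time rescaling", {
  for (cc in c(10, 0.1)) {
    tc1 <- simulate_timecourse("single_turnover", times = exp_times(),
                               k_obs = 0.2, A = 3)
    tc2 <- time_course(tc1$data$times * cc, tc1$data$product)
    f1 <- fit_single_exponential(tc1)
    f2 <- fit_single_exponential(tc2)
    expect_equal(f2$k_obs, f1$k_obs / cc, tolerance = 1e-6)
    expect_equal(f2$amplitude_A, f1$amplitude_A, tolerance = 1e-6)

    tb1 <- simulate_timecourse("burst", times = burst_times(),
                               k_burst = 0.15, k_ss = 9.9e-3, A = 8)
    tb2 <- time_course(tb1$data$times * cc, tb1$data$product)
    g1 <- fit_burst(tb1)
    g2 <- fit_burst(tb2)
    expect_equal(g2$k_burst, g1$k_burst / cc, tolerance = 1e-6)
    expect_equal(g2$k_ss, g1$k_ss / cc, tolerance = 1e-6)
  }
})

test_that("fitted RSS never exceeds the generating parameters' RSS", {
  for (seed in 1:20) {
    tc <- simulate_timecourse("single_turnover", times = exp_times(),
                              k_obs = 0.2, A = 3, noise_sd = 0.03,
                              seed = seed)
    f <- fit_single_exponential(tc)
    rss_truth <- sum((tc$data$product -
                        eval_single_exponential(tc$data$times, 3, 0.2))^2)
    expect_lte(f$rss, rss_truth + 1e-12)
  }
})

test_that("median k_obs error is below 5% over 200 noisy simulations", {
  rel_err <- vapply(1:200, function(seed) {
    tc <- simulate_timecourse("single_turnover", times = exp_times(),
                              k_obs = 0.2, A = 3, noise_sd = 0.03,
                              seed = seed)
    f <- fit_single_exponential(tc)
    abs(f$k_obs - 0.2) / 0.2
  }, 0)
  expect_lt(median(rel_err), 0.05)
})

test_that("single-exponential data yield a burst k_ss consistent with zero", {
  tc <- simulate_timecourse("single_turnover", times = burst_times(),
                            k_obs = 0.15, A = 8, noise_sd = 0.01, seed = 11)
  fb <- fit_burst(tc)
  expect_lt(abs(fb$k_ss), 2 * fb$se_kss)
})

test_that("inseparable burst phases are flagged as ill-conditioned", {
  tb <- simulate_timecourse("burst", times = burst_times(),
                            k_burst = 0.02, k_ss = 0.01, A = 8)
  fb <- fit_burst(tb)
  expect_true(fb$ill_conditioned)
})

test_that("band intensity converts proportionally to product concentration", {
  expect_equal(band_fraction_to_product(0, 100, 30), 0)
  expect_equal(band_fraction_to_product(100, 0, 30), 30)
  expect_equal(band_fraction_to_product(25, 75, 0.3), 0.075)
  expect_error(band_fraction_to_product(0, 0, 30), "both zero")
  expect_error(band_fraction_to_product(-1, 5, 30), ">= 0")
})

test_that("time-course validation rejects malformed inputs", {
  expect_error(time_course(c(1, 2, 3), c(1, 2, 3)), "at least 4")
  expect_error(time_course(c(1, 2, 2, 3), 1:4), "strictly increasing")
  expect_error(time_course(1:4, c(1, 2, -1, 3)), ">= 0")
  expect_error(time_course(1:4, c(1, 2, NA, 3)), "finite")
  expect_error(fit_single_exponential(time_course(1:4, rep(0, 4))),
               "product > 0")
  expect_error(fit_burst(time_course(1:5, 1:5)), "at least 6")
})
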