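test_that("saturation models hit their anchors and limits", {
  expect_equal(hyperbolic_rate(10, k_pol = 2, K_d = 10), 1)
  expect_equal(hyperbolic_rate(0, 2, 10), 0)
  expect_equal(hyperbolic_rate(1e9, 2, 10), 2, tolerance = 1e-6)
  expect_equal(quadratic_rate(0, 2, 10), 0)
  expect_equal(quadratic_rate(1e6, k_pol = 1, K_d = 10), 1, tolerance = 1e-4)
  expect_equal(quadratic_amplitude(0, 0.5, 45), 0)
  expect_error(quadratic_rate(-1, 2, 10), ">= 0")
  expect_error(quadratic_rate(1, -2, 10), ">= 0")
})

test_that("quadratic root satisfies its defining polynomial (residual oracle)", {
  set.seed(99)
  for (i in 1:200) {
    S <- runif(1, 0.1, 500)
    k_pol <- runif(1, 0.001, 5)
    K_d <- runif(1, 1, 200)
    x <- quadratic_rate(S, k_pol, K_d)
    res <- x^2 - (K_d + S + k_pol) * x + S * k_pol
    expect_lt(abs(res), 1e-10)
    # smaller root: below the vertex of the parabola
    expect_lte(x, (K_d + S + k_pol) / 2)
  }
})

test_that("quadratic and hyperbolic forms agree in the S -> 0 and S -> Inf limits", {
  k_pol <- 3; K_d <- 20
  expect_equal(quadratic_rate(1e-8, k_pol, K_d),
               hyperbolic_rate(1e-8, k_pol, K_d), tolerance = 1e-6)
  expect_equal(quadratic_rate(1e8, k_pol, K_d), k_pol, tolerance = 1e-6)
  expect_equal(hyperbolic_rate(1e8, k_pol, K_d), k_pol, tolerance = 1e-6)
})

test_that("noiseless titrations are recovered exactly in both branches", {
  # rate branch at the printed dATP/PreT values
  ts <- simulate_titration(4.6, 2.9, branch = "rate", form = "quadratic")
  kp <- fit_titration(ts, form = "quadratic", branch = "rate")
  expect_lt(abs(kp$k_pol - 4.6) / 4.6, 1e-6)
  expect_lt(abs(kp$K_d - 2.9) / 2.9, 1e-6)
  expect_identical(kp$branch, "rate")

  # hyperbolic self-consistency
  th <- simulate_titration(4.6, 2.9, branch = "rate", form = "hyperbolic")
  kh <- fit_titration(th, form = "hyperbolic", branch = "rate")
  expect_lt(abs(kh$k_pol - 4.6) / 4.6, 1e-6)
  expect_lt(abs(kh$K_d - 2.9) / 2.9, 1e-6)

  # amplitude branch at the printed analog/PreT values: constant rate,
  # binding read from the amplitudes
  ta <- simulate_titration(0.0037, 45,
                           concentrations = c(10, 25, 50, 100, 200, 400,
                                              700, 1000),
                           branch = "amplitude", A_max = 0.5)
  ka <- fit_titration(ta, branch = "amplitude")
  expect_equal(ka$k_pol, 0.0037)
  expect_lt(abs(ka$K_d - 45) / 45, 1e-6)
  expect_identical(ka$branch, "amplitude")
  expect_equal(ka$efficiency, ka$k_pol / ka$K_d)
})

test_that("the F-test classifies rate-concentration dependence correctly", {
  # constant rates + 2% noise: independent
  flat <- simulate_titration(0.0037, 45,
                             concentrations = c(10, 25, 50, 100, 200, 400,
                                                700, 1000),
                             branch = "amplitude", A_max = 0.5,
                             noise_sd = 0.02, seed = 5)
  expect_identical(test_rate_concentration_dependence(flat)$classification,
                   "independent")

  # saturating rates with K_d inside the tested range: dependent
  sat <- simulate_titration(4.6, 2.9, branch = "rate", noise_sd = 0.02,
                            seed = 6)
  expect_identical(test_rate_concentration_dependence(sat)$classification,
                   "dependent")

  # identical rates, zero noise: trivially independent
  ident <- titration_series(c(1, 2, 4, 8), rep(0.2, 4))
  res <- test_rate_concentration_dependence(ident)
  expect_identical(res$classification, "independent")

  # auto branch routes through the test
  expect_identical(fit_titration(flat, branch = "auto")$branch, "amplitude")
  expect_identical(fit_titration(sat, branch = "auto")$branch, "rate")

  expect_error(
    test_rate_concentration_dependence(
      structure(list(data = data.frame(conc = 1:3, k_obs = 1:3)),
                class = "titration_series")),
    "at least 4")
})

test_that("mean recovered k_pol over 100 noisy titrations is within 5%", {
  kpols <- vapply(1:100, function(seed) {
    ts <- simulate_titration(4.6, 2.9, branch = "rate", noise_sd = 0.05,
                             seed = seed)
    fit_titration(ts, branch = "rate")$k_pol
  }, 0)
  expect_lt(abs(mean(kpols) - 4.6) / 4.6, 0.05)
})

test_that("incorporation efficiency reproduces the printed table values", {
  # analog, favored PreT context
  expect_equal(signif(incorporation_efficiency(0.0037, 45.0), 2), 8.2e-5)
  # natural dATP, same context
  expect_equal(signif(incorporation_efficiency(4.6, 2.9), 2), 1.6)
  expect_equal(incorporation_efficiency(1, 1), 1)
  expect_error(incorporation_efficiency(1, 0), "> 0")
})

test_that("fold-difference table reproduces printed folds and is scale-invariant", {
  effs <- c(PreA = 1.8e-5, PreC = 7.6e-6, PreG = 1.0e-5, PreT = 8.2e-5)
  folds <- fold_difference_table(effs, "PreC")
  expect_identical(unname(folds["PreC"]), 1)
  expect_equal(round(unname(folds["PreT"]), 1), 10.8)
  expect_equal(round(unname(folds["PreA"]), 1), 2.4)
  expect_equal(fold_difference_table(effs * 1e3, "PreC"), folds)
  expect_error(fold_difference_table(effs, "PreX"), "not present")
})

test_that("discrimination factor matches the headline ratios and inverts", {
  expect_equal(signif(discrimination_factor(1.6, 8.2e-5), 1), 2e4)
  expect_equal(signif(discrimination_factor(2.1e-2, 1.8e-4), 1), 100)
  expect_equal(discrimination_factor(3, 3), 1)
  expect_equal(discrimination_factor(1.6, 8.2e-5) *
                 discrimination_factor(8.2e-5, 1.6), 1)
})

test_that("titration series validation rejects malformed inputs", {
  expect_error(titration_series(c(1, 2, 3), 1:3), "at least 4")
  expect_error(titration_series(c(1, 2, 2, 3), 1:4), "strictly increasing")
  expect_error(titration_series(c(-1, 1, 2, 3), 1:4), ">= 0")
  s <- titration_series(c(1, 2, 4, 8), c(0.1, 0.2, 0.3, 0.35))
  expect_error(fit_titration(s, branch = "amplitude"), "requires amplitudes")
})
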