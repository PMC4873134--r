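test_that("vapour pressure matches the published room-temperature values", {
  # cuelure and raspberry ketone, evaluated at 298.15 K (extrapolation)
  cl <- table2_cl()
  rk <- lure_antoine_params("RK")
  expect_warning(p_cl <- vapour_pressure(cl, 298.15),
                 class = "lurevp_extrapolation")
  expect_equal(signif(p_cl, 3), 7.54e-6)
  expect_equal(signif(vapour_pressure(rk, 298.15, warn_extrapolation = FALSE), 3),
               1.80e-6)
})

test_that("a flat law (B -> 0 limit) and domain errors behave", {
  # B must be positive, but a tiny B makes the law essentially flat
  flat <- antoine_params(3, 1e-9, 0, 100, 200)
  expect_equal(vapour_pressure(flat, 150), 10^3, tolerance = 1e-9)
  expect_error(antoine_params(3, -1, 0, 100, 200), class = "lurevp_domain_error")
  expect_error(antoine_params(3, 10, -150, 100, 200), class = "lurevp_domain_error")
  cl <- table2_cl()
  expect_error(vapour_pressure(cl, -10), class = "lurevp_domain_error")
  expect_error(boiling_temperature(cl, 1e12), class = "lurevp_domain_error")
  expect_error(boiling_temperature(cl, -1), class = "lurevp_domain_error")
})

test_that("boiling temperature is the exact inverse of the law", {
  simple <- antoine_params(10, 1000, 0, 50, 200)
  expect_equal(boiling_temperature(simple, 1), 100)   # 1000/10 - 0

  # round trip across all nine fixture parameter sets and many temperatures
  tab <- lure_antoine_params()
  for (i in seq_len(nrow(tab))) {
    pa <- antoine_params(tab$A[i], tab$B[i], tab$C[i],
                         tab$T_valid_low[i], tab$T_valid_high[i])
    Ts <- seq(tab$T_valid_low[i], tab$T_valid_high[i], length.out = 7)
    P <- vapour_pressure(pa, Ts)
    expect_equal(boiling_temperature(pa, P), Ts, tolerance = 1e-9)
  }

  # published value round trips through the inverse
  expect_equal(boiling_temperature(table2_cl(), 7.54e-6), 298.15,
               tolerance = 1e-3)
})

test_that("enthalpy of vaporisation matches the Clausius-Clapeyron derivative", {
  cl <- table2_cl()
  expect_equal(signif(enthalpy_of_vaporisation(cl, 298.15,
                                               warn_extrapolation = FALSE), 3),
               82.7)
  # C = 0 collapses the temperature ratio: dHvap = ln(10) B R, constant
  c0 <- antoine_params(8, 3000, 0, 300, 500)
  expect_equal(enthalpy_of_vaporisation(c0, 350),
               enthalpy_of_vaporisation(c0, 450))
  expect_equal(enthalpy_of_vaporisation(c0, 400),
               log(10) * 3000 * 8.314462 / 1000)

  # against the numerical derivative R T^2 dlnP/dT for all nine compounds
  tab <- lure_antoine_params()
  for (i in seq_len(nrow(tab))) {
    T <- mean(c(tab$T_valid_low[i], tab$T_valid_high[i]))
    pa <- antoine_params(tab$A[i], tab$B[i], tab$C[i],
                         tab$T_valid_low[i], tab$T_valid_high[i])
    numeric_h <- 8.314462 * T^2 *
      oracle_dlnp_dT(tab$A[i], tab$B[i], tab$C[i], T) / 1000
    expect_equal(enthalpy_of_vaporisation(pa, T), numeric_h,
                 tolerance = 1e-6)
  }
})

test_that("vapour pressure is monotone in temperature and sensitivity decays", {
  tab <- lure_antoine_params()
  for (i in seq_len(nrow(tab))) {
    pa <- antoine_params(tab$A[i], tab$B[i], tab$C[i],
                         tab$T_valid_low[i], tab$T_valid_high[i])
    Ts <- seq(tab$T_valid_low[i], tab$T_valid_high[i], length.out = 25)
    expect_true(all(diff(vapour_pressure(pa, Ts)) > 0))
    sens <- vapply(Ts, function(T) vp_sensitivity(pa, T), numeric(1))
    expect_true(all(diff(sens) < 0))
  }
})

test_that("sensitivity to a 1 K error matches a brute-force evaluation", {
  cl <- table2_cl()
  # direct evaluation of P at T +/- 1 from the raw law
  brute <- 100 * (oracle_antoine_p(9.32104, 4291.92, -0.998176, 588.4) -
                  oracle_antoine_p(9.32104, 4291.92, -0.998176, 586.4)) /
           (2 * oracle_antoine_p(9.32104, 4291.92, -0.998176, 587.4))
  expect_equal(vp_sensitivity(cl, 587.4), brute)
  expect_equal(round(vp_sensitivity(cl, 587.4), 1), 2.9)

  # essentially-flat law has zero sensitivity
  flat <- antoine_params(3, 1e-9, 0, 100, 200)
  expect_equal(vp_sensitivity(flat, 150), 0, tolerance = 1e-9)

  # the law is convex in T, so the forward difference exceeds the backward
  expect_gt(vp_sensitivity(cl, 550, direction = "up"),
            vp_sensitivity(cl, 550, direction = "down"))
})

test_that("relative volatility is a plain ratio of the two laws", {
  rk <- lure_antoine_params("RK")
  rkta <- lure_antoine_params("RKTA")
  expect_equal(relative_vp(rk, rk, 298.15), 1)
  expect_equal(relative_vp(rkta, rk, 298.15), 553.5, tolerance = 1e-3)
})

test_that("percent deviation averages per-point absolute deviations", {
  cl <- table2_cl()
  Ts <- seq(500, 580, length.out = 6)
  exact <- data.frame(T = Ts, P_kPa = vapour_pressure(cl, Ts))
  expect_equal(percent_deviation(exact, cl), 0)

  one <- data.frame(T = 550,
                    P_kPa = 1.01 * vapour_pressure(cl, 550))
  expect_equal(percent_deviation(one, cl), 1)

  noisy <- exact
  set.seed(42)
  noisy$P_kPa <- noisy$P_kPa * exp(rnorm(6, 0, 0.02))
  p_calc <- vapour_pressure(cl, noisy$T)
  loop <- mean(abs(noisy$P_kPa - p_calc) / p_calc) * 100
  expect_equal(percent_deviation(noisy, cl), loop)

  expect_error(percent_deviation(exact[0, ], cl),
               class = "lurevp_insufficient_data")
})

test_that("fitting recovers a generating Antoine curve from noise-free data", {
  cl <- table2_cl()
  pressures <- exp(seq(log(5), log(100), length.out = 12))
  pts <- simulate_boiling_series(cl, pressures, noise_sd = 0)
  fit <- fit_antoine(pts)
  expect_true(fit$converged)
  dlog <- log10(vapour_pressure(fit$params, pts$T, warn_extrapolation = FALSE)) -
    log10(pts$P_kPa)
  expect_lt(max(abs(dlog)), 1e-6)
  expect_lt(fit$mean_abs_pct_dev, 1e-4)
  # validity range is set by the data
  expect_equal(fit$params$T_valid_low, min(pts$T))
  expect_equal(fit$params$T_valid_high, max(pts$T))
})

test_that("three non-collinear points are interpolated exactly", {
  # three points near (but off) the cuelure law still admit an exact
  # three-parameter interpolant
  cl <- table2_cl()
  Ts <- c(500, 540, 580)
  tri <- data.frame(T = Ts,
                    P_kPa = vapour_pressure(cl, Ts) * c(1.02, 0.97, 1.01))
  fit <- fit_antoine(tri)
  expect_lt(fit$sse_logP, 1e-12)
  expect_error(fit_antoine(tri[1:2, ]), class = "lurevp_insufficient_data")
})

test_that("the fitted objective never exceeds the generating parameters'", {
  cl <- table2_cl()
  pts <- simulate_boiling_series(cl, c(0.5, 1, 2, 5, 10, 20, 50, 100),
                                 noise_sd = 0.5, seed = 11)
  fit <- fit_antoine(pts)
  sse_truth <- sum((log10(pts$P_kPa) -
                    log10(vapour_pressure(cl, pts$T,
                                          warn_extrapolation = FALSE)))^2)
  expect_lte(fit$sse_logP, sse_truth + 1e-12)
})

test_that("fitting every fixture back from its own curve reproduces it", {
  tab <- lure_antoine_params()
  for (i in seq_len(nrow(tab))) {
    pa <- antoine_params(tab$A[i], tab$B[i], tab$C[i],
                         tab$T_valid_low[i], tab$T_valid_high[i])
    Ts <- seq(tab$T_valid_low[i], tab$T_valid_high[i], length.out = 10)
    pts <- data.frame(T = Ts, P_kPa = vapour_pressure(pa, Ts))
    fit <- fit_antoine(pts)
    dlog <- log10(vapour_pressure(fit$params, Ts, warn_extrapolation = FALSE)) -
      log10(pts$P_kPa)
    expect_lt(max(abs(dlog)), 1e-6)
  }
})
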