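test_that("response probability is the treated fraction, with empty frames NA", {
  s <- response_series(times = c(0, 5, 10),
                       n_treated = c(9, 0, 5),
                       n_untreated = c(1, 0, 5))
  p <- response_probability(s)
  expect_equal(p$p, c(0.9, NA, 0.5))
})

test_that("noise-free curves are recovered exactly with the structural constraint", {
  t <- seq(0, 170, by = 5)
  p <- 0.91 - (0.91 - 0.5) * exp(-t / 15)
  fit <- fit_constrained_exponential(data.frame(time_s = t, p = p))
  expect_true(fit$converged)
  expect_equal(fit$p_max, 0.91, tolerance = 1e-6)
  expect_equal(fit$k, 15, tolerance = 1e-5)
  expect_equal(fit$A_mag, 0.41, tolerance = 1e-6)
  # the constraint is structural: p(0) = 0.5 to machine precision
  expect_identical(predict_response(fit, 0), 0.5)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
})

test_that("the identity A = p_max - 0.5 holds exactly in every fit", {
  set.seed(31)
  for (i in 1:5) {
    s <- simulate_response_series(runif(1, 0.6, 0.95), runif(1, 8, 30),
                                  n_flies = 40, seed = 300 + i)
    fit <- fit_response_series(s)
    expect_identical(fit$A_mag, fit$p_max - 0.5)
    expect_identical(predict_response(fit, 0), 0.5)
    # monotone approach to the asymptote for p_max > 0.5
    if (fit$p_max > 0.5) {
      curve <- predict_response(fit, seq(0, 300, 5))
      expect_true(all(diff(curve) > 0))
      expect_lt(abs(predict_response(fit, 1e6) - fit$p_max), 1e-12)
    }
  }
})

test_that("a series flat at 0.5 yields the degenerate constrained fit", {
  t <- seq(0, 170, 5)
  fit <- fit_constrained_exponential(data.frame(time_s = t, p = rep(0.5, length(t))))
  expect_equal(fit$p_max, 0.5)
  expect_equal(fit$A_mag, 0)
  expect_false(fit$k_identifiable)
  expect_true(fit$converged)
})

test_that("the fit objective never exceeds the generating parameters'", {
  s <- simulate_response_series(0.9, 15, n_flies = 30, seed = 77)
  pr <- mean_response_probability(s)
  fit <- fit_constrained_exponential(pr)
  obj <- function(pmax, k)
    sum((pr$p - (pmax - (pmax - 0.5) * exp(-pr$time_s / k)))^2)
  expect_lte(obj(fit$p_max, fit$k), obj(0.9, 15) + 1e-12)
})

test_that("the fit window and missing frames restrict the data used", {
  t <- seq(0, 300, by = 5)
  p <- 0.85 - 0.35 * exp(-t / 12)
  p[4] <- NA
  fit <- fit_constrained_exponential(data.frame(time_s = t, p = p))
  expect_equal(fit$n, sum(t <= 170) - 1)   # window cut plus one missing frame

  expect_error(
    fit_constrained_exponential(data.frame(time_s = c(0, 5), p = c(0.5, 0.6))),
    class = "lurevp_insufficient_data")
})

test_that("mean-then-fit averages replicates before fitting", {
  s <- simulate_response_series(0.88, 18, n_flies = 25, n_replicates = 5,
                                seed = 55)
  m <- mean_response_probability(s)
  direct <- fit_constrained_exponential(m)
  via <- fit_response_series(s, method = "mean-then-fit")
  expect_equal(via$p_max, direct$p_max)
  expect_equal(via$k, direct$k)

  per <- fit_response_series(s, method = "per-replicate")
  expect_length(per, 5)
  expect_s3_class(per[[1]], "response_fit")
})

test_that("interval disjointness separates clearly different maxima", {
  mkfit <- function(pmax, ci) {
    structure(list(p_max = pmax, ci_pmax = ci, A_mag = pmax - 0.5,
                   k = 15, ci_k = 2, r2 = 0.95, reduced_chi2 = 1e-4,
                   converged = TRUE, k_identifiable = TRUE, n = 35),
              class = "response_fit")
  }
  # CL-like vs RKTA-like published intervals are disjoint
  cmp <- compare_pmax(list(CL = mkfit(0.91, 0.01), RKTA = mkfit(0.94, 0.01)))
  expect_true(cmp$distinguishable)

  same <- compare_pmax(list(a = mkfit(0.9, 0.05), b = mkfit(0.91, 0.05)))
  expect_false(same$distinguishable)
  ident <- compare_pmax(list(a = mkfit(0.9, 0.01), b = mkfit(0.9, 0.01)))
  expect_false(ident$distinguishable)
})

test_that("confidence intervals for p_max have near-nominal coverage", {
  hits <- vapply(1:60, function(s) {
    f <- fit_response_series(simulate_response_series(0.9, 15, n_flies = 30,
                                                      seed = 4000 + s))
    abs(f$p_max - 0.9) <= f$ci_pmax
  }, logical(1))
  # binomial(60, 0.95) leaves essentially no mass below 85 percent
  expect_gte(mean(hits), 0.85)
})
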