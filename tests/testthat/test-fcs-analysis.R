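test_that("autocorrelation handles constant and alternating oracle traces", {
  # constant positive trace: zero fluctuation, G = 1 everywhere
  const <- intensity_trace(rep(3, 256), 1e-3)
  for (sch in c("direct", "multi_tau"))
    expect_true(all(abs(autocorrelate(const, sch)$g - 1) < 1e-12))

  # 2-periodic trace 2,0,2,0,...: direct-summation closed form gives
  # G(dt) = 0 and G(2 dt) = 2
  alt <- intensity_trace(rep(c(2, 0), 256), 1e-3)
  cv <- autocorrelate(alt, "direct", max_lag = 4e-3)
  expect_equal(cv$g[1], 0)
  expect_equal(cv$g[2], 2)

  # constant-zero trace: normalisation undefined
  expect_error(autocorrelate(intensity_trace(rep(0, 256), 1e-3)), "zero")
})

test_that("multi-tau equals direct summation on the binned series at every level", {
  set.seed(99)
  x <- rpois(2^14, 5) + rep(sin(seq_len(2^14) / 50) + 1, 1)
  tr <- intensity_trace(x, 1e-5)
  mt <- autocorrelate(tr, "multi_tau", m = 16)
  mu <- mean(x)
  xb <- x
  width <- 1L
  level <- 0L
  while (TRUE) {
    ks <- if (level == 0) 1:16 else 9:16
    present <- (ks * width * 1e-5) %in% mt$lags
    if (any(present)) {
      got <- mt$g[match(ks[present] * width * 1e-5, mt$lags)]
      oracle <- nucleophys:::raw_acf(xb, ks[present], mu)
      expect_equal(got, oracle, tolerance = 1e-12)
    }
    xb <- nucleophys:::bin_pairs(xb)
    width <- width * 2L
    level <- level + 1L
    if (length(xb) <= 16) break
  }
})

test_that("multi-tau agrees with the raw direct oracle within the binning bound", {
  tr <- simulate_trace(quick_spec(duration = 0.2, seed = 8))
  mt <- autocorrelate(tr)
  dir <- autocorrelate(tr, "direct", max_lag = 2000 * tr$dt)
  shared <- mt$lags[mt$lags <= 2000 * tr$dt]
  for (lag in shared) {
    k <- round(lag / tr$dt)
    width <- max(1, 2^floor(log2(max(k / 16, 1))))
    lo <- max(1, k - width); hi <- min(2000, k + width)
    local_range <- range(dir$g[lo:hi])
    tol <- (local_range[2] - local_range[1]) + 1e-6
    expect_lt(abs(mt$g[match(lag, mt$lags)] - dir$g[k]), tol + 1e-3)
  }
})

test_that("averaging replicate curves behaves as the protocol requires", {
  lags <- 10^seq(-6, -1, length.out = 30)
  cv <- model_gtau(lags, N = 2, tau_D = 1e-4)
  avg <- average_fafs(replicate(5, cv, simplify = FALSE))
  expect_equal(avg$g, cv$g)
  expect_true(all(avg$sd == 0))

  # mirror pair about 1 averages to a flat curve
  mirror <- faf_curve(lags, 2 - cv$g)
  flat <- average_fafs(list(cv, mirror))
  expect_true(all(abs(flat$g - 1) < 1e-12))

  expect_error(average_fafs(list(cv, faf_curve(lags * 2, cv$g))), "lag grid")
})

test_that("the diffusion model obeys its closed-form limits", {
  # amplitude law G(0+) = 1 + 1/N
  for (N in c(0.5, 1, 2, 5, 10)) {
    g0 <- model_gtau(1e-12, N = N, tau_D = 1e-4)$g
    expect_equal(g0 - 1, 1 / N, tolerance = 1e-7)
  }
  # tau = tau_D with s -> infinity, N = 1: G = 1 + 1/2
  expect_equal(model_gtau(1e-4, N = 1, tau_D = 1e-4, s = 1e9)$g, 1.5,
               tolerance = 1e-9)
  # two-component curve is the fraction-weighted sum of one-component curves
  lags <- 10^seq(-6, -1, length.out = 40)
  g2 <- model_gtau(lags, N = 2, tau_D = c(1e-4, 1e-2), y = c(0.5, 0.5))$g
  g_a <- model_gtau(lags, N = 2, tau_D = 1e-4)$g
  g_b <- model_gtau(lags, N = 2, tau_D = 1e-2)$g
  expect_equal(g2, (g_a + g_b) / 2, tolerance = 1e-12)
  # monotone non-increasing without triplet
  expect_true(all(diff(g2) <= 0))
  # parameter validation
  expect_error(model_gtau(lags, N = -1, tau_D = 1e-4), "N")
  expect_error(model_gtau(lags, N = 1, tau_D = -1e-4), "> 0")
  expect_error(model_gtau(lags, N = 1, tau_D = 1e-4, s = 0), "s")
})

test_that("triplet factor multiplies the fluctuation term as expected", {
  lags <- 10^seq(-7, -2, length.out = 50)
  base <- model_gtau(lags, N = 2, tau_D = 1e-4)
  trip <- model_gtau(lags, N = 2, tau_D = 1e-4,
                     triplet = list(T = 0.2, tau_T = 5e-6))
  fac <- (1 - 0.2 + 0.2 * exp(-lags / 5e-6)) / (1 - 0.2)
  expect_equal(trip$g - 1, (base$g - 1) * fac, tolerance = 1e-12)
})

test_that("noise-free inverse problems are recovered essentially exactly", {
  lags <- 10^seq(-6, 0, length.out = 60)
  fit <- fit_faf(model_gtau(lags, N = 2, tau_D = 1e-4, s = 5), 1)
  expect_lt(abs(fit$N - 2) / 2, 1e-6)
  expect_lt(abs(fit$tau_D - 1e-4) / 1e-4, 1e-6)

  lags2 <- 10^seq(-6, 0, length.out = 80)
  fit2 <- fit_faf(model_gtau(lags2, N = 2, tau_D = c(1e-4, 5e-3),
                             y = c(0.5, 0.5), s = 5), 2)
  expect_lt(abs(fit2$tau_D[1] - 1e-4) / 1e-4, 0.01)
  expect_lt(abs(fit2$tau_D[2] - 5e-3) / 5e-3, 0.01)
  expect_lt(abs(fit2$y[1] - 0.5), 0.01)

  # with a triplet term in the data and the fit
  fit3 <- fit_faf(model_gtau(lags, N = 1.5, tau_D = 2e-4,
                             triplet = list(T = 0.15, tau_T = 4e-6)),
                  1, triplet = TRUE)
  expect_lt(abs(fit3$tau_D - 2e-4) / 2e-4, 1e-3)
  expect_lt(abs(fit3$triplet$T - 0.15), 1e-3)
})

test_that("fitting contracts reject unusable curves", {
  expect_error(fit_faf(model_gtau(10^seq(-5, -3, length.out = 5), 2, 1e-4), 1),
               "10 lag")
  flat <- faf_curve(10^seq(-5, -1, length.out = 20), rep(1, 20))
  expect_error(fit_faf(flat, 1), "decay")
})

test_that("model selection follows the nested F-test contract", {
  lags <- 10^seq(-6, 0, length.out = 60)
  pure <- model_gtau(lags, N = 2, tau_D = 1e-4)
  # extra parameters cannot significantly improve a zero-residual fit
  expect_identical(select_model(pure, c(1, 2))$n_components, 1L)
  # single candidate returned unconditionally
  expect_identical(select_model(pure, 1)$n_components, 1L)
  expect_identical(select_model(pure, 2)$n_components, 2L)
  expect_error(select_model(pure, 3), "subset")
})

test_that("diffusion time / coefficient conversions are exact", {
  expect_equal(tau_to_D(2e-4, 0.2), 50)
  for (D in c(0.1, 1, 280))
    expect_equal(tau_to_D(D_to_tau(D, 0.2), 0.2), D, tolerance = 1e-14)
  # doubling w quadruples D at fixed tau_D
  expect_equal(tau_to_D(1e-3, 0.4), 4 * tau_to_D(1e-3, 0.2))
  expect_error(tau_to_D(-1, 0.2), "> 0")
  expect_error(D_to_tau(1, 0), "> 0")
})

test_that("reference-dye calibration reproduces its defining ratios", {
  expect_identical(calibrate_D(1e-4, 1e-4), 280)
  expect_equal(calibrate_D(2e-4, 1e-4), 140)
  # consistency with tau_to_D when w is set from the reference measurement
  tau_ref <- 3.5e-5
  w_implied <- sqrt(4 * 280 * tau_ref)
  expect_equal(calibrate_D(5e-4, tau_ref), tau_to_D(5e-4, w_implied),
               tolerance = 1e-12)
  expect_error(calibrate_D(-1e-4, 1e-4), "> 0")
})

test_that("characteristic D applies the slow-component rule", {
  expect_equal(characteristic_D(fake_fit(12), "nucleolus"), 12)
  expect_equal(characteristic_D(fake_fit(c(30, 3)), "nucleolus"), 3)
  expect_equal(characteristic_D(fake_fit(c(5, 5)), "nucleolus"), 5)
  # outside the nucleolus: fraction-weighted, components retained
  d <- characteristic_D(fake_fit(c(30, 3), y = c(0.25, 0.75)), "nucleoplasm")
  expect_equal(as.numeric(d), 0.25 * 30 + 0.75 * 3)
  expect_named(attr(d, "components"), c("y", "D"))
  # D must have been filled in
  f <- fake_fit(10); f$D <- NULL
  expect_error(characteristic_D(f, "nucleolus"), "tau_to_D")
})
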