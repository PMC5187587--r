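# Order-parameter and T1 extraction.

test_that("noiseless round trips recover the order parameter to 0.01", {
  cfg <- experiment_config()
  for (s in c(0.9, 0.437)) {
    fit <- fit_dipshift(simulate_dipshift(s, cfg), cfg, uncertainty = FALSE)
    expect_equal(fit$s_ch, s, tolerance = 0.01)
    expect_equal(fit$amplitude, 1, tolerance = 0.01)
  }
})

test_that("flat input yields s_ch = 0 with a warning", {
  cfg <- experiment_config()
  flat <- dephasing_curve(cfg$t1_grid_us, rep(1, cfg$n_t1_points))
  expect_warning(fit <- fit_dipshift(flat, cfg), "flat")
  expect_equal(fit$s_ch, 0)
  expect_error(fit_dipshift(dephasing_curve(c(0, 10, 20), c(1, 0.9, 0.8)),
                            cfg),
               "at least 5 points")
})

test_that("fit is invariant to uniform intensity scaling", {
  cfg <- experiment_config()
  base <- simulate_dipshift(0.7, cfg)
  set.seed(5)
  base$intensity <- base$intensity + rnorm(nrow(base), sd = 0.01)
  f1 <- fit_dipshift(base, cfg, uncertainty = FALSE)
  scaled <- dephasing_curve(base$t1_us, 10 * base$intensity)
  f2 <- fit_dipshift(scaled, cfg, uncertainty = FALSE)
  expect_equal(f2$s_ch, f1$s_ch, tolerance = 1e-6)
  expect_equal(f2$amplitude, 10 * f1$amplitude, tolerance = 1e-6)
})

test_that("reported chi2 equals the explicit sum of squared residuals", {
  cfg <- experiment_config()
  toy <- dephasing_curve(cfg$t1_grid_us[c(1, 9, 17, 25, 33)],
                         c(1.00, 0.80, 0.62, 0.81, 0.99))
  fit <- fit_dipshift(toy, cfg, uncertainty = FALSE)
  by_hand <- sum((toy$intensity - fit$fitted)^2)
  expect_equal(fit$chi2, by_hand)
  expect_equal(residuals(fit), toy$intensity - fit$fitted)
  expect_equal(coef(fit)[["s_ch"]], fit$s_ch)
})

test_that("seeded recovery grid: small bias and RMSE across noise levels", {
  # Per-cell bias is bounded everywhere; RMSE is pooled over the S_CH grid
  # per noise level, since at S_CH = 0.2 with sigma = 0.05 the single-curve
  # Fisher information (amplitude profiled out) already caps the attainable
  # sd near 0.08.
  cfg <- experiment_config()
  n_rep <- 20
  for (sigma in c(0, 0.01, 0.05)) {
    sq_err <- c()
    for (s_true in c(0.2, 0.4, 0.6, 0.8, 1.0)) {
      base <- simulate_dipshift(s_true, cfg)
      set.seed(round(1000 * s_true + 100000 * sigma))
      est <- replicate(n_rep, {
        y <- base$intensity + rnorm(nrow(base), sd = sigma)
        fit_dipshift(dephasing_curve(base$t1_us, y), cfg,
                     uncertainty = FALSE)$s_ch
      })
      expect_lt(abs(mean(est) - s_true), 0.03)
      sq_err <- c(sq_err, (est - s_true)^2)
    }
    expect_lt(sqrt(mean(sq_err)), 0.06)
  }
})

test_that("chi-square-scan uncertainty behaves like an error bar", {
  cfg <- experiment_config()
  base <- simulate_dipshift(0.5, cfg)
  # noiseless: tiny interval
  f0 <- fit_dipshift(base, cfg)
  expect_lt(as.numeric(f0$uncertainty_s_ch), 0.02)
  # uncertainty grows with noise (averaged over seeded replicates)
  mean_unc <- vapply(c(0.01, 0.03, 0.06), function(sigma) {
    set.seed(77)
    mean(replicate(8, {
      y <- base$intensity + rnorm(nrow(base), sd = sigma)
      as.numeric(fit_dipshift(dephasing_curve(base$t1_us, y), cfg,
                              uncertainty = FALSE) |>
                   estimate_uncertainty())
    }))
  }, numeric(1))
  expect_true(all(diff(mean_unc) > 0))
  # interval is truncated at the domain bound near s_ch = 1
  f1 <- fit_dipshift(simulate_dipshift(1, cfg), cfg)
  expect_lte(f1$s_ch + as.numeric(f1$uncertainty_s_ch), 1 + 1e-9)
})

test_that("T1 round trips: exact to 0.1%, scale-equivariant, plateau = M_eq", {
  delays <- c(0.1, 0.25, 0.5, 1, 2, 4, 8, 12, 16, 20)
  exact <- recovery_curve(delays, 1 * (1 - exp(-delays / 2)))
  fit <- fit_t1(exact)
  expect_equal(fit$t1_seconds, 2, tolerance = 1e-3)
  expect_equal(fit$m_eq, 1, tolerance = 1e-3)
  # x10 intensities: same T1, M_eq x10
  fit10 <- fit_t1(recovery_curve(delays, 10 * exact$intensity))
  expect_equal(fit10$t1_seconds, fit$t1_seconds, tolerance = 1e-9)
  expect_equal(fit10$m_eq, 10 * fit$m_eq, tolerance = 1e-9)
  # long-delay model plateau equals fitted M_eq
  expect_equal(predict(fit, 1e6), fit$m_eq, tolerance = 1e-12)
  # noisy recovery within 5%
  set.seed(9)
  noisy <- recovery_curve(delays,
                          1 - exp(-delays / 2) + rnorm(length(delays),
                                                       sd = 0.02))
  expect_equal(fit_t1(noisy)$t1_seconds, 2, tolerance = 0.05)
  expect_error(fit_t1(recovery_curve(c(0.5, 1), c(0.2, 0.4))),
               "3 distinct delays|equal length|distinct")
  expect_error(fit_t1(recovery_curve(delays, -abs(exact$intensity))),
               "non-convergence")
})

test_that("model methods are coherent (predict, simulate, summary)", {
  cfg <- experiment_config()
  fit <- fit_dipshift(simulate_dipshift(0.8, cfg), cfg, uncertainty = FALSE)
  expect_equal(predict(fit), fit$fitted, tolerance = 1e-9)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(fit$n_points, 3L))
  expect_output(print(summary(fit)), "S_CH")
  tf <- fit_t1(recovery_curve(c(0.2, 0.7, 1.5, 3, 6, 12),
                              1 - exp(-c(0.2, 0.7, 1.5, 3, 6, 12) / 1.3)))
  expect_equal(predict(tf, tf$data$delay_s), tf$fitted, tolerance = 1e-9)
  expect_output(print(tf), "T1")
})
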