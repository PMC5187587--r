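# Spin-system representation and DIPSHIFT dephasing simulation.

test_that("dipolar coupling constant has the right magnitude and scaling", {
  # hand calculation with CODATA constants:
  # 1e-7 * 2.6752218744e8 * 6.728284e7 * 1.054571817e-34 / (1.09e-10)^3
  d <- dipolar_coupling_constant(1.09)
  expect_equal(d / (2 * pi * 1e3), 23.328, tolerance = 1e-3)
  # r^-3 scaling: doubling r divides d by exactly 8
  expect_equal(dipolar_coupling_constant(2.18), d / 8)
  # large-r limit
  expect_lt(dipolar_coupling_constant(1e6), 1e-12)
  expect_error(dipolar_coupling_constant(0), "invalid geometry")
  expect_error(dipolar_coupling_constant(-1.09), "invalid geometry")
})

test_that("geometry constructors enforce their invariants", {
  v <- ch_vector(1.09, c(0, 0, 2))
  expect_equal(sqrt(sum(v$orientation^2)), 1, tolerance = 1e-12)
  expect_error(ch_vector(1.09, c(0, 0, 0)), "zero length")
  g2 <- spin_geometry_ch2(1.09, 109.47)
  u <- g2$ch_vectors[[1]]$orientation
  w <- g2$ch_vectors[[2]]$orientation
  expect_equal(acos(sum(u * w)) * 180 / pi, 109.47, tolerance = 1e-9)
  # mismatched angle is rejected
  expect_error(
    spin_geometry(list(ch_vector(1.09, c(0, 0, 1)),
                       ch_vector(1.09, c(1, 0, 0))), hch_angle = 45),
    "invalid geometry")
})

test_that("powder schemes are normalized and isotropic", {
  for (m in c("golden-spiral", "zcw-like", "grid")) {
    p <- make_powder_scheme(4096, m)
    expect_equal(sum(p$weight), 1, tolerance = 1e-10)
    expect_true(all(p$beta >= 0 & p$beta <= pi))
    expect_true(all(p$gamma >= 0 & p$gamma < 2 * pi))
    # sphere average of P2(cos beta) is 0
    p2 <- sum(p$weight * (1.5 * cos(p$beta)^2 - 0.5))
    expect_lt(abs(p2), 1e-3)
  }
  p1 <- make_powder_scheme(1)
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$weight, 1)
  expect_error(make_powder_scheme(10, "nonsense"), "configuration error")
  expect_error(make_powder_scheme(0), "configuration error")
})

test_that("closed-form dephasing phase matches adaptive quadrature", {
  cfg <- experiment_config()
  d <- 2 * pi * 1e4 # 10 kHz
  # spec worked point
  expect_equal(
    mas_dephasing_phase(d, pi / 2, 0, 7.813, cfg$tau_r_us / 2),
    quadrature_phase(d, pi / 2, 0, 7.813, cfg$tau_r_us / 2),
    tolerance = 1e-8)
  set.seed(11)
  for (k in 1:8) {
    beta <- acos(runif(1, -1, 1)); gamma <- runif(1, 0, 2 * pi)
    t1 <- runif(1, 0, cfg$tau_r_us)
    expect_equal(mas_dephasing_phase(d, beta, gamma, 7.813, t1),
                 quadrature_phase(d, beta, gamma, 7.813, t1),
                 tolerance = 1e-8)
  }
  # limits: beta = 0 kills both angular factors; full rotor period refocuses
  expect_equal(mas_dephasing_phase(d, 0, 1.1, 7.813, 50), 0)
  expect_equal(mas_dephasing_phase(d, 0.7, 2.3, 7.813, cfg$tau_r_us), 0,
               tolerance = 1e-12)
  expect_error(mas_dephasing_phase(d, 1, 1, 7.813, cfg$tau_r_us * 1.5),
               "range error")
  expect_error(mas_dephasing_phase(d, 1, 1, 7.813, -5), "range error")
})

test_that("simulated CH curves obey normalization, refocusing and S_CH scaling", {
  cfg <- experiment_config()
  p <- make_powder_scheme(4096)
  cv <- simulate_dipshift(0.9, cfg, powder = p)
  expect_equal(cv$intensity[1], 1)
  expect_lt(abs(cv$intensity[nrow(cv)] - 1), 1e-6)
  # s_ch = 0 is flat at 1
  flat <- simulate_dipshift(0, cfg, powder = p)
  expect_equal(flat$intensity, rep(1, nrow(flat)))
  # model depends only on the product S_CH * d
  d <- dipolar_coupling_constant(1.09)
  a <- simulate_dipshift(1, cfg, powder = p, d = d)
  b <- simulate_dipshift(0.5, cfg, powder = p, d = 2 * d)
  expect_equal(a$intensity, b$intensity, tolerance = 1e-12)
  # deeper minimum at higher order parameter
  lo <- simulate_dipshift(0.5, cfg, powder = p)
  expect_gt(min(lo$intensity), min(cv$intensity))
  expect_error(simulate_dipshift(1.2, cfg), "\\[0, 1\\]")
  expect_error(simulate_dipshift(0.5, cfg, powder = p[0, ]),
               "configuration error")
})

test_that("curve depth is monotone in S_CH and powder-converged", {
  cfg <- experiment_config()
  p <- make_powder_scheme(4096)
  depth <- vapply(seq(0, 1, by = 0.1), function(s)
    1 - min(simulate_dipshift(s, cfg, powder = p)$intensity), numeric(1))
  expect_true(all(diff(depth) >= -1e-12))
  # doubling the orientation count barely moves any curve point
  p2 <- make_powder_scheme(8192)
  c1 <- simulate_dipshift(0.9, cfg, powder = p)
  c2 <- simulate_dipshift(0.9, cfg, powder = p2)
  expect_lt(max(abs(c1$intensity - c2$intensity)), 1e-3)
})

test_that("gamma-averaged curves are symmetric about tau_r/2", {
  cfg <- experiment_config()
  p <- make_powder_scheme(4096)
  for (s in c(0.4, 0.9)) {
    sig <- simulate_dipshift(s, cfg, powder = p)$intensity
    expect_lt(max(abs(sig - rev(sig))), 1e-4)
  }
})

test_that("exact CH2 curve matches the 3-spin density-matrix propagator", {
  cfg <- experiment_config()
  d_eff <- cfg$kappa * dipolar_coupling_constant(1.09)
  set.seed(21)
  for (k in 1:5) {
    aa <- c(acos(runif(1, -1, 1)), runif(1, 0, 2 * pi))
    bb <- c(acos(runif(1, -1, 1)), runif(1, 0, 2 * pi))
    for (t1 in cfg$t1_grid_us[c(7, 17, 27)]) {
      prod_formula <- cos(mas_dephasing_phase(d_eff, aa[1], aa[2], 7.813, t1)) *
        cos(mas_dephasing_phase(d_eff, bb[1], bb[2], 7.813, t1))
      oracle <- propagator_ch2_signal(d_eff, d_eff, aa, bb, 7.813, t1)
      expect_equal(prod_formula, oracle, tolerance = 1e-6)
    }
  }
})

test_that("CH2 simulation degenerates to cos^2 for coincident protons", {
  cfg <- fast_config()
  p <- make_powder_scheme(512)
  geom0 <- spin_geometry(list(ch_vector(1.09, c(0, 0, 1)),
                              ch_vector(1.09, c(0, 0, 1))), hch_angle = 0)
  ch2 <- simulate_dipshift_ch2_exact(0.8, cfg, geom0, p, n_alpha = 4)
  # cos^2(phi) powder average computed directly from the phase matrix
  d_eff <- cfg$kappa * 0.8 * dipolar_coupling_constant(1.09)
  ref <- vapply(seq_along(cfg$t1_grid_us), function(i) {
    phis <- mas_dephasing_phase(d_eff, p$beta, p$gamma, 7.813,
                                cfg$t1_grid_us[i])
    sum(p$weight * cos(phis)^2)
  }, numeric(1))
  expect_equal(ch2$intensity, ref, tolerance = 1e-10)
  # flat at s_ch = 0; wrong geometry rejected
  expect_equal(simulate_dipshift_ch2_exact(0, cfg, powder = p)$intensity,
               rep(1, cfg$n_t1_points))
  expect_error(simulate_dipshift_ch2_exact(0.5, cfg, spin_geometry_ch(), p),
               "invalid geometry")
})

test_that("effective CH2 coupling is bracketed and scales with S_CH * d", {
  cfg <- experiment_config(n_powder = 1024)
  ec <- effective_ch2_coupling(cfg)
  d1 <- dipolar_coupling_constant(1.09)
  expect_gt(ec$factor, 1.0)
  expect_lt(ec$factor, 2.0)
  # grid-scan oracle: no grid value beats the optimizer by a meaningful margin
  exact <- ec$curve_exact
  grid_res <- vapply(seq(0.8, 2.2, by = 0.02), function(f) {
    m <- simulate_dipshift(1, cfg, d = f * d1)
    sqrt(mean((m$intensity - exact$intensity)^2))
  }, numeric(1))
  expect_lte(ec$residual_l2, min(grid_res) + 1e-9)
  # both curve families depend only on S_CH * d, so the factor is unchanged
  # at a different order parameter
  # the L2-calibrated factor tracks S_CH * d approximately: the calibration
  # re-weights the curve as its depth changes, so constancy holds to ~2%
  ec_half <- effective_ch2_coupling(cfg, s_ch = 0.5)
  expect_equal(ec_half$factor, ec$factor, tolerance = 0.02)
})
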