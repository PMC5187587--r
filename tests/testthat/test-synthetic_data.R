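# Seeded synthetic-data generation.

test_that("single noiseless population passes the simulator through", {
  cfg <- experiment_config(n_powder = 1024)
  spec <- synthetic_spec(data.frame(name = "only", conformation = "twofold",
                                    s_ch = 0.8, t1_s = 3, abundance = 1,
                                    mobility = "rigid"),
                         noise_sigma = 0, seed = 4, config = cfg)
  ds <- generate_dipshift_dataset(spec, "cp-like")
  ref <- simulate_dipshift(0.8, cfg)
  expect_equal(ds$only$intensity, ref$intensity, tolerance = 1e-12)
})

test_that("identical seed and spec give identical outputs", {
  cfg <- experiment_config(n_powder = 512)
  spec <- synthetic_spec(config = cfg, seed = 17)
  d1 <- generate_dipshift_dataset(spec, "cp-like")
  d2 <- generate_dipshift_dataset(spec, "cp-like")
  expect_identical(d1, d2)
  r1 <- generate_t1_series(spec, c(0.1, 0.5, 2, 8))
  r2 <- generate_t1_series(spec, c(0.1, 0.5, 2, 8))
  expect_identical(r1, r2)
  p1 <- generate_peak_list("wild-type-like", seed = 17)
  p2 <- generate_peak_list("wild-type-like", seed = 17)
  expect_identical(p1, p2)
})

test_that("CP/DP excitation weighting follows the mobility classes", {
  cfg <- experiment_config(n_powder = 512)
  spec <- synthetic_spec(config = cfg, noise_sigma = 0)
  cp <- attr(generate_dipshift_dataset(spec, "cp-like"), "truth")
  dp <- attr(generate_dipshift_dataset(spec, "dp-like"), "truth")
  # cp-like keeps rigid at abundance, down-weights mobile by 0.2
  expect_equal(cp$weight[cp$mobility == "rigid"],
               cp$abundance[cp$mobility == "rigid"])
  expect_equal(cp$weight[cp$mobility == "mobile"],
               0.2 * cp$abundance[cp$mobility == "mobile"])
  expect_equal(dp$weight, dp$abundance)
  zero <- synthetic_spec(data.frame(name = "x", conformation = "twofold",
                                    s_ch = 0.5, t1_s = 1, abundance = 0,
                                    mobility = "rigid"), config = cfg)
  expect_error(generate_dipshift_dataset(zero, "cp-like"), "empty dataset")
})

test_that("end-to-end order-parameter recovery from a cp-like dataset", {
  cfg <- experiment_config()
  spec <- synthetic_spec(default_populations("wild-type-like"),
                         noise_sigma = 0.02, seed = 42, config = cfg)
  ds <- generate_dipshift_dataset(spec, "cp-like")
  truth <- attr(ds, "truth")
  fit2f <- fit_dipshift(ds$`xylan-twofold`, cfg, uncertainty = FALSE)
  expect_lt(abs(fit2f$s_ch - truth$s_ch[truth$name == "xylan-twofold"]),
            0.05)
})

test_that("T1 series round-trip and ordering", {
  cfg <- experiment_config(n_powder = 512)
  delays <- c(0.05, 0.15, 0.4, 1, 2.5, 6, 12, 20)
  # sigma = 0: exact recovery
  spec0 <- synthetic_spec(config = cfg, noise_sigma = 0, seed = 3)
  rec <- generate_t1_series(spec0, delays)
  truth <- attr(rec, "truth")
  for (nm in names(rec)) {
    fit <- fit_t1(rec[[nm]])
    expect_equal(fit$t1_seconds, truth$t1_s[truth$name == nm],
                 tolerance = 1e-3)
  }
  # permuting delays before generation changes nothing (stored sorted)
  rec_perm <- generate_t1_series(spec0, rev(delays))
  expect_identical(rec_perm, rec)
  # two populations with different T1 truths come out ordered
  fits <- vapply(rec, function(r) fit_t1(r)$t1_seconds, numeric(1))
  expect_equal(order(fits), order(truth$t1_s))
  expect_error(generate_t1_series(spec0, c(-1, 2, 3)), "range error")
  expect_error(generate_t1_series(spec0, c(1, 2)), "3 recovery delays")
})

test_that("genotype peak lists classify to the intended conformation", {
  # jitter 0: wild-type twofold Xn4-Xn5 peak sits exactly at (82.2, 64.3, 146.5)
  wt0 <- generate_peak_list("wild-type-like", seed = 1, jitter_sd = 0)
  p45 <- wt0[wt0$residue == "Xn" & wt0$carbon_a == 4 & wt0$carbon_b == 5 &
               wt0$context == "twofold-cell-wall", ]
  expect_equal(c(p45$sq_a, p45$sq_b, p45$dq), c(82.2, 64.3, 146.5))
  expect_equal(wt0$dq, wt0$sq_a + wt0$sq_b)
  tab <- xylan_shift_table()
  # strongest xylan peaks in wild type are twofold, in irx3 threefold
  wt <- generate_peak_list("wild-type-like", seed = 8)
  expect_equal(classify_conformation(dominant_shift_set(wt), tab)$label,
               "twofold-cell-wall")
  mut <- generate_peak_list("irx3-like", seed = 8)
  expect_equal(classify_conformation(dominant_shift_set(mut), tab)$label,
               "threefold-cell-wall")
  # generated twofold peaks match the reference predictions
  pred <- predict_inadequate_peaks(tab, default_bond_list(),
                                   "twofold-cell-wall")
  rep <- match_peaks(pred, wt[wt$context == "twofold-cell-wall", ], tol = 0.5)
  expect_equal(nrow(rep$matches), nrow(pred))
  expect_error(generate_peak_list("wild-type-like",
                                  table = tab[tab$context !=
                                                "threefold-cell-wall", ]),
               "insufficient data")
})

test_that("bundles write every file plus a truth sidecar, reproducibly", {
  dir1 <- file.path(tempdir(), "bundle_a")
  dir2 <- file.path(tempdir(), "bundle_b")
  cfg <- experiment_config(n_powder = 512)
  f1 <- write_synthetic_bundle("wild-type-like", dir1, seed = 5,
                               config = cfg)
  f2 <- write_synthetic_bundle("wild-type-like", dir2, seed = 5,
                               config = cfg)
  expect_true(all(file.exists(f1)))
  expect_true(any(grepl("truth\\.json$", f1)))
  # same seed -> identical bytes
  for (i in seq_along(f1))
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  # recovery tests read truth only from the sidecar
  truth <- jsonlite::read_json(file.path(dir1, "truth.json"),
                               simplifyVector = TRUE)
  cv <- read_curve_csv(file.path(dir1, "dipshift_xylan-twofold.csv"))
  fit <- fit_dipshift(cv, cfg, uncertainty = FALSE)
  s_true <- truth$populations$s_ch[truth$populations$name == "xylan-twofold"]
  expect_lt(abs(fit$s_ch - s_true), 0.05)
})
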