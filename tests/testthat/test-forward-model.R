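test_that("noiseless decay follows the mono-exponential model exactly", {
  # Rate chosen so R * dTE = 1 over the 16.07 ms span of the UTE echo train
  # (about 62.2 1/s): the last echo is then exactly exp(-1) of the first.
  rate <- 1000 / 16.07
  tissues <- default_tissue_table()
  tissues$joint_space_control <- tissue_spec("joint_space_control", 100, rate, 40)
  out <- noiseless_series(tissues = tissues)
  js <- roi_mask(out$phantom, "joint_space")
  s <- out$series$data
  expect_equal(mean(s[, , 5][js] / s[, , 1][js]), exp(-1), tolerance = 1e-12)

  # log S is exactly affine in TE for every tissue voxel.
  te_s <- out$series$echo_times_ms / 1000
  vox <- which(js)[1]
  y <- log(vapply(1:5, function(e) s[, , e][vox], numeric(1)))
  fit <- stats::lm(y ~ te_s)
  expect_lt(max(abs(residuals(fit))), 1e-12)
  expect_equal(unname(-coef(fit)[2]), rate, tolerance = 1e-9)
})

test_that("protocol presets reject invalid echo timing", {
  expect_error(protocol("bad", c(5, 4, 3), tr_ms = 23, flip_angle_deg = 15),
               class = "uteqmri_bad_protocol")
  expect_error(protocol("bad", c(5, 30), tr_ms = 23, flip_angle_deg = 15,
                        mode = "r2star"),
               class = "uteqmri_bad_protocol")
  # Spin-echo TEs may exceed TR spacing rules of gradient echo.
  expect_s3_class(protocol_preset("fse_r2"), "qmri_protocol")
})

test_that("Rician noise on an empty voxel has the Rayleigh mean sigma*sqrt(pi/2)", {
  # Monte-Carlo oracle: background voxels (PD = 0) are pure Rayleigh draws.
  sigma <- 5
  cfg <- phantom_config(grid_size = c(256L, 256L))
  ph <- generate_phantom(cfg, seed = 1)
  series <- simulate_series(ph, protocol_preset("cones_ute"),
                            noise_sigma = sigma, seed = 42)
  bg <- ph$label_map == 0
  draws <- c(series$data[, , 1][bg], series$data[, , 2][bg],
             series$data[, , 3][bg], series$data[, , 4][bg])
  expect_gt(length(draws), 1e5)
  expect_equal(mean(draws), sigma * sqrt(pi / 2), tolerance = 0.01)
})

test_that("magnitude series converges to the noiseless series as sigma -> 0", {
  out <- noiseless_series()
  ph <- out$phantom
  ref <- out$series$data
  dev <- vapply(c(1, 0.1, 0.01), function(s) {
    noisy <- simulate_series(ph, protocol_preset("cones_ute"),
                             noise_sigma = s, seed = 3)$data
    mean(abs(noisy - ref))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3], 0.02)
})

test_that("simulation is deterministic given the seed and series are non-negative", {
  ph <- generate_phantom(small_config(), seed = 1)
  s1 <- simulate_series(ph, protocol_preset("cartesian_mge"), 2, seed = 9)
  s2 <- simulate_series(ph, protocol_preset("cartesian_mge"), 2, seed = 9)
  expect_identical(s1$data, s2$data)
  expect_true(all(s1$data >= 0))
})

test_that("blooming void area is non-decreasing across the UTE echo train", {
  depot <- depot_spec()
  ph <- generate_phantom(small_config(depot = depot), seed = 1)
  ph0 <- generate_phantom(small_config(), seed = 1)
  p <- protocol_preset("cones_ute")
  with_spio <- simulate_series(ph, p)
  without <- simulate_series(ph0, p)
  tissue <- ph0$label_map > 0
  void <- vapply(seq_along(p$echo_times_ms), function(e) {
    sum(tissue & with_spio$data[, , e] < 0.1 * without$data[, , e])
  }, numeric(1))
  expect_true(all(diff(void) >= 0))
  expect_gt(void[length(void)], void[1])
})
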