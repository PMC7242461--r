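test_that("log-linear fit recovers every tissue rate from noiseless series", {
  # Central round trip: simulate -> fit equals the ground-truth rates to
  # machine precision, for both gradient-echo protocols.
  for (proto in c("cones_ute", "cartesian_mge")) {
    out <- noiseless_series(joint = "joint_space_spio",
                            protocol = protocol_preset(proto))
    fit <- fit_loglinear(out$series)
    for (roi in names(out$phantom$roi_codes)) {
      true_rate <- out$phantom$tissues[[as.character(out$phantom$roi_codes[[roi]])]]$r2star
      sel <- roi_mask(out$phantom, roi) & fit$valid_mask
      if (sum(sel) == 0) next  # bone decays below floor at late Cartesian TEs
      expect_equal(max(abs(fit$rate[sel] - true_rate)), 0, tolerance = 1e-8)
      expect_equal(min(fit$r_squared[sel]), 1, tolerance = 1e-8)
    }
  }
})

test_that("constant signal fits to rate zero and all-dark images yield empty masks", {
  series <- structure(list(
    data = array(50, c(8, 8, 4)),
    echo_times_ms = c(1, 5, 9, 13),
    protocol = protocol_preset("fse_r2"),
    noise_sigma = 0, seed = 1L), class = "multi_echo_series")
  fit <- fit_loglinear(series, signal_floor = 1)
  expect_equal(max(abs(fit$rate)), 0, tolerance = 1e-10)

  dark <- series
  dark$data <- array(0.1, c(8, 8, 4))
  fit_dark <- fit_loglinear(dark, signal_floor = 1)
  expect_true(all(!fit_dark$valid_mask))
})

test_that("mono-exponential fit of bi-exponential decay lands between the two rates", {
  # Direct OLS oracle on the 5-point log signal of a 50/50 mix of 300 and
  # 20 1/s components at the UTE echo times.
  te_ms <- protocol_preset("cones_ute")$echo_times_ms
  te_s <- te_ms / 1000
  s <- 100 * (0.5 * exp(-300 * te_s) + 0.5 * exp(-20 * te_s))
  oracle_rate <- -unname(coef(stats::lm(log(s) ~ te_s))[2])

  tissues <- default_tissue_table()
  tissues$joint_space_control <- tissue_spec("joint_space_control", 100,
                                             r2star = 20, r2 = 20,
                                             r2star_fast = 300,
                                             fast_fraction = 0.5)
  out <- noiseless_series(tissues = tissues)
  fit <- fit_loglinear(out$series)
  js <- roi_mask(out$phantom, "joint_space") & fit$valid_mask
  fitted <- unique(round(fit$rate[js], 9))
  expect_length(fitted, 1)
  expect_equal(fitted, oracle_rate, tolerance = 1e-6)
  expect_gt(fitted, 20 + 1)
  expect_lt(fitted, 300 - 1)
})

test_that("echo ratios follow their definitions, bounds and multiplicative identity", {
  out <- noiseless_series(joint = "joint_space_spio")
  r12 <- ratio_map(out$series, "R12")
  r15 <- ratio_map(out$series, "R15")
  r25 <- ratio_map(out$series, "R25")
  tissue <- out$phantom$label_map > 0

  # Definitional check on one voxel: S1 = 100 exp-decayed values.
  vox <- which(roi_mask(out$phantom, "joint_space"))[1]
  s1 <- out$series$data[, , 1][vox]; s5 <- out$series$data[, , 5][vox]
  expect_equal(r15$value[vox], (s1 - s5) / s1, tolerance = 1e-12)

  # Bounds: zero at no loss, approaching one at complete loss, never outside.
  for (r in list(r12, r15, r25)) {
    v <- r$value[tissue & r$valid_mask]
    expect_true(all(v >= 0 & v < 1))
  }

  # Algebraic identity: 1 - R15 = (1 - R12)(1 - R25).
  ok <- tissue & r12$valid_mask & r25$valid_mask & r15$valid_mask
  gap <- (1 - r15$value[ok]) - (1 - r12$value[ok]) * (1 - r25$value[ok])
  expect_lt(max(abs(gap)), 1e-10)

  # S1 = S5 gives a zero ratio ("zero when no signal has been lost").
  const <- structure(list(data = array(80, c(4, 4, 5)),
                          echo_times_ms = c(0.03, 4, 8.1, 12.1, 16.1),
                          protocol = protocol_preset("cones_ute"),
                          noise_sigma = 0, seed = 1L),
                     class = "multi_echo_series")
  expect_true(all(ratio_map(const, "R15")$value == 0))

  expect_error(ratio_map(out$series, "R13"), class = "uteqmri_bad_ratio_kind")
})

test_that("two-point estimate inverts the ratio and matches the full fit", {
  # R = 1 - exp(-1) over a 1 s echo spacing gives exactly 1 1/s.
  rm <- structure(list(value = matrix(1 - exp(-1), 2, 2), echo_pair = c(1L, 2L),
                       kind = "R12", valid_mask = matrix(TRUE, 2, 2),
                       echo_times_used_ms = c(0, 1000)),
                  class = "ratio_map")
  tp <- two_point_r2star(rm, c(0, 1000))
  expect_equal(unique(as.numeric(tp$rate)), 1, tolerance = 1e-12)

  # On a noiseless 64 1/s phantom the R12 inversion recovers 64 exactly and
  # the R15 inversion equals the log-linear fit to machine precision.
  out <- noiseless_series(joint = "joint_space_spio")
  js <- roi_mask(out$phantom, "joint_space")
  tp12 <- two_point_r2star(ratio_map(out$series, "R12"), out$series$echo_times_ms)
  expect_equal(max(abs(tp12$rate[js] - 64)), 0, tolerance = 1e-9)

  fit <- fit_loglinear(out$series)
  tp15 <- two_point_r2star(ratio_map(out$series, "R15"), out$series$echo_times_ms)
  ok <- fit$valid_mask & tp15$valid_mask & out$phantom$label_map > 0
  expect_lt(max(abs(tp15$rate[ok] - fit$rate[ok])), 1e-9)

  rm_bad <- rm; rm_bad$echo_times_used_ms <- c(5, 5)
  expect_error(two_point_r2star(rm_bad, c(5, 5)), class = "uteqmri_bad_input")
})

test_that("subtraction images highlight fast decay", {
  out <- noiseless_series()
  expect_error(subtraction_image(out$series, 3, 2), class = "uteqmri_bad_input")
  expect_error(subtraction_image(out$series, 1, 9), class = "uteqmri_bad_input")

  # Equal PD, different rates: the faster tissue loses more signal between
  # echoes (monotonicity of 1 - exp(-R dTE) in R).
  tissues <- default_tissue_table()
  tissues$tibial_bone <- tissue_spec("tibial_bone", 80, 300, 150)
  tissues$dorsal_muscle <- tissue_spec("dorsal_muscle", 80, 40, 29)
  out2 <- noiseless_series(tissues = tissues)
  sub <- subtraction_image(out2$series, 1, 2)
  bone <- roi_mask(out2$phantom, "tibial_bone")
  muscle <- roi_mask(out2$phantom, "dorsal_muscle")
  expect_gt(min(sub[bone]), max(sub[muscle]))

  # Defect brighter than intact bone in the subtraction iff its rate is higher.
  d_def <- mean(sub[roi_mask(out2$phantom, "defect_region")])
  expect_lt(d_def, mean(sub[bone]))  # default defect decays slower than bone
})

test_that("identical echoes subtract to a zero image", {
  out <- noiseless_series()
  s <- out$series
  s$data[, , 2] <- s$data[, , 1]
  expect_true(all(subtraction_image(s, 1, 2) == 0))
})
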