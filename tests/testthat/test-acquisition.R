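# Smooth test object (Gaussian blobs): its spectrum is negligible at the
# k-space edge, so circular (radial) and square (Cartesian) coverage carry
# the same information and the FFT oracle applies to both.
smooth_object <- function(n) {
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  100 * exp(-((rows - n * 0.45)^2 + (cols - n * 0.47)^2) / (0.015 * n^2)) +
    60 * exp(-((rows - n * 0.62)^2 + (cols - n * 0.6)^2) / (0.025 * n^2))
}

test_that("Cartesian sampling and reconstruction invert exactly (FFT oracle)", {
  n <- 64
  img <- smooth_object(n)
  tr <- trajectory_cartesian(n, fov_mm = n, te_ms = 7)
  rec <- reconstruct(sample_kspace(function(t) img + 0i, tr), tr)
  expect_lt(sqrt(mean((rec - img)^2)) / sqrt(mean(img^2)), 1e-10)
})

test_that("radial gridding matches the FFT oracle within 2% on non-decaying objects", {
  n <- 64
  img <- smooth_object(n)
  obj <- function(t) img + 0i
  tr_rad <- trajectory_radial(n, fov_mm = n)
  rec_rad <- reconstruct(sample_kspace(obj, tr_rad), tr_rad)
  expect_lt(sqrt(mean((rec_rad - img)^2)) / sqrt(mean(img^2)), 0.02)

  # No decay means no trajectory-dependent contrast: the two reconstructions
  # agree within gridding tolerance.
  tr_cart <- trajectory_cartesian(n, fov_mm = n, te_ms = 7)
  rec_cart <- reconstruct(sample_kspace(obj, tr_cart), tr_cart)
  expect_lt(sqrt(mean((rec_rad - rec_cart)^2)) / sqrt(mean(rec_cart^2)), 0.02)
})

test_that("center-out DC sample sees the object at the first echo time", {
  n <- 32
  amp <- 42
  center <- matrix(0, n, n); center[n / 2 + 1, n / 2 + 1] <- amp
  rate <- 100  # 1/s
  obj <- function(t_ms) center * exp(-rate * t_ms / 1000) + 0i
  tr <- trajectory_radial(n, fov_mm = n, te0_ms = 0.03)
  s <- sample_kspace(obj, tr)
  dc <- s[tr$kx == 0 & tr$ky == 0]
  expect_equal(unique(round(Mod(dc), 9)), round(amp * exp(-rate * 0.03e-3), 9))
})

test_that("reconstruction is deterministic and rejects or zeroes degenerate input", {
  n <- 32
  tr <- trajectory_radial(n, fov_mm = n)
  expect_error(reconstruct(complex(0), tr), class = "uteqmri_empty_samples")
  zero <- reconstruct(complex(real = rep(0, length(tr$kx))), tr)
  expect_true(all(zero == 0))
  img <- smooth_object(n)
  s <- sample_kspace(function(t) img + 0i, tr)
  expect_identical(reconstruct(s, tr), reconstruct(s, tr))
})

test_that("SPIO void area is larger in the Cartesian first echo than center-out", {
  n <- 64
  ph <- generate_phantom(small_config(depot = depot_spec()), seed = 1)
  ph0 <- generate_phantom(small_config(), seed = 1)
  fov <- n * ph$voxel_size_mm
  om <- object_model(ph); om0 <- object_model(ph0)

  tr_cart <- trajectory_cartesian(n, fov, te_ms = 7)
  tr_rad <- trajectory_radial(n, fov, te0_ms = 0.03)
  rec <- list(
    cart = reconstruct(sample_kspace(om, tr_cart), tr_cart),
    cart0 = reconstruct(sample_kspace(om0, tr_cart), tr_cart),
    rad = reconstruct(sample_kspace(om, tr_rad), tr_rad),
    rad0 = reconstruct(sample_kspace(om0, tr_rad), tr_rad)
  )
  tissue <- ph0$label_map > 0
  void_cart <- sum(tissue & rec$cart < 0.1 * rec$cart0)
  void_rad <- sum(tissue & rec$rad < 0.1 * rec$rad0)
  expect_gt(void_cart, void_rad)

  # Bone visibility: the center-out first echo retains the short-T2* bone
  # signal that the 7 ms Cartesian echo has lost (factor exp(300 * 6.97 ms)).
  bone <- roi_mask(ph0, "tibial_bone")
  expect_gte(mean(rec$rad0[bone]) / mean(rec$cart0[bone]), exp(300 * 0.00697))
})
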