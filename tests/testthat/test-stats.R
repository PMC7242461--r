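test_that("roi_summary computes mean and population SD over valid voxels", {
  ph <- generate_phantom(small_config(), seed = 1)
  js <- roi_mask(ph, "joint_space")

  m <- matrix(NA_real_, 64, 64)
  m[js] <- 64
  s <- roi_summary(m, ph)
  expect_equal(s$mean[s$roi == "joint_space"], 64)
  expect_equal(s$sd[s$roi == "joint_space"], 0)

  # Checkerboard of 60/80: mean 70, population SD 10 (direct enumeration).
  chk <- matrix(NA_real_, 64, 64)
  idx <- which(js)
  chk[idx] <- ifelse(seq_along(idx) %% 2 == 0, 60, 80)
  # enforce an even split so the enumeration is exact
  if (length(idx) %% 2 == 1) chk[idx[1]] <- NA
  vals <- chk[js]; vals <- vals[!is.na(vals)]
  expect_equal(mean(vals), 70)
  s2 <- roi_summary(chk, ph)
  expect_equal(s2$mean[s2$roi == "joint_space"], 70)
  expect_equal(s2$sd[s2$roi == "joint_space"], 10)

  # An ROI with no valid voxel is missing from the table, not zero.
  m[js] <- NA_real_
  s3 <- roi_summary(m, ph)
  expect_false("joint_space" %in% s3$roi)

  expect_error(roi_summary(matrix(1, 32, 32), ph),
               class = "uteqmri_grid_mismatch")
})

test_that("group comparison reproduces the Welch t-test and its symmetries", {
  # Identical groups: no evidence, not significant.
  same <- compare_groups(c(64, 64, 64), c(64, 64, 64))
  expect_equal(same$p_value, 1)
  expect_false(same$significant)

  # Closed-form Welch oracle for {63,64,65} vs {69,70,71}: equal variances 1,
  # t = -6 / sqrt(2/3), df = 4.
  a <- c(63, 64, 65); b <- c(69, 70, 71)
  t_oracle <- -6 / sqrt(2 / 3)
  p_oracle <- 2 * stats::pt(t_oracle, df = 4)
  cmp <- compare_groups(a, b)
  expect_equal(cmp$t_statistic, t_oracle, tolerance = 1e-12)
  expect_equal(cmp$p_value, p_oracle, tolerance = 1e-12)
  expect_lt(cmp$p_value, 0.01)
  expect_true(cmp$significant)

  # Swapping the groups negates t and leaves p unchanged.
  rev <- compare_groups(b, a)
  expect_equal(rev$t_statistic, -cmp$t_statistic)
  expect_equal(rev$p_value, cmp$p_value)

  expect_error(compare_groups(c(1), c(2, 3)),
               class = "uteqmri_too_few_replicates")
})

test_that("Welch p-values agree with an exhaustive permutation oracle", {
  # Permutation oracle: exhaustive relabelling of n=5+5 normal samples,
  # two-sided p on the Welch statistic. Approximate agreement is expected
  # for normal data.
  welch_t <- function(a, b) {
    (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
  }
  perm_p <- function(a, b) {
    pool <- c(a, b)
    n <- length(a)
    combos <- utils::combn(length(pool), n)
    t_obs <- abs(welch_t(a, b))
    t_all <- apply(combos, 2, function(ix) {
      abs(welch_t(pool[ix], pool[-ix]))
    })
    mean(t_all >= t_obs - 1e-12)
  }
  set.seed(11)
  gaps <- replicate(6, {
    a <- rnorm(5, 64, 6)
    b <- rnorm(5, 70, 6)
    abs(compare_groups(a, b)$p_value - perm_p(a, b))
  })
  expect_lt(max(gaps), 0.05)
})

test_that("replicate_study reproduces group means exactly in the noiseless limit", {
  report <- replicate_study(n_per_group = 3,
                            between_sd = c(spio = 0, control = 0),
                            noise_sigma = 0, seed = 5,
                            grid_size = c(48L, 48L))
  s <- report$summary
  m_spio <- s$mean[s$metric == "r2star_cones" & s$group == "spio"]
  m_ctrl <- s$mean[s$metric == "r2star_cones" & s$group == "control"]
  expect_equal(m_spio, 64, tolerance = 1e-8)
  expect_equal(m_ctrl, 70, tolerance = 1e-8)
  expect_equal(m_ctrl - m_spio, 6, tolerance = 1e-8)
  # Ratios increase with the relaxation rate: control decays faster.
  r15 <- s[s$metric == "R15", ]
  expect_gt(r15$mean[r15$group == "control"], r15$mean[r15$group == "spio"])
})

test_that("replicate_study is deterministic in its seed", {
  r1 <- replicate_study(n_per_group = 2, seed = 7, grid_size = c(48L, 48L))
  r2 <- replicate_study(n_per_group = 2, seed = 7, grid_size = c(48L, 48L))
  expect_identical(r1$replicates$value, r2$replicates$value)
  expect_identical(r1$comparisons$p, r2$comparisons$p)
  expect_error(replicate_study(n_per_group = 1),
               class = "uteqmri_too_few_replicates")
})
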