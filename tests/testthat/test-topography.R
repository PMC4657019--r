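centers6 <- unique(joint_grid()$freq_hz)

test_that("voxel preference finds the peak and ignores scale and offset", {
  w <- rep(0, 42L)
  # (frequency bin 3, +30 deg): azimuth block 5, entry 3
  w[(5L - 1L) * 6L + 3L] <- 1
  p <- voxel_preference(w)
  expect_equal(p$freq_bin, 3L)
  expect_equal(p$best_azimuth, 30L)
  expect_equal(p$best_frequency, centers6[3L])
  expect_false(p$tie)

  # invariance to positive scaling and additive constants
  p2 <- voxel_preference(w * 7.3)
  p3 <- voxel_preference(w + 5)
  expect_equal(p2[c("freq_bin", "azimuth_bin")], p[c("freq_bin", "azimuth_bin")])
  expect_equal(p3[c("freq_bin", "azimuth_bin")], p[c("freq_bin", "azimuth_bin")])

  # all-equal weights tie deterministically: lowest bin, most central azimuth
  pt <- voxel_preference(rep(1, 42L))
  expect_true(pt$tie)
  expect_equal(pt$freq_bin, 1L)
  expect_equal(pt$best_azimuth, 0L)
})

test_that("noise-free Gaussian tuning maps to the nearest grid point", {
  vox <- data.frame(center_frequency = 1000, center_azimuth = -60,
                    freq_bandwidth = 0.5, azimuth_bandwidth = 30,
                    gain = 1, noise_sd = 0)
  R <- tuning_to_weights(vox)
  p <- voxel_preference(R[, 1L])
  expect_equal(p$best_azimuth, -60L)
  expect_equal(p$freq_bin, which.min(abs(log2(centers6) - log2(1000))))
})

test_that("preference maps respect selection and geometry", {
  pref <- data.frame(voxel = 1:6, cf_hz = rep(centers6[2L], 6L),
                     azimuth_deg = rep(30L, 6L), freq_bin = 2L,
                     azimuth_bin = 5L, tie = FALSE)
  coords <- cbind(c(1, 1, 2, 2, 3, 3), c(1, 2, 1, 2, 1, 2))
  m <- tonotopy_map(pref, coords, dims = c(3L, 2L))
  expect_true(all(m$frequency == centers6[2L]))   # constant ground truth
  expect_true(all(m$azimuth == 30L))

  m2 <- tonotopy_map(pref, coords, dims = c(3L, 2L), selection = 1:3)
  expect_equal(sum(!is.na(m2$frequency)), 3L)     # unselected voxels absent
  expect_error(tonotopy_map(pref, coords[1:3, ], dims = c(3L, 2L)),
               "geometry")
  expect_error(tonotopy_map(pref, coords * 10, dims = c(3L, 2L)), "geometry")
})

test_that("planted two-cluster frequency layout is recovered in the map", {
  ss <- generate_sound_set(56L, 28L, 7L, seed = 61L)
  n_half <- 50L
  vox <- rbind(
    generate_voxel_tuning(n_half, seed = 62L, cf_range = c(250, 450)),
    generate_voxel_tuning(n_half, seed = 63L, cf_range = c(4000, 7000))
  )
  ds <- generate_responses(ss, vox, seed = 64L)
  tr <- ds$events$split == "train"
  fit <- ridge_solve(build_joint(ds$profiles[tr, ], ds$events$azimuth_deg[tr]),
                     ds$Y[tr, ])
  pref <- preference_table(fit)
  low_correct <- mean(pref$cf_hz[1:n_half] < 1500)
  high_correct <- mean(pref$cf_hz[(n_half + 1):(2 * n_half)] > 1500)
  expect_gte(low_correct, 0.95)
  expect_gte(high_correct, 0.95)
})

test_that("gradient angles follow the stated convention", {
  # log2(CF) increasing along the first axis: all angles 0 degrees
  ramp <- outer(1:8, 1:6, function(i, j) 2^(0.4 * i))
  g <- gradient_directions(ramp)
  expect_true(all(abs(g$angles) < 1e-9))
  expect_equal(sum(g$counts), length(g$angles))   # histogram accounts for all

  # negated ramp: all angles 180 degrees
  g2 <- gradient_directions(outer(1:8, 1:6, function(i, j) 2^(-0.4 * i)))
  expect_true(all(abs(g2$angles - 180) < 1e-9))

  # rotating the slice by 90 degrees shifts every angle by 90 degrees
  diag_ramp <- outer(1:6, 1:8, function(i, j) 2^(0.3 * i + 0.1 * j))
  rot <- t(diag_ramp)[ncol(diag_ramp):1, , drop = FALSE]
  a1 <- gradient_directions(diag_ramp)$angles
  a2 <- gradient_directions(rot)$angles
  expect_equal(sort(unique(round((a1 + 90) %% 360, 6))),
               sort(unique(round(a2, 6))))

  expect_error(gradient_directions(matrix(NA_real_, 4, 4)), "mapped")
  expect_error(gradient_directions(matrix(1000, 4, 4)), "gradient")
})

test_that("unimodal and mirror-gradient maps give one and two peaks", {
  set.seed(65L)
  # single gradient along +x with mild jitter
  base <- outer(1:12, 1:10, function(i, j) 0.35 * i)
  single <- 2^(base + matrix(stats::rnorm(120, sd = 0.02), 12L, 10L))
  g1 <- gradient_directions(single, bin_width = 20)
  circ_dist <- function(a, b) {
    d <- abs(a - b) %% 360
    pmin(d, 360 - d)
  }
  # peak within one bin of the planted 0-degree direction
  expect_lte(circ_dist(g1$peaks$angle[1L], 0), 20)

  # mirror-symmetric low-high-low pattern: peaks about 180 deg apart
  half <- outer(1:6, 1:10, function(i, j) 0.35 * i)
  mirror <- 2^(rbind(half, half[6:1, ]) +
                 matrix(stats::rnorm(120, sd = 0.02), 12L, 10L))
  g2 <- gradient_directions(mirror, bin_width = 20)
  top2 <- sort(g2$peaks$angle[1:2])
  expect_equal(abs(diff(top2)), 180, tolerance = 21)
})

test_that("azimuth distributions report strata and periphery excess", {
  set.seed(66L)
  azis <- azimuth_grid()
  pref_uniform <- data.frame(voxel = 1:700,
                             cf_hz = rep(c(500, 4000), 350L),
                             azimuth_deg = sample(rep(azis, 100L)))
  d <- azimuth_distribution(pref_uniform)
  expect_equal(d$prop_all, rep(1 / 7, 7L))
  expect_equal(sum(d$n_low), 350L)

  pref_left <- data.frame(voxel = 1:20, cf_hz = 500,
                          azimuth_deg = rep(-90L, 20L))
  expect_warning(d2 <- azimuth_distribution(pref_left), "stratum")
  expect_equal(d2$prop_all[d2$azimuth_deg == -90], 1)

  # planted 2:1 periphery excess across 6 replicates
  reps <- lapply(1:6, function(r) {
    set.seed(66L + r)
    draws <- sample(azis, 400L, replace = TRUE,
                    prob = c(2, 1, 1, 1, 1, 1, 2) / 9)
    data.frame(voxel = seq_along(draws), cf_hz = 1000, azimuth_deg = draws)
  })
  tt <- periphery_vs_center_test(reps)
  expect_true(all(tt$p_adj < 0.05))
})

test_that("laterality maps apply the left-side sign flip", {
  pref <- data.frame(voxel = 1:4, cf_hz = 1000,
                     azimuth_deg = c(30L, 30L, 0L, -60L))
  side <- c("left", "right", "left", "right")
  lm <- laterality_maps(pref, side)
  expect_equal(lm$signed_azimuth, c(-30, 30, 0, -60))
  expect_equal(as.character(lm$laterality),
               c("contra", "ipsi", "central", "contra"))
  expect_equal(attr(lm, "contra_proportion"), 2 / 3)
  expect_error(laterality_maps(pref, c("left", NA, "right", "right")),
               "side label")
  expect_error(laterality_maps(pref, side[1:2]), "side label")
})
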