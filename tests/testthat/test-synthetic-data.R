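test_that("sound sets are balanced across azimuths and reproducible", {
  ss <- generate_sound_set(56L, 28L, 7L, seed = 3L)
  expect_equal(nrow(ss$events), 84L)
  tab <- table(ss$events$split, ss$events$azimuth_deg)
  expect_true(all(tab["train", ] == 8L))
  expect_true(all(tab["test", ] == 4L))

  minimal <- generate_sound_set(7L, 7L, 7L, seed = 3L)
  tab2 <- table(minimal$events$split, minimal$events$azimuth_deg)
  expect_true(all(tab2 == 1L))

  again <- generate_sound_set(56L, 28L, 7L, seed = 3L)
  expect_identical(ss, again)
  other <- generate_sound_set(56L, 28L, 7L, seed = 4L)
  expect_false(identical(ss$profiles, other$profiles))

  expect_error(generate_sound_set(55L, 28L, 7L), "55")
  expect_error(generate_sound_set(56L, 27L, 7L), "27")
})

test_that("sound profiles live on the filterbank grid and are nonnegative", {
  ss <- generate_sound_set(14L, 7L, 7L, seed = 11L)
  expect_equal(ncol(ss$profiles), 128L)
  expect_true(all(ss$profiles >= 0))
  expect_true(all(rowSums(ss$profiles) > 0))
})

test_that("responses follow Y = W R with per-voxel Gaussian noise", {
  ss <- generate_sound_set(14L, 7L, 7L, seed = 5L)
  vox <- generate_voxel_tuning(10L, seed = 6L, noise_sd = 0)
  ds <- generate_responses(ss, vox, seed = 7L)
  expect_equal(ds$Y, unclass(ds$W_true) %*% ds$R_true, ignore_attr = TRUE)

  # doubling gain doubles noise-free responses
  vox2 <- vox
  vox2$gain <- 2
  ds2 <- generate_responses(ss, vox2, seed = 7L)
  expect_equal(ds2$Y, 2 * ds$Y)

  # same seed, same draw, including noise
  voxn <- generate_voxel_tuning(10L, seed = 6L, noise_sd = 0.3)
  a <- generate_responses(ss, voxn, seed = 8L)
  b <- generate_responses(ss, voxn, seed = 8L)
  expect_identical(a$Y, b$Y)

  expect_error(generate_responses(ss, vox[0, ], seed = 1L), "empty")
})

test_that("a voxel responds more to a sound matching its tuning peak", {
  # one voxel tuned to (1 kHz, -60 deg); one matched and one opposite sound
  vox <- data.frame(center_frequency = 1000, center_azimuth = -60,
                    freq_bandwidth = 0.5, azimuth_bandwidth = 30,
                    gain = 1, noise_sd = 0)
  logf <- log2(cochlear_centers())
  matched <- exp(-(logf - log2(1000))^2 / (2 * 0.4^2))
  opposite <- exp(-(logf - log2(6500))^2 / (2 * 0.4^2))
  events <- data.frame(sound_id = c("m", "o"), split = "train",
                       azimuth_deg = c(-60L, 90L))
  ss <- structure(list(events = events,
                       profiles = rbind(matched, opposite), seed = 1L),
                  class = "sound_set")
  ds <- generate_responses(ss, vox, seed = 1L)
  expect_gt(ds$Y["m", 1L], ds$Y["o", 1L])

  # independent oracle: evaluate the separable Gaussian tuning by hand
  grid <- joint_grid()
  r_hand <- exp(-(log2(grid$freq_hz / 1000))^2 / (2 * 0.5^2)) *
    exp(-(grid$azimuth_deg + 60)^2 / (2 * 30^2))
  expect_equal(ds$R_true[, 1L], r_hand)
})

test_that("time series are impulse responses of the HRF at event onsets", {
  ds1 <- make_single_event_dataset(beta = 1)
  hrf <- canonical_hrf(2.8)
  ts1 <- generate_timeseries(ds1, tr = 2.8, hrf = hrf, noise_sd = 0, seed = 2L)
  onset <- ts1$event_table$onset_tr[1L]
  expect_equal(ts1$values[onset + seq_along(hrf) - 1L, 1L], hrf)
  expect_true(all(ts1$values[seq_len(onset - 1L), 1L] == 0))

  # jittered onsets differ by 2, 3 or 4 TRs only
  ds <- make_small_dataset(n_train = 28L, n_test = 14L, n_voxels = 5L)
  ts <- generate_timeseries(ds, seed = 9L)
  gaps <- diff(ts$event_table$onset_tr)
  expect_true(all(gaps %in% c(2L, 3L, 4L)))

  # deterministic under a fixed seed
  ts_b <- generate_timeseries(ds, seed = 9L)
  expect_identical(ts$values, ts_b$values)
})

test_that("betas estimated from noise-free series equal the generating betas", {
  ds <- make_small_dataset(n_train = 14L, n_test = 7L, n_voxels = 6L,
                           noise_sd = 0)
  hrf <- canonical_hrf(2.8)
  ts <- generate_timeseries(ds, hrf = hrf, noise_sd = 0, seed = 3L)
  betas <- estimate_betas(ts, ts$event_table, hrf)
  expect_equal(betas[rownames(ds$Y), ], ds$Y, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("binaural generator imposes ILD and ITD exactly", {
  # no cues: channels identical
  ba0 <- generate_binaural_audio(itd_us = 0, seed = 4L)
  expect_equal(ba0$left, ba0$right, tolerance = 1e-10)

  # broadband 6 dB: interaural RMS ratio is 10^(6/20)
  ba6 <- generate_binaural_audio(ild_db_by_band = 6, seed = 4L)
  rms <- function(x) sqrt(mean(x^2))
  expect_equal(rms(ba6$left) / rms(ba6$right), 10^(6 / 20), tolerance = 1e-6)

  # 500 us delay on a 500 Hz tone: cross-correlation lag of 8 samples
  ba <- generate_binaural_audio(carrier = "tone", tone_hz = 500,
                                itd_us = 500, seed = 5L)
  lags <- -20:20
  cc <- vapply(lags, function(l) {
    n <- length(ba$left)
    idx <- (seq_len(n) + l - 1L) %% n + 1L
    sum(ba$right[idx] * ba$left)     # right lags left by the ITD
  }, numeric(1L))
  expect_equal(lags[which.max(cc)], 8L)     # 500 us at 16 kHz

  # ambiguity limit recorded; warning when an ILD band crosses it
  expect_equal(ba$ambiguous_above_hz, 1000)
  bands <- data.frame(lo_hz = 200, hi_hz = 4000, ild_db = 6)
  ba_w <- generate_binaural_audio(ild_db_by_band = bands, itd_us = 500,
                                  seed = 6L)
  expect_match(ba_w$warning, "ambiguous")

  # determinism
  expect_identical(generate_binaural_audio(seed = 7L)$left,
                   generate_binaural_audio(seed = 7L)$left)
})
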