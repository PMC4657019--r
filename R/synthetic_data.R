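#' Generate a balanced set of synthetic sounds
#'
#' Creates training and testing sound events with azimuth labels balanced
#' across the 7-position grid and a synthetic log-frequency spectral
#' profile per sound (a mixture of 1-3 Gaussian bumps in log2-frequency,
#' widths 0.3-1.5 octaves, over 180-7040 Hz). Only the time-averaged
#' spectral profile enters the encoding models, so sounds are represented
#' directly at the 128-channel filterbank grid.
#'
#' @param n_train,n_test Numbers of training and testing sounds; each must
#'   be divisible by `n_azimuths`.
#' @param n_azimuths Number of azimuth positions (default 7, the full grid).
#' @param seed Integer seed; regeneration with the same seed is identical.
#' @return An object of class `sound_set`: list with `events` (data frame:
#'   `sound_id`, `split`, `azimuth_deg`), `profiles` (sounds x 128 matrix,
#'   rows named by sound id) and `seed`.
#' @export
generate_sound_set <- function(n_train = 56L, n_test = 28L, n_azimuths = 7L,
                               seed = 1L) {
  if (n_train %% n_azimuths != 0L) {
    stop("n_train (", n_train, ") is not divisible by n_azimuths (", n_azimuths, ")")
  }
  if (n_test %% n_azimuths != 0L) {
    stop("n_test (", n_test, ") is not divisible by n_azimuths (", n_azimuths, ")")
  }
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)

  azis <- azimuth_grid()[seq_len(n_azimuths)]
  if (n_azimuths == 7L) azis <- azimuth_grid()
  n <- n_train + n_test
  events <- data.frame(
    sound_id = sprintf("snd%03d", seq_len(n)),
    split = rep(c("train", "test"), c(n_train, n_test)),
    azimuth_deg = c(sample(rep(azis, n_train / n_azimuths)),
                    sample(rep(azis, n_test / n_azimuths))),
    stringsAsFactors = FALSE
  )

  cf <- cochlear_centers()
  logf <- log2(cf)
  profiles <- matrix(0, n, length(cf), dimnames = list(events$sound_id, NULL))
  for (i in seq_len(n)) {
    n_bumps <- sample(1:3, 1L)
    centers <- stats::runif(n_bumps, min(logf) + 0.2, max(logf) - 0.2)
    widths <- stats::runif(n_bumps, 0.3, 1.5)     # SD in octaves
    amps <- stats::runif(n_bumps, 0.5, 1)
    for (b in seq_len(n_bumps)) {
      profiles[i, ] <- profiles[i, ] +
        amps[b] * exp(-(logf - centers[b])^2 / (2 * widths[b]^2))
    }
  }
  structure(list(events = events, profiles = profiles, seed = seed),
            class = "sound_set")
}

# Run code under a private RNG state: seeds, and returns a restore function.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Ground-truth voxel tuning parameters
#'
#' Draws a population of voxels with separable Gaussian tuning in
#' log2-frequency and azimuth — the tuning form the joint encoding model
#' can represent on its 6 x 7 grid.
#'
#' @param n_voxels Number of voxels.
#' @param seed Integer seed.
#' @param cf_range Range (Hz) from which center frequencies are drawn
#'   log-uniformly.
#' @param azimuth_on_grid If `TRUE` (default) center azimuths are drawn
#'   from the 7-position grid; otherwise uniformly in [-90, 90].
#' @param freq_bandwidth Gaussian SD of frequency tuning in octaves; the
#'   default 0.5 corresponds to roughly 1.2 octaves FWHM, in the range
#'   auditory fMRI studies report for voxel frequency tuning.
#' @param azimuth_bandwidth Gaussian SD of azimuth tuning in degrees
#'   (default 30, about 70 degrees FWHM — broad spatial tuning).
#' @param gain Response gain (response units).
#' @param noise_sd Response noise SD (response units).
#' @return Data frame with one row per voxel: `center_frequency`,
#'   `center_azimuth`, `freq_bandwidth`, `azimuth_bandwidth`, `gain`,
#'   `noise_sd`.
#' @export
generate_voxel_tuning <- function(n_voxels, seed = 1L,
                                  cf_range = c(180, 7040),
                                  azimuth_on_grid = TRUE,
                                  freq_bandwidth = 0.5,
                                  azimuth_bandwidth = 30,
                                  gain = 1, noise_sd = 0.1) {
  stopifnot(n_voxels >= 1L, freq_bandwidth > 0, azimuth_bandwidth > 0,
            noise_sd >= 0, cf_range[1] >= 180, cf_range[2] <= 7040)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  cf <- 2^stats::runif(n_voxels, log2(cf_range[1]), log2(cf_range[2]))
  az <- if (azimuth_on_grid) {
    sample(azimuth_grid(), n_voxels, replace = TRUE)
  } else {
    stats::runif(n_voxels, -90, 90)
  }
  data.frame(center_frequency = cf, center_azimuth = az,
             freq_bandwidth = freq_bandwidth,
             azimuth_bandwidth = azimuth_bandwidth,
             gain = gain, noise_sd = noise_sd)
}

#' Ground-truth tuning weights on the joint-model grid
#'
#' Evaluates each voxel's separable Gaussian tuning (log2-frequency x
#' azimuth) at the joint model's 6 x 7 grid and flattens it in the same
#' azimuth-major order [build_joint()] uses, yielding the true tuning
#' matrix R (42 x voxels).
#'
#' @param voxels Data frame from [generate_voxel_tuning()].
#' @return 42 x n_voxels numeric matrix.
#' @export
tuning_to_weights <- function(voxels) {
  grid <- joint_grid()
  R <- vapply(seq_len(nrow(voxels)), function(v) {
    vox <- voxels[v, ]
    vox$gain *
      exp(-(log2(grid$freq_hz / vox$center_frequency))^2 /
            (2 * vox$freq_bandwidth^2)) *
      exp(-(grid$azimuth_deg - vox$center_azimuth)^2 /
            (2 * vox$azimuth_bandwidth^2))
  }, numeric(42L))
  R
}

#' Generate synthetic voxel responses
#'
#' Builds the joint-model feature matrix of the sound set, the ground-truth
#' tuning matrix of the voxels, and the response matrix
#' `Y = W_joint %*% R_true + noise` with independent Gaussian noise of each
#' voxel's `noise_sd`.
#'
#' @param sounds A `sound_set` from [generate_sound_set()].
#' @param voxels Data frame from [generate_voxel_tuning()].
#' @param seed Integer seed for the response noise.
#' @return An object of class `synthetic_dataset`: list with `events`,
#'   `profiles`, `W_true` (joint feature matrix, all sounds), `R_true`
#'   (42 x V), `Y` (sounds x V), `voxels` and `seed`.
#' @export
generate_responses <- function(sounds, voxels, seed = 1L) {
  stopifnot(inherits(sounds, "sound_set"))
  if (is.null(voxels) || nrow(voxels) == 0L) stop("empty voxel list")
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  W <- build_joint(sounds$profiles, sounds$events$azimuth_deg)
  R <- tuning_to_weights(voxels)
  Y <- unclass(W) %*% R
  noise <- matrix(stats::rnorm(length(Y)), nrow(Y), ncol(Y))
  Y <- Y + sweep(noise, 2L, voxels$noise_sd, `*`)
  rownames(Y) <- sounds$events$sound_id
  structure(list(events = sounds$events, profiles = sounds$profiles,
                 W_true = W, R_true = R, Y = Y, voxels = voxels, seed = seed),
            class = "synthetic_dataset")
}

#' Generate event-related voxel time series
#'
#' Lays the dataset's sounds out as a jittered event-related run and builds
#' each voxel's BOLD series as the sum over events of beta times the
#' shifted HRF, plus white noise.
#'
#' @param dataset A `synthetic_dataset` (its `Y` supplies the betas).
#' @param tr Repetition time in seconds.
#' @param hrf HRF kernel sampled at TR resolution (default:
#'   [canonical_hrf()]).
#' @param jitter_trs Set of admissible inter-onset intervals in TRs.
#' @param noise_sd White-noise SD added to every voxel's series.
#' @param seed Integer seed (event order, jitter, noise).
#' @return An object of class `voxel_timeseries`: list with `values`
#'   (TRs x voxels), `tr`, `event_table` (data frame `sound_id`,
#'   `azimuth_deg`, `onset_tr`), and `hrf`.
#' @export
generate_timeseries <- function(dataset, tr = 2.8, hrf = canonical_hrf(tr),
                                jitter_trs = c(2L, 3L, 4L), noise_sd = 0,
                                seed = 1L) {
  stopifnot(inherits(dataset, "synthetic_dataset"), tr > 0,
            all(jitter_trs >= 1L))
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  n_ev <- nrow(dataset$events)
  order_idx <- sample(n_ev)
  gaps <- sample(jitter_trs, n_ev - 1L, replace = TRUE)
  onsets <- cumsum(c(3L, gaps))      # first onset after a 3-TR lead-in
  L <- length(hrf)
  n_tr <- max(onsets) + L + 3L
  V <- ncol(dataset$Y)
  values <- matrix(0, n_tr, V)
  for (e in seq_len(n_ev)) {
    rows <- onsets[e] + seq_len(L) - 1L
    values[rows, ] <- values[rows, ] + outer(hrf, dataset$Y[order_idx[e], ])
  }
  if (noise_sd > 0) {
    values <- values + matrix(stats::rnorm(length(values), sd = noise_sd),
                              n_tr, V)
  }
  event_table <- data.frame(
    sound_id = dataset$events$sound_id[order_idx],
    azimuth_deg = dataset$events$azimuth_deg[order_idx],
    onset_tr = onsets,
    stringsAsFactors = FALSE
  )
  structure(list(values = values, tr = tr, event_table = event_table,
                 hrf = hrf),
            class = "voxel_timeseries")
}

#' Generate binaural audio with imposed ILD and ITD
#'
#' Synthesizes a stereo signal whose right channel is the left channel with
#' a per-band interaural level difference and a broadband time delay
#' applied, both imposed exactly in the frequency domain. Positive ILD
#' means the left ear is louder; positive ITD means the right ear lags
#' (a source on the listener's left).
#'
#' @param carrier Either `"noise"` (white noise shaped to the filterbank
#'   band, default) or `"tone"`.
#' @param tone_hz Tone frequency when `carrier = "tone"`.
#' @param ild_db_by_band Either a single number (broadband ILD in dB), or a
#'   data frame with columns `lo_hz`, `hi_hz`, `ild_db` (0 dB outside the
#'   listed bands), or `NULL` for 0 dB.
#' @param itd_us Interaural time difference in microseconds.
#' @param fs Sampling rate (Hz).
#' @param duration_s Signal duration (seconds).
#' @param seed Integer seed for the noise carrier.
#' @return An object of class `binaural_audio`: list with `left`, `right`,
#'   `fs`, `itd_us` and `ambiguous_above_hz`, the frequency beyond which
#'   the imposed delay wraps in phase (bins above it cannot carry an
#'   unambiguous ITD); a warning string is recorded in
#'   `$warning` when an ILD band extends beyond that limit.
#' @export
generate_binaural_audio <- function(carrier = c("noise", "tone"),
                                    tone_hz = 500,
                                    ild_db_by_band = NULL, itd_us = 0,
                                    fs = 16000, duration_s = 1, seed = 1L) {
  carrier <- match.arg(carrier)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  n <- round(fs * duration_s)
  t <- seq_len(n) / fs
  left <- if (carrier == "tone") {
    sin(2 * pi * tone_hz * t)
  } else {
    x <- stats::rnorm(n)
    X <- stats::fft(x)
    f <- (seq_len(n) - 1L) * fs / n
    f <- pmin(f, fs - f)
    X[f < 180 | f > 7040] <- 0
    Re(stats::fft(X, inverse = TRUE)) / n
  }
  left <- left / max(abs(left))

  X <- stats::fft(left)
  f_signed <- (seq_len(n) - 1L) * fs / n
  conj_half <- f_signed > fs / 2
  f <- ifelse(conj_half, fs - f_signed, f_signed)

  gain <- rep(1, n)
  if (!is.null(ild_db_by_band)) {
    if (is.numeric(ild_db_by_band) && length(ild_db_by_band) == 1L) {
      gain <- rep(10^(-ild_db_by_band / 20), n)
    } else {
      stopifnot(is.data.frame(ild_db_by_band),
                all(c("lo_hz", "hi_hz", "ild_db") %in% names(ild_db_by_band)))
      for (b in seq_len(nrow(ild_db_by_band))) {
        in_band <- f >= ild_db_by_band$lo_hz[b] & f < ild_db_by_band$hi_hz[b]
        gain[in_band] <- 10^(-ild_db_by_band$ild_db[b] / 20)
      }
    }
  }
  tau <- itd_us * 1e-6
  # delay applied with the correct phase sign on the conjugate half
  phase <- -2 * pi * f * tau
  phase[conj_half] <- -phase[conj_half]
  right <- Re(stats::fft(X * gain * exp(1i * phase), inverse = TRUE)) / n

  amb_hz <- if (tau != 0) 1 / (2 * abs(tau)) else Inf
  warning_msg <- NULL
  if (!is.null(ild_db_by_band) && is.data.frame(ild_db_by_band) &&
      any(ild_db_by_band$hi_hz > amb_hz)) {
    warning_msg <- paste0("imposed ITD is phase-ambiguous above ",
                          round(amb_hz), " Hz within requested bands")
  }
  structure(list(left = left, right = right, fs = fs, itd_us = itd_us,
                 ambiguous_above_hz = amb_hz, warning = warning_msg),
            class = "binaural_audio")
}
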