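#' Short-time Fourier transform front end for cue extraction
#'
#' Complex STFT with a Hann window, used for the binaural cue analysis
#' (phase is required, so the energy-only cochlear filterbank cannot be
#' used here). Defaults: 32 ms window, 8 ms hop.
#'
#' @param x Numeric waveform.
#' @param fs Sampling rate (Hz).
#' @param window_s,hop_s Window and hop lengths in seconds.
#' @return List of class `stft`: `values` (complex, frequency bins x
#'   frames), `frequencies` (Hz), `fs`.
#' @export
stft <- function(x, fs, window_s = 0.032, hop_s = 0.008) {
  win <- round(window_s * fs)
  hop <- round(hop_s * fs)
  stopifnot(win >= 2L, hop >= 1L, length(x) >= win)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(win) / win)   # Hann
  starts <- seq(1L, length(x) - win + 1L, by = hop)
  frames <- vapply(starts, function(s) x[s + seq_len(win) - 1L] * w,
                   numeric(win))
  S <- stats::mvfft(frames)[seq_len(win %/% 2L + 1L), , drop = FALSE]
  structure(list(values = S,
                 frequencies = (seq_len(win %/% 2L + 1L) - 1L) * fs / win,
                 fs = fs),
            class = "stft")
}

check_stft_pair <- function(left_spec, right_spec) {
  stopifnot(inherits(left_spec, "stft"), inherits(right_spec, "stft"))
  if (!identical(dim(left_spec$values), dim(right_spec$values)) ||
      !isTRUE(all.equal(left_spec$frequencies, right_spec$frequencies))) {
    stop("left and right spectrograms are not on matched time-frequency grids")
  }
}

#' Interaural level difference per frequency bin
#'
#' Difference of time-averaged log-power between the ears, per STFT
#' frequency bin. Positive values mean the left ear is louder.
#'
#' @param left_spec,right_spec `stft` objects on matched grids.
#' @return Data frame: `frequency_hz`, `ild_db`.
#' @export
compute_ild <- function(left_spec, right_spec) {
  check_stft_pair(left_spec, right_spec)
  pl <- rowMeans(Mod(left_spec$values)^2)
  pr <- rowMeans(Mod(right_spec$values)^2)
  data.frame(frequency_hz = left_spec$frequencies,
             ild_db = 10 * log10(pl / pr))
}

#' Interaural time difference per frequency bin
#'
#' The interaural phase difference of each bin, aggregated over time
#' frames by a power-weighted circular mean, converted to time as
#' `itd = delta_phi / (2 * pi * f)`. Positive values mean the right ear
#' lags (source on the left). Bins whose frequency exceeds the phase
#' ambiguity limit `1 / (2 * max_itd_us)` are flagged invalid: at those
#' frequencies a physical delay up to `max_itd_us` can wrap beyond +/- pi.
#'
#' @inheritParams compute_ild
#' @param max_itd_us Largest physical delay (microseconds) the analysis
#'   should resolve unambiguously; default 800 us, just above the human
#'   free-field maximum.
#' @return Data frame: `frequency_hz`, `itd_us`, `valid`.
#' @export
compute_itd <- function(left_spec, right_spec, max_itd_us = 800) {
  check_stft_pair(left_spec, right_spec)
  cross <- rowSums(left_spec$values * Conj(right_spec$values))
  dphi <- Arg(cross)
  f <- left_spec$frequencies
  itd_us <- ifelse(f > 0, dphi / (2 * pi * f) * 1e6, NA_real_)
  valid <- f > 0 & f < 1 / (2 * max_itd_us * 1e-6)
  data.frame(frequency_hz = f, itd_us = itd_us, valid = valid)
}

#' Binaural cue spectrum of a stereo sound
#'
#' Convenience wrapper computing the per-bin ILD and ITD of one stereo
#' signal.
#'
#' @param audio A `binaural_audio` object, or a list with `left`, `right`,
#'   `fs`.
#' @inheritParams compute_itd
#' @return Data frame of class `cue_spectrum`: `frequency_hz`, `ild_db`,
#'   `itd_us`, `valid`.
#' @export
binaural_cue_spectrum <- function(audio, max_itd_us = 800) {
  sl <- stft(audio$left, audio$fs)
  sr <- stft(audio$right, audio$fs)
  ild <- compute_ild(sl, sr)
  itd <- compute_itd(sl, sr, max_itd_us)
  out <- data.frame(frequency_hz = ild$frequency_hz, ild_db = ild$ild_db,
                    itd_us = itd$itd_us, valid = itd$valid)
  class(out) <- c("cue_spectrum", "data.frame")
  out
}

#' Cue informativeness across the azimuth extremes
#'
#' For each frequency bin, subtracts the cue (ILD or ITD) of sounds
#' presented at +90 degrees from that of paired sounds at -90 degrees,
#' normalizes the per-bin mean difference by its maximum, and tests the
#' per-sound differences against zero with a one-tailed one-sample t-test
#' per bin, corrected for multiple comparisons (Bonferroni by default).
#' Positive values indicate that the cue distinguishes the extreme
#' azimuths, i.e. is informative about location.
#'
#' @param cues_minus90,cues_plus90 Lists of `cue_spectrum` objects (same
#'   length, paired by sound) for sounds at -90 and +90 degrees.
#' @param cue `"ild"` or `"itd"`.
#' @param alpha Significance level after correction.
#' @param method Correction method passed to [stats::p.adjust()].
#' @return Data frame: `frequency_hz`, `mean_diff` (raw units),
#'   `statistic` (normalized mean difference, max 1), `t_stat`, `p_value`,
#'   `p_adj`, `significant`. For ITD, bins invalid in any sound are `NA`
#'   and never significant.
#' @export
cue_informativeness <- function(cues_minus90, cues_plus90,
                                cue = c("ild", "itd"), alpha = 0.05,
                                method = "bonferroni") {
  cue <- match.arg(cue)
  n_s <- length(cues_minus90)
  if (n_s < 2L || length(cues_plus90) != n_s) {
    stop("need at least 2 paired sounds per azimuth for a variance estimate")
  }
  f <- cues_minus90[[1L]]$frequency_hz
  col <- if (cue == "ild") "ild_db" else "itd_us"
  d <- vapply(seq_len(n_s),
              function(s) cues_minus90[[s]][[col]] - cues_plus90[[s]][[col]],
              numeric(length(f)))
  if (cue == "itd") {
    valid <- Reduce(`&`, lapply(c(cues_minus90, cues_plus90), `[[`, "valid"))
    d[!valid, ] <- NA_real_
  }
  mean_d <- rowMeans(d)
  max_d <- max(mean_d, na.rm = TRUE)
  stat <- if (is.finite(max_d) && max_d > 0) mean_d / max_d else mean_d

  tt <- apply(d, 1L, function(x) {
    if (anyNA(x) || stats::sd(x) == 0) {
      # degenerate bins: no variance (or invalid); t undefined
      return(c(t = if (all(!is.na(x)) && all(x == 0)) 0 else NA_real_,
               p = NA_real_))
    }
    r <- stats::t.test(x, mu = 0, alternative = "greater")
    c(t = unname(r$statistic), p = r$p.value)
  })
  p <- tt["p", ]
  p_adj <- stats::p.adjust(p, method = method, n = sum(!is.na(p)))
  data.frame(frequency_hz = f, mean_diff = mean_d, statistic = stat,
             t_stat = tt["t", ], p_value = p, p_adj = p_adj,
             significant = !is.na(p_adj) & p_adj < alpha)
}
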