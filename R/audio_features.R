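#' Cochlear-style filterbank spectrogram
#'
#' Decomposes a sound into the energy outputs of 128 overlapping constant-Q
#' bandpass filters equally spaced along a logarithmic frequency axis
#' between 180 and 7040 Hz (5.3 octaves), mimicking the spectral
#' transformation of the auditory periphery. Filtering is performed in the
#' frequency domain with a fourth-order gammatone-like magnitude response,
#' symmetric in log-frequency; filter outputs are half-wave rectified,
#' squared, and averaged within short frames.
#'
#' @param audio Numeric vector, a mono waveform.
#' @param fs Sampling rate in Hz; must satisfy `fs >= 2 * fmax`.
#' @param n_channels Number of filterbank channels.
#' @param fmin,fmax Frequency range of the channel grid (Hz).
#' @param bw_octaves Filter bandwidth scale in octaves.
#' @param frame_s Frame length for energy averaging, in seconds.
#' @return An object of class `cochlear_spectrogram`: a list with `values`
#'   (channels x frames energy matrix, nonnegative), `center_frequencies`
#'   (Hz) and `frame_rate` (Hz).
#' @export
cochlear_filterbank <- function(audio, fs, n_channels = 128L,
                                fmin = 180, fmax = 7040,
                                bw_octaves = 0.25, frame_s = 0.008) {
  if (length(audio) == 0L) stop("empty audio input")
  if (!all(is.finite(audio))) stop("audio contains non-finite samples")
  if (fs < 2 * fmax) {
    stop("sampling rate ", fs, " Hz violates the Nyquist requirement for fmax = ",
         fmax, " Hz (need fs >= ", 2 * fmax, " Hz)")
  }
  cf <- cochlear_centers(n_channels, fmin, fmax)
  n <- length(audio)
  spec <- stats::fft(audio)
  # physical frequency of each DFT bin (mirror the upper half)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)
  logf <- ifelse(f > 0, log2(f), -Inf)

  frame_len <- max(1L, round(frame_s * fs))
  n_frames <- max(1L, n %/% frame_len)
  frame_id <- rep(seq_len(n_frames), each = frame_len, length.out = n)

  values <- matrix(0, n_channels, n_frames)
  for (k in seq_len(n_channels)) {
    h <- (1 + ((logf - log2(cf[k])) / bw_octaves)^2)^(-2)
    y <- Re(stats::fft(spec * h, inverse = TRUE)) / n
    y[y < 0] <- 0                      # half-wave rectification
    e <- y^2
    values[k, ] <- as.numeric(tapply(e, frame_id, mean))
  }
  structure(list(values = values, center_frequencies = cf,
                 frame_rate = fs / frame_len),
            class = "cochlear_spectrogram")
}

#' Time-averaged spectral profile
#'
#' Averages a cochlear spectrogram over time frames, yielding the
#' per-channel energy profile that all encoding-model feature spaces are
#' built from.
#'
#' @param spec A `cochlear_spectrogram`.
#' @return Numeric vector (one value per channel) with attribute
#'   `frequencies` holding the channel center frequencies.
#' @export
time_average <- function(spec) {
  stopifnot(inherits(spec, "cochlear_spectrogram"))
  if (ncol(spec$values) < 1L) stop("spectrogram has no time frames")
  p <- rowMeans(spec$values)
  attr(p, "frequencies") <- spec$center_frequencies
  p
}

#' Average a spectral profile into octave-spaced bins
#'
#' Divides the tonotopic axis into `n_bins` bins of equal bandwidth in
#' octaves between 180 and 7040 Hz and averages channel values within each
#' bin. Channels are assigned by center-frequency membership in half-open
#' bins (closed at the top edge only for the last bin), so the assignment
#' is a partition: no channel is dropped or duplicated.
#'
#' @param profile Numeric vector of channel values. Channel frequencies are
#'   taken from its `frequencies` attribute, or default to the standard
#'   128-channel grid.
#' @param n_bins Number of octave bins; must not exceed the channel count.
#' @param fmin,fmax Frequency range (Hz).
#' @return Numeric vector of length `n_bins`, with attributes `bin_edges`
#'   (Hz, length `n_bins + 1`) and `frequencies` (geometric bin centers).
#' @export
bin_octaves <- function(profile, n_bins, fmin = 180, fmax = 7040) {
  n_ch <- length(profile)
  if (n_bins > n_ch) {
    stop("n_bins (", n_bins, ") exceeds the number of channels (", n_ch, ")")
  }
  freqs <- attr(profile, "frequencies")
  if (is.null(freqs)) freqs <- cochlear_centers(n_ch, fmin, fmax)
  idx <- octave_bin_assign(freqs, n_bins, fmin, fmax)
  out <- as.numeric(tapply(as.numeric(profile), factor(idx, levels = seq_len(n_bins)), mean))
  out[is.na(out)] <- 0             # bins with no member channel (n_bins near n_ch)
  edges <- octave_bin_edges(n_bins, fmin, fmax)
  attr(out, "bin_edges") <- edges
  attr(out, "frequencies") <- sqrt(edges[-1L] * edges[-(n_bins + 1L)])
  out
}
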