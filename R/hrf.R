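#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma HRF (response peak near 5 s, undershoot near
#' 15 s), sampled at the repetition time and normalized to unit peak so
#' that response amplitudes (betas) carry the scale.
#'
#' @param tr Sampling interval in seconds (the fMRI TR).
#' @param duration_s Length of the sampled kernel in seconds.
#' @param peak_delay,undershoot_delay Gamma shape parameters (seconds).
#' @param undershoot_ratio Amplitude ratio of the undershoot.
#' @return Numeric vector: the kernel sampled at `0, tr, 2*tr, ...`,
#'   peak value 1.
#' @export
canonical_hrf <- function(tr = 2.8, duration_s = 20,
                          peak_delay = 6, undershoot_delay = 16,
                          undershoot_ratio = 1 / 6) {
  stopifnot(tr > 0, duration_s > tr)
  t <- seq(0, duration_s, by = tr)
  h <- stats::dgamma(t, shape = peak_delay, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot_delay, rate = 1)
  h / max(h)
}
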