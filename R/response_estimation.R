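#' Event-onset design matrices
#'
#' `event_design()` builds the TRs x sounds indicator matrix (one column
#' per sound, 1 at its onsets); `fir_design()` builds the TRs x window
#' finite-impulse-response matrix treating all sounds as one condition.
#' Both are internal building blocks of the response-estimation stage.
#'
#' @param event_table Data frame with `sound_id` and `onset_tr` (1-based).
#' @param n_trs Series length in TRs.
#' @return A design matrix.
#' @export
event_design <- function(event_table, n_trs) {
  ids <- unique(event_table$sound_id)
  X <- matrix(0, n_trs, length(ids), dimnames = list(NULL, ids))
  for (e in seq_len(nrow(event_table))) {
    X[event_table$onset_tr[e], match(event_table$sound_id[e], ids)] <- 1
  }
  X
}

#' @rdname event_design
#' @param window FIR window length in TRs.
#' @export
fir_design <- function(event_table, n_trs, window = 7L) {
  X <- matrix(0, n_trs, window)
  for (onset in event_table$onset_tr) {
    for (l in seq_len(window)) {
      r <- onset + l - 1L
      if (r <= n_trs) X[r, l] <- X[r, l] + 1
    }
  }
  X
}

# convolve an onset indicator column with a kernel, truncated to n TRs
convolve_onsets <- function(indicator, kernel) {
  n <- length(indicator)
  out <- numeric(n)
  for (t in which(indicator > 0)) {
    rows <- t + seq_along(kernel) - 1L
    keep <- rows <= n
    out[rows[keep]] <- out[rows[keep]] + indicator[t] * kernel[keep]
  }
  out
}

#' Estimate nuisance (noise) regressors from a noise pool
#'
#' Identifies voxels that the task design fails to explain and extracts
#' principal components of their time series as nuisance regressors to be
#' appended to subsequent design matrices. Task fit is measured by
#' split-half cross-validated R-squared (regression fit on odd TRs,
#' evaluated on even TRs, so every event contributes to both folds),
#' which is negative for voxels
#' carrying no task signal; the noise pool is all voxels with
#' cross-validated R-squared at or below zero.
#'
#' @param series A `voxel_timeseries` or a TRs x voxels matrix.
#' @param design TRs x k task design matrix (e.g. HRF-convolved onsets).
#' @param n_components Number of principal components to return; 0 yields
#'   a zero-column matrix (no denoising).
#' @return List: `components` (TRs x n_components), `noise_pool` (voxel
#'   indices), `cv_r2` (per-voxel cross-validated R-squared).
#' @export
estimate_noise_regressors <- function(series, design, n_components = 5L) {
  values <- if (inherits(series, "voxel_timeseries")) series$values else series
  n_tr <- nrow(values)
  stopifnot(nrow(design) == n_tr, n_tr > 2 * ncol(design) + 4L)
  half1 <- seq(1L, n_tr, by = 2L)
  half2 <- seq(2L, n_tr, by = 2L)
  X1 <- cbind(1, design[half1, , drop = FALSE])
  X2 <- cbind(1, design[half2, , drop = FALSE])
  beta <- qr.coef(qr(X1), values[half1, , drop = FALSE])
  beta[is.na(beta)] <- 0
  pred <- X2 %*% beta
  resid2 <- values[half2, , drop = FALSE] - pred
  ss_res <- colSums(resid2^2)
  centered <- sweep(values[half2, , drop = FALSE], 2L,
                    colMeans(values[half2, , drop = FALSE]))
  ss_tot <- colSums(centered^2)
  cv_r2 <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, -Inf)
  pool <- which(cv_r2 <= 0)

  if (n_components == 0L || length(pool) == 0L) {
    if (n_components > 0L) {
      warning("noise pool is empty; returning no nuisance components")
    }
    return(list(components = matrix(0, n_tr, 0L), noise_pool = pool,
                cv_r2 = cv_r2))
  }
  max_rank <- min(n_tr - 1L, length(pool))
  if (n_components > max_rank) {
    stop("n_components (", n_components,
         ") exceeds the available rank of the noise pool (", max_rank, ")")
  }
  pc <- stats::prcomp(values[, pool, drop = FALSE], center = TRUE,
                      scale. = FALSE)
  list(components = pc$x[, seq_len(n_components), drop = FALSE],
       noise_pool = pool, cv_r2 = cv_r2)
}

#' Per-voxel HRF estimation by FIR deconvolution
#'
#' Estimates one hemodynamic response kernel per voxel, shared across all
#' sounds of that voxel, by least-squares deconvolution over a fixed
#' window (default 7 TRs, about 20 s at TR = 2.8 s). Kernels are
#' normalized to unit peak so that response amplitudes carry the scale;
#' all-zero voxels return all-zero kernels.
#'
#' @inheritParams estimate_noise_regressors
#' @param event_table Data frame with `sound_id`, `onset_tr`.
#' @param window FIR window length in TRs.
#' @param noise_regressors Optional TRs x k nuisance matrix.
#' @return window x voxels matrix of HRF estimates.
#' @export
estimate_hrf <- function(series, event_table, window = 7L,
                         noise_regressors = NULL) {
  values <- if (inherits(series, "voxel_timeseries")) series$values else series
  n_tr <- nrow(values)
  if (nrow(event_table) < window) {
    stop("too few events (", nrow(event_table), ") for a ", window,
         "-TR deconvolution window")
  }
  X <- cbind(fir_design(event_table, n_tr, window), 1)
  if (!is.null(noise_regressors) && ncol(noise_regressors) > 0L) {
    X <- cbind(X, noise_regressors)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop("singular deconvolution design: rank ", qx$rank, " < ", ncol(X),
         " columns")
  }
  coefs <- qr.coef(qx, values)[seq_len(window), , drop = FALSE]
  apply(coefs, 2L, function(h) {
    pk <- max(h)
    if (pk > 0) h / pk else h
  })
}

#' Per-sound response amplitudes (betas)
#'
#' Estimates the amplitude of each voxel's response to each sound by least
#' squares, with one regressor per sound (the sound's onsets convolved
#' with that voxel's HRF), an intercept, and optional nuisance columns.
#'
#' @inheritParams estimate_hrf
#' @param hrf Either a single kernel (vector) shared by all voxels or a
#'   window x voxels matrix of per-voxel kernels.
#' @param exclude_ids Sound ids to drop before estimation (e.g. target or
#'   zero trials).
#' @return Sounds x voxels beta matrix (rows named by sound id).
#' @export
estimate_betas <- function(series, event_table, hrf,
                           noise_regressors = NULL, exclude_ids = NULL) {
  values <- if (inherits(series, "voxel_timeseries")) series$values else series
  if (!is.null(exclude_ids)) {
    event_table <- event_table[!(event_table$sound_id %in% exclude_ids), ,
                               drop = FALSE]
  }
  n_tr <- nrow(values)
  V <- ncol(values)
  onsets <- event_design(event_table, n_tr)
  ids <- colnames(onsets)
  S <- length(ids)
  hrf_mat <- if (is.matrix(hrf)) hrf else matrix(hrf, length(hrf), V)
  stopifnot(ncol(hrf_mat) == V)
  nuis <- if (!is.null(noise_regressors) && ncol(noise_regressors) > 0L) {
    noise_regressors
  } else NULL

  shared <- !is.matrix(hrf) || all(hrf_mat == hrf_mat[, 1L])
  betas <- matrix(NA_real_, S, V, dimnames = list(ids, colnames(values)))
  fit_block <- function(kernel, cols) {
    X <- apply(onsets, 2L, convolve_onsets, kernel = kernel)
    X <- cbind(X, 1)
    if (!is.null(nuis)) X <- cbind(X, nuis)
    qx <- qr(X)
    if (qx$rank < ncol(X)) stop("collinear beta-estimation design")
    qr.coef(qx, values[, cols, drop = FALSE])[seq_len(S), , drop = FALSE]
  }
  if (shared) {
    betas[] <- fit_block(hrf_mat[, 1L], seq_len(V))
  } else {
    for (v in seq_len(V)) betas[, v] <- fit_block(hrf_mat[, v], v)
  }
  betas
}
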