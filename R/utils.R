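#' Azimuth grid used throughout the pipeline
#'
#' Seven frontal azimuthal positions, from the listener's left (-90 degrees)
#' to the right (+90 degrees) in 30-degree steps.
#'
#' @return Integer vector of length 7.
#' @export
azimuth_grid <- function() {
  seq(-90L, 90L, by = 30L)
}

#' Center frequencies of the cochlear filterbank
#'
#' Log-spaced channel center frequencies between `fmin` and `fmax`:
#' channel k (k = 0..n-1) sits at `fmin * 2^(k * log2(fmax/fmin) / (n-1))`.
#' The default grid of 128 channels spans 180-7040 Hz, i.e. 5.3 octaves.
#'
#' @param n_channels Number of channels.
#' @param fmin,fmax Frequency range in Hz.
#' @return Numeric vector of strictly increasing center frequencies (Hz).
#' @export
cochlear_centers <- function(n_channels = 128L, fmin = 180, fmax = 7040) {
  stopifnot(n_channels >= 2L, fmin > 0, fmax > fmin)
  span <- log2(fmax / fmin)
  fmin * 2^(seq(0L, n_channels - 1L) * span / (n_channels - 1L))
}

#' Octave-spaced bin edges
#'
#' Edges equally spaced in log2(Hz) between `fmin` and `fmax`.
#'
#' @inheritParams cochlear_centers
#' @param n_bins Number of bins.
#' @return Numeric vector of `n_bins + 1` edges (Hz).
#' @export
octave_bin_edges <- function(n_bins, fmin = 180, fmax = 7040) {
  stopifnot(n_bins >= 1L)
  2^seq(log2(fmin), log2(fmax), length.out = n_bins + 1L)
}

# Assign frequencies to octave bins: half-open [lo, hi), the last bin closed
# at the top edge so no channel is dropped.  Returns integers in 1..n_bins.
octave_bin_assign <- function(freqs, n_bins, fmin = 180, fmax = 7040) {
  edges <- octave_bin_edges(n_bins, fmin, fmax)
  idx <- findInterval(freqs, edges, rightmost.closed = TRUE)
  if (any(idx < 1L | idx > n_bins)) {
    stop("frequencies outside [", fmin, ", ", fmax, "] Hz cannot be binned")
  }
  idx
}

# 2D Gaussian smoothing with a (2*half+1)^2 kernel, truncated and
# renormalized at the matrix edges (no wraparound).  `sd` is in grid units.
gaussian_smooth_2d <- function(m, size = 3L, sd = 0.5) {
  stopifnot(is.matrix(m), size %% 2L == 1L, sd > 0)
  half <- (size - 1L) %/% 2L
  off <- seq(-half, half)
  kern <- outer(off, off, function(dx, dy) exp(-(dx^2 + dy^2) / (2 * sd^2)))
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ii <- pmax(1L, i - half):pmin(nr, i + half)
      jj <- pmax(1L, j - half):pmin(nc, j + half)
      kw <- kern[ii - i + half + 1L, jj - j + half + 1L, drop = FALSE]
      out[i, j] <- sum(kw * m[ii, jj, drop = FALSE]) / sum(kw)
    }
  }
  out
}

#' Write a labelled matrix as TSV
#'
#' Plain-text export used by the analysis drivers: a header row of column
#' labels and one row per observation, with optional row identifiers in the
#' first column.
#'
#' @param m Matrix.
#' @param path Output path.
#' @param row_ids Optional character vector of row identifiers.
#' @export
write_matrix_tsv <- function(m, path, row_ids = rownames(m)) {
  df <- as.data.frame(m, check.names = FALSE)
  if (!is.null(row_ids)) df <- cbind(id = row_ids, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a voxel matrix as NIfTI (optional helper)
#'
#' Thin wrappers around the RNifti package for users whose responses live
#' in NIfTI volumes. The pipeline itself operates on plain matrices; these
#' helpers only bridge formats and require RNifti to be installed.
#'
#' @param path NIfTI file path.
#' @return `read_nifti_matrix()` returns a matrix with voxels in columns
#'   (4D input: time by voxel) and an attribute `dim3d` with the spatial
#'   grid dimensions.
#' @export
read_nifti_matrix <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required to read NIfTI files")
  }
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  d <- dim(a)
  if (length(d) == 4L) {
    m <- t(matrix(a, prod(d[1:3]), d[4]))
    attr(m, "dim3d") <- d[1:3]
  } else {
    m <- matrix(a, nrow = 1L)
    attr(m, "dim3d") <- d
  }
  m
}

#' @rdname read_nifti_matrix
#' @param values Numeric vector of per-voxel values.
#' @param dim3d Spatial grid dimensions (length 3).
#' @export
write_nifti_volume <- function(values, dim3d, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required to write NIfTI files")
  }
  stopifnot(length(values) == prod(dim3d))
  RNifti::writeNifti(array(values, dim = dim3d), path)
  invisible(path)
}
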