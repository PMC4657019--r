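#' @title Encoding-model feature spaces
#' @description
#' Four competing stimulus representations, each with the same budget of
#' F = 42 parameters: a frequency-only model (42 octave bins of the sound's
#' time-averaged cochlear profile), a location-only model (a fixed 6-bin
#' taper placed in the block of the sound's azimuth), an independent
#' frequency-location model (35 frequency bins concatenated with a one-hot
#' 7-azimuth vector), and a joint frequency-location model (the sound's
#' 6-bin frequency profile placed in its azimuth's block, zero elsewhere).
#' The joint/location column ordering is azimuth-major (blocks ordered
#' -90 to +90 degrees) with frequency ascending inside each block.
#' @name model_spaces
NULL

# fixed location taper: 6 values placed in the azimuth's block
location_taper <- function() c(1 / 6, 1 / 3, 1, 1, 1 / 3, 1 / 6)

new_feature_matrix <- function(values, model_kind, freq_hz, azimuth_deg) {
  stopifnot(ncol(values) == length(freq_hz), ncol(values) == length(azimuth_deg))
  colnames(values) <- paste0(
    ifelse(is.na(freq_hz), "", paste0("f", round(freq_hz))),
    ifelse(is.na(azimuth_deg), "", paste0("@", azimuth_deg))
  )
  structure(values, model_kind = model_kind, freq_hz = freq_hz,
            azimuth_deg = azimuth_deg, class = c("feature_matrix", "matrix", "array"))
}

#' @describeIn model_spaces Feature labels of a feature matrix: a data frame
#'   with one row per column, giving each feature's frequency-bin center
#'   (Hz, `NA` for pure location features) and azimuth (degrees, `NA` for
#'   pure frequency features).
#' @param W A `feature_matrix`.
#' @export
feature_labels <- function(W) {
  stopifnot(inherits(W, "feature_matrix"))
  data.frame(column = colnames(W),
             freq_hz = attr(W, "freq_hz"),
             azimuth_deg = attr(W, "azimuth_deg"))
}

check_profiles <- function(profiles) {
  if (is.numeric(profiles) && is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1L)
  profiles <- as.matrix(profiles)
  if (ncol(profiles) != 128L) {
    stop("expected 128-channel spectral profiles, got ", ncol(profiles), " channels")
  }
  profiles
}

check_azimuths <- function(azimuths) {
  bad <- setdiff(unique(azimuths), azimuth_grid())
  if (length(bad) > 0L) {
    stop("azimuths outside the -90..90 degree grid (30 degree steps): ",
         paste(bad, collapse = ", "))
  }
  as.integer(azimuths)
}

bin_profiles <- function(profiles, n_bins) {
  t(apply(profiles, 1L, function(p) as.numeric(bin_octaves(p, n_bins))))
}

#' @describeIn model_spaces Frequency-only model: each row is the sound's
#'   128-channel profile averaged into 42 octave bins.
#' @param profiles Sounds-by-128 matrix of time-averaged spectral profiles
#'   (or a single profile vector).
#' @export
build_frequency_only <- function(profiles) {
  profiles <- check_profiles(profiles)
  vals <- bin_profiles(profiles, 42L)
  centers <- attr(bin_octaves(profiles[1L, ], 42L), "frequencies")
  new_feature_matrix(vals, "frequency_only",
                     freq_hz = centers, azimuth_deg = rep(NA_real_, 42L))
}

#' @describeIn model_spaces Location-only model: a row carries the taper
#'   `[1/6, 1/3, 1, 1, 1/3, 1/6]` in the 6-column block of its azimuth
#'   (columns 1-6 for -90 degrees, 7-12 for -60 degrees, ...) and zeros
#'   elsewhere.
#' @param azimuths Integer vector of azimuth labels (degrees on the grid).
#' @export
build_location_only <- function(azimuths) {
  azimuths <- check_azimuths(azimuths)
  grid <- azimuth_grid()
  vals <- matrix(0, length(azimuths), 42L)
  taper <- location_taper()
  for (i in seq_along(azimuths)) {
    a <- match(azimuths[i], grid)
    vals[i, (a - 1L) * 6L + 1:6] <- taper
  }
  new_feature_matrix(vals, "location_only",
                     freq_hz = rep(NA_real_, 42L),
                     azimuth_deg = rep(grid, each = 6L))
}

#' @describeIn model_spaces Independent frequency-location model: the
#'   35-bin frequency profile concatenated with a one-hot 7-azimuth vector
#'   (35 + 7 = 42 columns).
#' @export
build_independent <- function(profiles, azimuths) {
  profiles <- check_profiles(profiles)
  azimuths <- check_azimuths(azimuths)
  stopifnot(nrow(profiles) == length(azimuths))
  grid <- azimuth_grid()
  freq_part <- bin_profiles(profiles, 35L)
  loc_part <- matrix(0, length(azimuths), 7L)
  loc_part[cbind(seq_along(azimuths), match(azimuths, grid))] <- 1
  centers <- attr(bin_octaves(profiles[1L, ], 35L), "frequencies")
  new_feature_matrix(cbind(freq_part, loc_part), "independent",
                     freq_hz = c(centers, rep(NA_real_, 7L)),
                     azimuth_deg = c(rep(NA_real_, 35L), grid))
}

#' @describeIn model_spaces Joint frequency-location model: the sound's
#'   6-bin frequency profile occupies its azimuth's 6-column block, all
#'   other 36 entries are zero, so column (f, a) carries frequency-bin-f
#'   energy only for sounds presented at azimuth a.
#' @export
build_joint <- function(profiles, azimuths) {
  profiles <- check_profiles(profiles)
  azimuths <- check_azimuths(azimuths)
  stopifnot(nrow(profiles) == length(azimuths))
  grid <- azimuth_grid()
  freq6 <- bin_profiles(profiles, 6L)
  vals <- matrix(0, length(azimuths), 42L)
  for (i in seq_along(azimuths)) {
    a <- match(azimuths[i], grid)
    vals[i, (a - 1L) * 6L + 1:6] <- freq6[i, ]
  }
  centers <- attr(bin_octaves(profiles[1L, ], 6L), "frequencies")
  new_feature_matrix(vals, "joint",
                     freq_hz = rep(centers, times = 7L),
                     azimuth_deg = rep(grid, each = 6L))
}

#' Frequency-azimuth grid of the joint model
#'
#' The 6 frequency-bin centers and 7 azimuths whose outer product spans the
#' joint model's 42 features, in the flattened column order used by
#' [build_joint()] (azimuth-major, frequency ascending within a block).
#'
#' @return Data frame with columns `freq_hz` and `azimuth_deg`, 42 rows.
#' @export
joint_grid <- function() {
  edges <- octave_bin_edges(6L)
  centers <- sqrt(edges[-1L] * edges[-7L])
  data.frame(freq_hz = rep(centers, times = 7L),
             azimuth_deg = rep(azimuth_grid(), each = 6L))
}
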