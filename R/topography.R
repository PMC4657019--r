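#' Reshape joint-model weights to the frequency x azimuth grid
#'
#' A voxel's 42 joint-model weights, reorganized as a 6 (frequency) by 7
#' (azimuth) matrix in the flattened order [build_joint()] uses.
#'
#' @param w Numeric vector of length 42.
#' @return 6 x 7 matrix with frequency-bin centers (Hz) as row names and
#'   azimuths (degrees) as column names.
#' @export
reshape_joint_weights <- function(w) {
  stopifnot(length(w) == 42L)
  grid <- joint_grid()
  matrix(as.numeric(w), 6L, 7L,
         dimnames = list(round(unique(grid$freq_hz)),
                         unique(grid$azimuth_deg)))
}

#' Preferred frequency and azimuth of one voxel
#'
#' Reshapes the voxel's joint-model weight vector to the 6 x 7 grid,
#' applies 2D Gaussian smoothing (3 x 3 kernel, SD 0.5 grid units,
#' truncated and renormalized at the edges), and returns the frequency and
#' azimuth of the maximum. Ties are resolved deterministically (lowest
#' frequency bin, then most central azimuth) and flagged.
#'
#' @param w Numeric vector of length 42 (one voxel's joint weights).
#' @param smooth Apply the smoothing step (default `TRUE`).
#' @return List: `best_frequency` (Hz, one of the 6 bin centers),
#'   `best_azimuth` (degrees, one of the 7 grid values), `freq_bin`,
#'   `azimuth_bin` (indices), `tie` (logical).
#' @export
voxel_preference <- function(w, smooth = TRUE) {
  m <- reshape_joint_weights(w)
  if (smooth) m <- gaussian_smooth_2d(m, size = 3L, sd = 0.5)
  mx <- max(m)
  hits <- which(m == mx, arr.ind = TRUE)
  tie <- nrow(hits) > 1L
  azis <- azimuth_grid()
  if (tie) {
    ord <- order(hits[, 1L], abs(azis[hits[, 2L]]), azis[hits[, 2L]])
    hits <- hits[ord, , drop = FALSE]
  }
  fi <- hits[1L, 1L]; ai <- hits[1L, 2L]
  edges <- octave_bin_edges(6L)
  centers <- sqrt(edges[-1L] * edges[-7L])
  list(best_frequency = centers[fi], best_azimuth = azis[ai],
       freq_bin = unname(fi), azimuth_bin = unname(ai), tie = tie)
}

#' Preference table for all voxels of a fit
#'
#' Applies [voxel_preference()] to every column of a joint-model tuning
#' matrix.
#'
#' @param R 42 x voxels weight matrix, or an `encoding_fit` from the joint
#'   model.
#' @param voxel_ids Optional voxel identifiers.
#' @param smooth Passed to [voxel_preference()].
#' @return Data frame: `voxel`, `cf_hz`, `azimuth_deg`, `freq_bin`,
#'   `azimuth_bin`, `tie`.
#' @export
preference_table <- function(R, voxel_ids = NULL, smooth = TRUE) {
  if (inherits(R, "encoding_fit")) {
    if (!identical(R$model_kind, "joint")) {
      stop("preference maps require a joint-model fit")
    }
    R <- R$weights
  }
  V <- ncol(R)
  if (is.null(voxel_ids)) voxel_ids <- seq_len(V)
  rows <- lapply(seq_len(V), function(v) {
    p <- voxel_preference(R[, v], smooth = smooth)
    data.frame(voxel = voxel_ids[v], cf_hz = p$best_frequency,
               azimuth_deg = p$best_azimuth, freq_bin = p$freq_bin,
               azimuth_bin = p$azimuth_bin, tie = p$tie)
  })
  do.call(rbind, rows)
}

#' Render preference maps onto a voxel grid
#'
#' Writes per-voxel preferred frequency and azimuth into a spatial grid at
#' the voxels' coordinates; only voxels that passed selection appear, the
#' rest stay `NA`. A log-frequency colour scale is the intended rendering
#' for tonotopy (attached as an attribute).
#'
#' @param preferences Data frame from [preference_table()].
#' @param coords Voxel coordinates, one row per row of `preferences`
#'   (2 or 3 integer columns).
#' @param dims Grid dimensions (length must match `ncol(coords)`).
#' @param selection Optional `voxel_selection` or vector of voxel ids to
#'   keep; default keeps all rows.
#' @return List: `frequency` and `azimuth` arrays of dimension `dims`
#'   (`NA` where unmapped), `colour_scale = "log-frequency"`.
#' @export
tonotopy_map <- function(preferences, coords, dims, selection = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(preferences) || ncol(coords) != length(dims)) {
    stop("geometry mismatch between preferences, coords and dims")
  }
  if (any(coords < 1L) || any(sweep(coords, 2L, dims, `>`))) {
    stop("geometry mismatch: coordinates fall outside the grid")
  }
  keep <- rep(TRUE, nrow(preferences))
  if (!is.null(selection)) {
    ids <- if (inherits(selection, "voxel_selection")) selection$voxel_ids else selection
    if (length(ids) == 0L) stop("empty voxel selection")
    keep <- preferences$voxel %in% ids
  }
  fmap <- array(NA_real_, dim = dims)
  amap <- array(NA_real_, dim = dims)
  fmap[coords[keep, , drop = FALSE]] <- preferences$cf_hz[keep]
  amap[coords[keep, , drop = FALSE]] <- preferences$azimuth_deg[keep]
  list(frequency = fmap, azimuth = amap, colour_scale = "log-frequency")
}

#' Gradient directions of a tonotopic slice
#'
#' Computes, per mapped voxel of a 2D best-frequency slice, the spatial
#' gradient of log2(best frequency) (central differences in the interior,
#' one-sided at edges; unmapped neighbours are skipped, and voxels lacking
#' both neighbours along either axis, or with a zero gradient, are
#' dropped), converts it to an angle in [0, 360) (0 degrees = +first-axis
#' direction, counterclockwise positive), and summarizes the angles as an
#' angular histogram with circular 3-bin smoothing and its local-maximum
#' peaks (one peak for a unimodal map, two for a mirror-symmetric one).
#'
#' @param map_slice 2D matrix of best frequencies in Hz (`NA` = unmapped).
#' @param bin_width Histogram bin width in degrees.
#' @return Object of class `gradient_distribution`: list with `angles`
#'   (degrees, one per contributing voxel), `breaks`, `counts`,
#'   `smoothed`, and `peaks` (data frame: `angle` of bin center, `height`,
#'   ordered by height).
#' @export
gradient_directions <- function(map_slice, bin_width = 20) {
  stopifnot(is.matrix(map_slice))
  if (sum(!is.na(map_slice)) < 4L) {
    stop("need at least a 2 x 2 mapped region to compute gradients")
  }
  lf <- log2(map_slice)
  nr <- nrow(lf); nc <- ncol(lf)
  diff1d <- function(vals, idx) {
    # derivative along a line at position idx, skipping NA neighbours
    lo <- if (idx > 1L) vals[idx - 1L] else NA_real_
    hi <- if (idx < length(vals)) vals[idx + 1L] else NA_real_
    if (!is.na(lo) && !is.na(hi)) (hi - lo) / 2
    else if (!is.na(hi)) hi - vals[idx]
    else if (!is.na(lo)) vals[idx] - lo
    else NA_real_
  }
  angles <- c()
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (is.na(lf[i, j])) next
      g1 <- diff1d(lf[, j], i)
      g2 <- diff1d(lf[i, ], j)
      if (is.na(g1) || is.na(g2) || (g1 == 0 && g2 == 0)) next
      ang <- atan2(g2, g1) * 180 / pi
      angles <- c(angles, ang %% 360)
    }
  }
  if (length(angles) == 0L) stop("no voxel yielded a defined gradient")
  breaks <- seq(0, 360, by = bin_width)
  counts <- as.numeric(table(cut(angles, breaks, right = FALSE,
                                 include.lowest = TRUE)))
  nb <- length(counts)
  smoothed <- vapply(seq_len(nb), function(b) {
    mean(counts[((b - 2L):b %% nb) + 1L])
  }, numeric(1L))
  is_peak <- vapply(seq_len(nb), function(b) {
    prev <- smoothed[((b - 2L) %% nb) + 1L]
    nxt <- smoothed[(b %% nb) + 1L]
    smoothed[b] > prev && smoothed[b] >= nxt
  }, logical(1L))
  centers <- breaks[-length(breaks)] + bin_width / 2
  peaks <- data.frame(angle = centers[is_peak], height = smoothed[is_peak])
  peaks <- peaks[order(-peaks$height), , drop = FALSE]
  structure(list(angles = angles, breaks = breaks, counts = counts,
                 smoothed = smoothed, peaks = peaks),
            class = "gradient_distribution")
}

#' Distribution of preferred azimuth
#'
#' Proportion of voxels preferring each azimuth, overall and separately
#' for low- and high-frequency voxels split at a characteristic-frequency
#' boundary (default 1.5 kHz, below which ITD as well as ILD cues carry
#' location information).
#'
#' @param preferences Data frame from [preference_table()].
#' @param cf_split Split frequency in Hz.
#' @return Data frame: `azimuth_deg`, `prop_all`, `prop_low`, `prop_high`,
#'   `n_all`, `n_low`, `n_high`. An empty stratum is reported as `NA` with
#'   a warning.
#' @export
azimuth_distribution <- function(preferences, cf_split = 1500) {
  azis <- azimuth_grid()
  tab <- function(p) {
    if (nrow(p) == 0L) return(list(prop = rep(NA_real_, 7L), n = rep(0L, 7L)))
    n <- vapply(azis, function(a) sum(p$azimuth_deg == a), integer(1L))
    list(prop = n / nrow(p), n = n)
  }
  low <- preferences[preferences$cf_hz < cf_split, , drop = FALSE]
  high <- preferences[preferences$cf_hz > cf_split, , drop = FALSE]
  if (nrow(low) == 0L) warning("low-frequency stratum is empty")
  if (nrow(high) == 0L) warning("high-frequency stratum is empty")
  all_t <- tab(preferences); low_t <- tab(low); high_t <- tab(high)
  data.frame(azimuth_deg = azis,
             prop_all = all_t$prop, prop_low = low_t$prop,
             prop_high = high_t$prop,
             n_all = all_t$n, n_low = low_t$n, n_high = high_t$n)
}

#' Periphery-versus-center test of azimuth preference
#'
#' Across replicates (subjects or simulated datasets), tests whether the
#' proportion of voxels tuned to the azimuthal periphery (-90 and +90
#' degrees, averaged) exceeds the proportion tuned to each central
#' azimuth, with one-tailed paired t-tests corrected for multiple
#' comparisons.
#'
#' @param preference_list List of preference tables (one per replicate).
#' @param method Correction method for [stats::p.adjust()].
#' @return Data frame: `center_azimuth`, `mean_periphery`, `mean_center`,
#'   `t`, `p`, `p_adj`.
#' @export
periphery_vs_center_test <- function(preference_list, method = "bonferroni") {
  if (length(preference_list) < 2L) stop("need at least 2 replicates")
  azis <- azimuth_grid()
  props <- vapply(preference_list, function(p) {
    vapply(azis, function(a) mean(p$azimuth_deg == a), numeric(1L))
  }, numeric(7L))                       # 7 x replicates
  periph <- colMeans(props[c(1L, 7L), , drop = FALSE])
  centers <- azis[2:6]
  out <- do.call(rbind, lapply(seq_along(centers), function(k) {
    ctr <- props[k + 1L, ]
    tt <- stats::t.test(periph, ctr, paired = TRUE, alternative = "greater")
    data.frame(center_azimuth = centers[k], mean_periphery = mean(periph),
               mean_center = mean(ctr), t = unname(tt$statistic),
               p = tt$p.value)
  }))
  out$p_adj <- stats::p.adjust(out$p, method = method)
  out
}

#' Contralateral / ipsilateral preference maps
#'
#' Applies the left-side sign flip (azimuths of voxels in left-hemisphere
#' structures are multiplied by -1) so that negative signed values mean a
#' contralateral and positive values an ipsilateral preference; voxels
#' preferring 0 degrees are classified "central" and excluded from
#' contra/ipsi proportions.
#'
#' @param preferences Data frame from [preference_table()].
#' @param side Character vector per voxel: `"left"` or `"right"`.
#' @return Data frame: `voxel`, `azimuth_deg`, `side`, `signed_azimuth`,
#'   `laterality` (factor: contra/ipsi/central), with attribute
#'   `contra_proportion` (share of contra among non-central voxels).
#' @export
laterality_maps <- function(preferences, side) {
  if (length(side) != nrow(preferences) || anyNA(side)) {
    stop("every voxel needs a side label ('left' or 'right')")
  }
  if (!all(side %in% c("left", "right"))) {
    stop("side labels must be 'left' or 'right'")
  }
  signed <- ifelse(side == "left", -preferences$azimuth_deg,
                   preferences$azimuth_deg)
  lat <- ifelse(signed == 0, "central", ifelse(signed < 0, "contra", "ipsi"))
  out <- data.frame(voxel = preferences$voxel,
                    azimuth_deg = preferences$azimuth_deg,
                    side = side, signed_azimuth = signed,
                    laterality = factor(lat,
                                        levels = c("contra", "central", "ipsi")))
  noncentral <- lat != "central"
  attr(out, "contra_proportion") <-
    if (any(noncentral)) mean(lat[noncentral] == "contra") else NA_real_
  out
}
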