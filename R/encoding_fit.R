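#' Select responsive voxels
#'
#' Ranks voxels by the t-statistic of their overall response to the sounds
#' (one-sample t of the per-sound amplitudes against zero), keeps those
#' with t strictly above the threshold inside the mask, and truncates the
#' ranking at the cap (the analysis is run on the "best" voxels only).
#'
#' @param Y Sounds x voxels response matrix.
#' @param mask Optional logical vector or integer indices restricting the
#'   candidate voxels (e.g. an anatomical mask).
#' @param t_threshold Inclusion threshold; strictly `t > t_threshold`.
#' @param cap Maximum number of voxels retained.
#' @return Object of class `voxel_selection`: list with `voxel_ids`
#'   (column indices into `Y`, ranked by t), `t_values` (per selected
#'   voxel) and `n_selected`.
#' @export
select_voxels <- function(Y, mask = NULL, t_threshold = 2.9, cap = 5000L) {
  V <- ncol(Y)
  cand <- seq_len(V)
  if (!is.null(mask)) {
    cand <- if (is.logical(mask)) which(mask) else as.integer(mask)
    if (length(cand) == 0L) stop("empty voxel mask")
  }
  S <- nrow(Y)
  mu <- colMeans(Y[, cand, drop = FALSE])
  sdv <- apply(Y[, cand, drop = FALSE], 2L, stats::sd)
  tv <- ifelse(sdv > 0, mu / (sdv / sqrt(S)), 0)
  keep <- which(tv > t_threshold)
  keep <- keep[order(tv[keep], decreasing = TRUE)]
  keep <- utils::head(keep, cap)
  structure(list(voxel_ids = cand[keep], t_values = tv[keep],
                 n_selected = length(keep)),
            class = "voxel_selection")
}

#' Default ridge penalty grid
#'
#' 25 log-spaced values over `[1e-3, 1e3]` times the mean diagonal of the
#' (column-centered) feature Gram matrix, so the grid brackets the scale
#' of the problem.
#'
#' @param W Feature matrix.
#' @param n_lambda Grid size.
#' @return Increasing numeric vector of penalties.
#' @export
default_lambda_grid <- function(W, n_lambda = 25L) {
  Wc <- scale(unclass(W), center = TRUE, scale = FALSE)
  s <- mean(diag(crossprod(Wc)))
  exp(seq(log(1e-3), log(1e3), length.out = n_lambda)) * s
}

#' Per-voxel ridge regression with ridge-trace penalty selection
#'
#' Solves `W R = Y` per voxel as
#' `R_j = (W'W + lambda_j I)^-1 W' Y_j` over a grid of penalties, choosing
#' each voxel's penalty by ridge-trace stability: the smallest grid value
#' at which the maximum relative coefficient change to the next grid value
#' falls below `stability_tol`. If no grid value reaches the threshold,
#' the flattest point of the trace (the grid value minimizing the relative
#' change) is used: at the large-penalty end coefficients shrink as
#' 1/lambda, whose relative change on a log grid is a large constant, so
#' the fallback lands on the plateau of the trace, not on a grid edge.
#' Both `W` (per column) and `Y` (per voxel)
#' are mean-centered before solving; means are restored at prediction.
#' The solution uses one eigendecomposition of `W'W`, reused across voxels
#' and penalties; it matches the direct solve to numerical precision.
#'
#' @param W Sounds x features feature matrix (training sounds).
#' @param Y Sounds x voxels response matrix (training sounds).
#' @param lambda_grid Increasing penalty grid; default
#'   [default_lambda_grid()].
#' @param stability_tol Relative-change threshold of the stability rule.
#' @param lambda_fixed Optional per-voxel penalties; when given, penalty
#'   selection is skipped and these values are used (the permutation test
#'   relies on this to freeze penalties).
#' @return Object of class `encoding_fit`: list with `weights`
#'   (features x voxels), `lambdas`, `w_means`, `y_means`, `lambda_grid`,
#'   `model_kind`, plus the feature labels of `W`.
#' @export
ridge_solve <- function(W, Y, lambda_grid = NULL, stability_tol = 0.05,
                        lambda_fixed = NULL) {
  Wv <- unclass(W)
  if (!all(is.finite(Wv)) || !all(is.finite(Y))) {
    stop("non-finite values in W or Y")
  }
  stopifnot(nrow(Wv) == nrow(Y))
  if (is.null(lambda_grid)) lambda_grid <- default_lambda_grid(W)
  stopifnot(length(lambda_grid) >= 1L, !is.unsorted(lambda_grid),
            all(lambda_grid >= 0))

  w_means <- colMeans(Wv)
  y_means <- colMeans(Y)
  Wc <- sweep(Wv, 2L, w_means)
  Yc <- sweep(Y, 2L, y_means)
  eg <- eigen(crossprod(Wc), symmetric = TRUE)
  A <- crossprod(eg$vectors, crossprod(Wc, Yc))    # F x V
  d <- pmax(eg$values, 0)
  V <- ncol(Y)
  nf <- ncol(Wv)

  if (!is.null(lambda_fixed)) {
    stopifnot(length(lambda_fixed) == V)
    weights <- matrix(0, nf, V)
    for (lam in unique(lambda_fixed)) {
      idx <- which(lambda_fixed == lam)
      weights[, idx] <- eg$vectors %*% (A[, idx, drop = FALSE] / (d + lam))
    }
    lambdas <- lambda_fixed
  } else {
    L <- length(lambda_grid)
    paths <- array(0, c(nf, V, L))
    for (l in seq_len(L)) {
      paths[, , l] <- eg$vectors %*% (A / (d + lambda_grid[l]))
    }
    if (L == 1L) {
      sel <- rep(1L, V)
    } else {
      sel <- integer(V)
      for (v in seq_len(V)) {
        pv <- paths[, v, ]
        den <- apply(abs(pv[, -L, drop = FALSE]), 2L, max)
        num <- apply(abs(pv[, -1L, drop = FALSE] -
                           pv[, -L, drop = FALSE]), 2L, max)
        rel <- num / pmax(den, .Machine$double.eps)
        stable <- which(rel < stability_tol | den == 0)
        sel[v] <- if (length(stable) > 0L) stable[1L] else which.min(rel)
      }
    }
    weights <- matrix(0, nf, V)
    for (v in seq_len(V)) weights[, v] <- paths[, v, sel[v]]
    lambdas <- lambda_grid[sel]
  }
  structure(list(weights = weights, lambdas = lambdas,
                 w_means = w_means, y_means = y_means,
                 lambda_grid = lambda_grid,
                 model_kind = attr(W, "model_kind"),
                 freq_hz = attr(W, "freq_hz"),
                 azimuth_deg = attr(W, "azimuth_deg"),
                 feature_names = colnames(Wv)),
            class = "encoding_fit")
}

#' Predict voxel responses to new sounds
#'
#' `Yhat = W_test %*% R`, with the training column means of `W` and the
#' per-voxel response means restored. The feature ordering of `W_test`
#' must match the fit (column labels are checked: the ordering is
#' load-bearing).
#'
#' @param object An `encoding_fit`.
#' @param W_test Feature matrix of the test sounds (same model space).
#' @param ... Unused.
#' @return Test-sounds x voxels matrix of predicted responses.
#' @export
predict.encoding_fit <- function(object, W_test, ...) {
  Wv <- unclass(W_test)
  if (ncol(Wv) != length(object$w_means)) {
    stop("feature count mismatch between fit and W_test")
  }
  if (!is.null(colnames(Wv)) && !is.null(object$feature_names) &&
      !identical(colnames(Wv), object$feature_names)) {
    stop("feature labels of W_test do not match the fitted model space")
  }
  Wc <- sweep(Wv, 2L, object$w_means)
  sweep(Wc %*% object$weights, 2L, object$y_means, `+`)
}
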