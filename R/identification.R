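#' Sound-identification analysis
#'
#' Evaluates predicted test responses against the measured ones: for each
#' test sound i, the predicted response pattern is correlated with every
#' measured test pattern; the rank r_i of the correlation with the
#' matching sound (1 = highest) yields the prediction accuracy
#' `P_i = 1 - (r_i - 1) / (S_test - 1)`, so perfect prediction gives 1,
#' the worst rank gives 0, and chance is 0.5. Correlation ties are broken
#' by average rank.
#'
#' @param Y_hat Predicted responses, test sounds x voxels.
#' @param Y_test Measured responses, same dimensions and voxel order.
#' @return Object of class `identification_result`: list with
#'   `per_sound_accuracy`, `ranks`, `mean_accuracy`, and the full
#'   `correlations` matrix (predicted x measured).
#' @export
identify_sounds <- function(Y_hat, Y_test) {
  stopifnot(identical(dim(Y_hat), dim(Y_test)))
  S <- nrow(Y_test)
  if (S < 2L) stop("need at least 2 test sounds")
  ids <- rownames(Y_test)
  if (is.null(ids)) ids <- as.character(seq_len(S))
  sd_hat <- apply(Y_hat, 1L, stats::sd)
  sd_obs <- apply(Y_test, 1L, stats::sd)
  if (any(sd_hat == 0) || any(sd_obs == 0)) {
    bad <- ids[sd_hat == 0 | sd_obs == 0]
    stop("zero-variance response row(s), correlation undefined for sound(s): ",
         paste(bad, collapse = ", "))
  }
  C <- stats::cor(t(Y_hat), t(Y_test))
  ranks <- vapply(seq_len(S), function(i) rank(-C[i, ])[i], numeric(1L))
  acc <- 1 - (ranks - 1) / (S - 1)
  structure(list(per_sound_accuracy = stats::setNames(acc, ids),
                 ranks = stats::setNames(ranks, ids),
                 mean_accuracy = mean(acc),
                 correlations = C),
            class = "identification_result")
}

#' Location-constrained label permutation
#'
#' Draws a pseudo-random permutation of sound indices in which no sound
#' receives a label originating from its own azimuth. A uniform
#' permutation is drawn and same-azimuth violations are repaired by
#' randomized pair swaps; the constraint is verified exactly before the
#' permutation is returned.
#'
#' @param azimuths Azimuth label per sound.
#' @param max_iter Safety bound on repair sweeps.
#' @return Integer permutation of `seq_along(azimuths)` with
#'   `azimuths[perm] != azimuths` everywhere.
#' @export
constrained_permutation <- function(azimuths, max_iter = 1000L) {
  n <- length(azimuths)
  if (length(unique(azimuths)) < 2L) {
    stop("constraint infeasible: all sounds share one azimuth")
  }
  if (max(table(azimuths)) > n - max(table(azimuths))) {
    stop("constraint infeasible: one azimuth holds more than half the sounds")
  }
  perm <- sample(n)
  for (iter in seq_len(max_iter)) {
    viol <- which(azimuths[perm] == azimuths)
    if (length(viol) == 0L) return(perm)
    v <- viol[1L]
    ok <- which(azimuths[perm] != azimuths[v] & azimuths[perm[v]] != azimuths)
    ok <- setdiff(ok, v)
    j <- if (length(ok) == 1L) ok else sample(ok, 1L)
    perm[c(v, j)] <- perm[c(j, v)]
  }
  stop("failed to repair the permutation constraint in ", max_iter, " sweeps")
}

#' Permutation test of identification accuracy
#'
#' Builds the empirical null distribution of the mean identification
#' accuracy by permuting the training stimulus labels (rows of `Y_train`)
#' under the constraint that a shuffled label never originates from the
#' sound's own azimuth, refitting the encoding model, and re-running the
#' identification analysis. The per-voxel ridge penalty is frozen at the
#' value obtained from the unpermuted fit. The p-value is
#' `(1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' @param W_train,Y_train Training feature and response matrices.
#' @param W_test,Y_test Test feature and response matrices.
#' @param azimuths_train Azimuth label per training sound.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param lambda_grid Optional penalty grid for the unpermuted fit.
#' @return List: `observed` (mean accuracy), `null_accuracies`
#'   (length `n_perm`), `p_value`, `n_perm`, `fit` (the unpermuted
#'   `encoding_fit`), `constraint_ok` (fraction of draws satisfying the
#'   different-azimuth constraint; 1 by construction).
#' @export
permutation_test <- function(W_train, Y_train, W_test, Y_test,
                             azimuths_train, n_perm = 200L, seed = 1L,
                             lambda_grid = NULL) {
  stopifnot(nrow(Y_train) == length(azimuths_train))
  fit <- ridge_solve(W_train, Y_train, lambda_grid = lambda_grid)
  observed <- identify_sounds(predict(fit, W_test), Y_test)$mean_accuracy

  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  null_acc <- numeric(n_perm)
  ok <- logical(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- constrained_permutation(azimuths_train)
    ok[b] <- all(azimuths_train[perm] != azimuths_train)
    fit_b <- ridge_solve(W_train, Y_train[perm, , drop = FALSE],
                         lambda_fixed = fit$lambdas)
    null_acc[b] <- identify_sounds(predict(fit_b, W_test),
                                   Y_test)$mean_accuracy
  }
  list(observed = observed, null_accuracies = null_acc,
       p_value = (1 + sum(null_acc >= observed)) / (1 + n_perm),
       n_perm = n_perm, fit = fit, constraint_ok = mean(ok))
}

#' Group-level model comparison on Fisher-transformed accuracies
#'
#' Treats each replicate's (subject's) mean identification accuracy as a
#' correlation-like quantity, applies the Fisher z-transform (atanh, with
#' accuracies clipped just below 1), and runs (a) a one-tailed one-sample
#' t-test of each model against chance (0.5) and (b) one-tailed paired
#' t-tests between all ordered model pairs, with multiple-comparison
#' correction on each family.
#'
#' @param acc Replicates x models matrix of mean accuracies (columns
#'   named by model).
#' @param chance Chance accuracy level.
#' @param method Correction method for [stats::p.adjust()].
#' @return List: `group` (data frame: model, mean accuracy, t, p, p_adj),
#'   `pairwise` (data frame: model_a, model_b, t, p, p_adj for the
#'   one-tailed test that a exceeds b).
#' @export
compare_models <- function(acc, chance = 0.5, method = "bonferroni") {
  acc <- as.matrix(acc)
  if (nrow(acc) < 2L) stop("need at least 2 paired replicates")
  if (is.null(colnames(acc))) colnames(acc) <- paste0("model", seq_len(ncol(acc)))
  z <- atanh(pmin(pmax(acc, -1 + 1e-6), 1 - 1e-6))
  group <- do.call(rbind, lapply(colnames(acc), function(m) {
    mu <- atanh(chance)
    if (stats::sd(z[, m]) == 0) {
      # degenerate replicates: all exactly equal
      delta <- mean(z[, m]) - mu
      return(data.frame(model = m, mean_accuracy = mean(acc[, m]),
                        t = if (delta == 0) 0 else sign(delta) * Inf,
                        p = if (delta > 0) 0 else 1))
    }
    tt <- stats::t.test(z[, m], mu = mu, alternative = "greater")
    data.frame(model = m, mean_accuracy = mean(acc[, m]),
               t = unname(tt$statistic), p = tt$p.value)
  }))
  group$p_adj <- stats::p.adjust(group$p, method = method)
  pairs <- expand.grid(model_a = colnames(acc), model_b = colnames(acc),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$model_a != pairs$model_b, ]
  pw <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    a <- pairs$model_a[k]; b <- pairs$model_b[k]
    dz <- z[, a] - z[, b]
    if (stats::sd(dz) == 0) {
      # identical accuracy vectors: no evidence either way
      return(data.frame(model_a = a, model_b = b, t = 0, p = 0.5))
    }
    tt <- stats::t.test(z[, a], z[, b], paired = TRUE,
                        alternative = "greater")
    data.frame(model_a = a, model_b = b, t = unname(tt$statistic),
               p = tt$p.value)
  }))
  pw$p_adj <- stats::p.adjust(pw$p, method = method)
  list(group = group, pairwise = pw)
}
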