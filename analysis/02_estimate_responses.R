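#!/usr/bin/env Rscript
# Step 2: from BOLD time series back to per-sound response amplitudes.
#
# Lays the simulated sounds out as a jittered event-related run
# (TR = 2.8 s, inter-onset intervals of 2/3/4 TRs), adds measurement
# noise, then runs the three estimation stages: nuisance components from
# the noise pool, per-voxel FIR HRF deconvolution, and per-sound beta
# estimation. Reports how well the recovered betas match the generating
# ones. Run on a 60-voxel subset to keep the per-voxel deconvolution fast.

library(soundenc)

dataset <- readRDS("results/dataset.rds")
keep <- 1:60
dataset$Y <- dataset$Y[, keep]
dataset$voxels <- dataset$voxels[keep, ]

hrf <- canonical_hrf(tr = 2.8)
ts <- generate_timeseries(dataset, tr = 2.8, hrf = hrf, noise_sd = 0.2,
                          seed = 20260923L)
cat("Simulated run of", nrow(ts$values), "TRs (",
    round(nrow(ts$values) * 2.8 / 60, 1), "min ) x", ncol(ts$values),
    "voxels.\n")

design <- apply(event_design(ts$event_table, nrow(ts$values)), 2L,
                soundenc:::convolve_onsets, kernel = hrf)
noise <- estimate_noise_regressors(ts$values, design, n_components = 3L)
cat("Noise pool:", length(noise$noise_pool), "voxels (cv-R2 <= 0).\n")

hrf_est <- estimate_hrf(ts, ts$event_table, window = length(hrf),
                        noise_regressors = noise$components)
hrf_err <- sqrt(mean((hrf_est - hrf)^2))
cat("Per-voxel FIR HRF RMSE vs generating kernel:", signif(hrf_err, 3), "\n")

betas <- estimate_betas(ts, ts$event_table, hrf_est,
                        noise_regressors = noise$components)
betas <- betas[rownames(dataset$Y), ]
sel <- select_voxels(betas, t_threshold = 2.9)
v <- sel$voxel_ids
cat(sel$n_selected, "voxels respond significantly (t > 2.9).\n")
r <- stats::cor(as.numeric(betas[, v]), as.numeric(dataset$Y[, v]))
cat("Beta recovery on selected voxels (per-voxel FIR HRF): r =",
    round(r, 3), "\n")

# reference: the same betas with the generating kernel, to show that the
# per-voxel HRF deconvolution is the noisiest stage here -- each sound
# occurs only once in this single simulated run, so amplitude variability
# across sounds acts as structured noise on the FIR estimate (the original
# design repeats every sound across runs)
betas_ref <- estimate_betas(ts, ts$event_table, hrf,
                            noise_regressors = noise$components)
betas_ref <- betas_ref[rownames(dataset$Y), ]
r_ref <- stats::cor(as.numeric(betas_ref[, v]), as.numeric(dataset$Y[, v]))
cat("Beta recovery on selected voxels (known kernel):      r =",
    round(r_ref, 3), "\n")

write_matrix_tsv(betas, "results/betas_recovered.tsv")
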