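#!/usr/bin/env Rscript
# Step 1: simulate the study's inputs with known ground truth.
#
# 56 training + 28 testing sounds, balanced over 7 azimuths (-90..+90 in
# 30-degree steps), each sound a smooth log-frequency spectral profile on
# the 128-channel cochlear grid; 500 voxels with separable Gaussian
# frequency x azimuth tuning; responses Y = W_joint R_true + noise
# (noise SD 0.1, SNR ~ 4).

library(soundenc)

dir.create("results", showWarnings = FALSE)
seed <- 20260922L

sounds <- generate_sound_set(n_train = 56L, n_test = 28L, n_azimuths = 7L,
                             seed = seed)
voxels <- generate_voxel_tuning(n_voxels = 500L, seed = seed + 1L)
dataset <- generate_responses(sounds, voxels, seed = seed + 2L)

utils::write.table(dataset$events, "results/events.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
write_matrix_tsv(dataset$Y, "results/responses_Y.tsv")
write_matrix_tsv(dataset$R_true, "results/tuning_R_true.tsv",
                 row_ids = sprintf("feat%02d", 1:42))
utils::write.table(voxels, "results/voxels_ground_truth.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
saveRDS(dataset, "results/dataset.rds")   # local cache for later steps

cat("Simulated", nrow(dataset$events), "sounds x", ncol(dataset$Y),
    "voxels.\n")
cat("Azimuth balance (train):",
    paste(table(dataset$events$azimuth_deg[dataset$events$split == "train"]),
          collapse = " "), "\n")
cat("Response range:", paste(round(range(dataset$Y), 3), collapse = " .. "),
    "\n")
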