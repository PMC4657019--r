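# Shared fixture builders: everything is generated in code at test time.

# small balanced sound set + voxels + responses under one seed
make_small_dataset <- function(n_train = 28L, n_test = 14L, n_voxels = 40L,
                               seed = 42L, noise_sd = 0.1, ...) {
  ss <- generate_sound_set(n_train, n_test, 7L, seed = seed)
  vox <- generate_voxel_tuning(n_voxels, seed = seed + 1L,
                               noise_sd = noise_sd, ...)
  generate_responses(ss, vox, seed = seed + 2L)
}

train_test_features <- function(ds, kind = "joint") {
  tr <- ds$events$split == "train"
  build <- function(rows) {
    switch(kind,
           frequency_only = build_frequency_only(ds$profiles[rows, , drop = FALSE]),
           location_only = build_location_only(ds$events$azimuth_deg[rows]),
           independent = build_independent(ds$profiles[rows, , drop = FALSE],
                                           ds$events$azimuth_deg[rows]),
           joint = build_joint(ds$profiles[rows, , drop = FALSE],
                               ds$events$azimuth_deg[rows]))
  }
  list(W_train = build(tr), W_test = build(!tr), train = tr)
}

# a one-event synthetic dataset for impulse-response checks
make_single_event_dataset <- function(beta = 1) {
  events <- data.frame(sound_id = "snd001", split = "train",
                       azimuth_deg = 0L, stringsAsFactors = FALSE)
  structure(list(events = events,
                 profiles = matrix(0, 1L, 128L),
                 W_true = NULL, R_true = NULL,
                 Y = matrix(beta, 1L, 1L, dimnames = list("snd001", NULL)),
                 voxels = data.frame(noise_sd = 0), seed = 1L),
            class = "synthetic_dataset")
}
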