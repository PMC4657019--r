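#!/usr/bin/env Rscript
# Step 5: stimulus-side binaural cue analysis.
#
# Synthesizes 6 sounds per extreme azimuth with a frequency-dependent ILD
# (6 dB above 1 kHz, mimicking head shadow) and a 500 us ITD, extracts
# per-bin ILD and ITD from the STFT, and tests per-bin cue
# informativeness (-90 vs +90 deg) with one-tailed t-tests, Bonferroni
# corrected.

library(soundenc)

ild_band <- function(s) data.frame(lo_hz = 1000, hi_hz = 7040, ild_db = s)

cues_m90 <- lapply(1:6, function(s) binaural_cue_spectrum(
  generate_binaural_audio(ild_db_by_band = ild_band(6), itd_us = 400,
                          seed = 500L + s)))
cues_p90 <- lapply(1:6, function(s) binaural_cue_spectrum(
  generate_binaural_audio(ild_db_by_band = ild_band(-6), itd_us = -400,
                          seed = 600L + s)))

ild_info <- cue_informativeness(cues_m90, cues_p90, cue = "ild")
itd_info <- cue_informativeness(cues_m90, cues_p90, cue = "itd")

n_sig_ild <- sum(ild_info$significant)
sig_range <- range(ild_info$frequency_hz[ild_info$significant])
cat("ILD informative in", n_sig_ild, "bins spanning",
    paste(round(sig_range), collapse = "-"), "Hz (planted: > 1 kHz).\n")
valid_lim <- max(itd_info$frequency_hz[!is.na(itd_info$p_value)])
cat("ITD testable below the phase-ambiguity limit (",
    round(valid_lim), "Hz );", sum(itd_info$significant, na.rm = TRUE),
    "bins informative there.\n")

out <- data.frame(frequency_hz = ild_info$frequency_hz,
                  ild_stat = ild_info$statistic,
                  ild_significant = ild_info$significant,
                  itd_stat = itd_info$statistic,
                  itd_significant = itd_info$significant)
dir.create("results", showWarnings = FALSE)
utils::write.table(out, "results/cue_informativeness.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("Wrote results/cue_informativeness.tsv\n")
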