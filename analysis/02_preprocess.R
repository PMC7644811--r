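#!/usr/bin/env Rscript
# Preprocess every cohort trial: linear envelope (50 Hz high-pass, full-wave
# rectification, 20 Hz low-pass, all zero-phase), per-muscle amplitude
# normalization, and time normalization to 200 points per gait cycle
# (100 stance + 100 swing), keeping at most the first 30 cycles.

suppressPackageStartupMessages(library(synlab))

manifest <- read.csv("results/manifest.csv")
norm <- list()
for (i in seq_len(nrow(manifest))) {
  key <- manifest$key[i]
  rec <- read_trial_csv(file.path("results/cohort", paste0(key, ".csv")))
  events <- attr(rec, "events")
  env <- normalize_amplitude(emg_envelope(rec))
  norm[[key]] <- time_normalize(env, events, max_cycles = 30)
}
saveRDS(norm, "results/normalized_cycles.rds")
message("preprocessed ", length(norm), " trials; cycles per trial: ",
        paste(range(vapply(norm, `[[`, integer(1), "n_cycles")),
              collapse = "-"))
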