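#!/usr/bin/env Rscript
# Fractal analysis of motor primitives (rescaled-range Hurst exponent,
# averaged over all primitives per trial) and gait spatiotemporal
# parameters with their step-to-step coefficients of variation.

suppressPackageStartupMessages(library(synlab))

manifest <- read.csv("results/manifest.csv")
models <- readRDS("results/synergy_models.rds")

hurst_tab <- NULL
gait_tab <- NULL
for (i in seq_len(nrow(manifest))) {
  key <- manifest$key[i]
  th <- suppressWarnings(trial_hurst(models[[key]]))
  hurst_tab <- rbind(hurst_tab, data.frame(
    key = key, environment = manifest$environment[i],
    locomotion = manifest$locomotion[i], h_mean = th$h_mean))
  rec <- read_trial_csv(file.path("results/cohort", paste0(key, ".csv")))
  g <- gait_summary(attr(rec, "events"))
  gait_tab <- rbind(gait_tab, data.frame(
    key = key, environment = manifest$environment[i],
    locomotion = manifest$locomotion[i],
    stance_mean = g$stance_mean, swing_mean = g$swing_mean,
    cadence_mean = g$cadence_mean, stance_cv = g$stance_cv,
    swing_cv = g$swing_cv, cadence_cv = g$cadence_cv))
}
write.csv(hurst_tab, "results/hurst_table.csv", row.names = FALSE)
write.csv(gait_tab, "results/gait_table.csv", row.names = FALSE)

# condition-level CV summary (the analogue of a variability table)
cvsum <- aggregate(cbind(stance_cv, swing_cv, cadence_cv) ~
                     locomotion + environment, gait_tab, mean)
write.csv(cvsum, "results/gait_cv_summary.csv", row.names = FALSE)
message(paste(capture.output(print(cvsum)), collapse = "\n"))
message("mean H by condition:")
message(paste(capture.output(
  print(aggregate(h_mean ~ locomotion + environment, hurst_tab, mean))),
  collapse = "\n"))
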