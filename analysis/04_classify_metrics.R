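#!/usr/bin/env Rscript
# Classify extracted primitives into fundamental (weight acceptance,
# propulsion, early swing, late swing) or combined synergies, per
# condition, then compute motor primitive geometrics: center of activity
# (circular, in normalized points) and full width at half maximum, plus the
# half-maximum exceedance heat maps.

suppressPackageStartupMessages(library(synlab))

manifest <- read.csv("results/manifest.csv")
models <- readRDS("results/synergy_models.rds")

labels_tab <- NULL
metrics_tab <- NULL
heatmaps <- NULL
for (env in c("O", "T")) for (loc in c("W", "R")) {
  keys <- manifest$key[manifest$environment == env &
                         manifest$locomotion == loc]
  prims <- NULL
  idx <- NULL
  for (key in keys) {
    P <- models[[key]]$P
    for (j in seq_len(nrow(P))) {
      prims <- rbind(prims, mean_cycle(P[j, ]))
      idx <- rbind(idx, data.frame(key = key, synergy = j))
    }
  }
  max_rank <- max(vapply(models[keys], function(m) m$r, numeric(1)))
  cl <- suppressWarnings(
    cluster_primitives(prims, max_rank = max_rank, seed = 1))
  for (i in seq_len(nrow(idx))) {
    key <- idx$key[i]; j <- idx$synergy[i]
    lab <- cl$labels$label[i]
    labels_tab <- rbind(labels_tab, data.frame(
      key = key, synergy = j, label = lab,
      match_weight = cl$labels$match_weight[i],
      match_r2 = cl$labels$match_r2[i]))
    g <- primitive_geometrics(models[[key]]$P[j, ])
    metrics_tab <- rbind(metrics_tab, data.frame(
      key = key, synergy = j, label = lab,
      coa_points = g$coa_points, fwhm_points = g$fwhm))
    heatmaps <- rbind(heatmaps, data.frame(
      key = key, synergy = j, label = lab,
      t(halfmax_heatmap(models[[key]]$P[j, ]))))
  }
}
write.csv(labels_tab, "results/synergy_labels.csv", row.names = FALSE)
write.csv(metrics_tab, "results/primitive_metrics.csv", row.names = FALSE)
write.csv(heatmaps, "results/halfmax_heatmaps.csv", row.names = FALSE)
message("combined synergies: ",
        round(100 * mean(labels_tab$label == "combined"), 1), "%")
agg <- aggregate(coa_points ~ label, metrics_tab, mean)
message(paste(capture.output(print(agg)), collapse = "\n"))
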