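#!/usr/bin/env Rscript
# Statistics: two-way repeated-measures ANOVAs (environment x locomotion
# type) for the scalar outcomes, and one-dimensional SPM with permutation
# cluster inference for the propulsion primitive (overground vs treadmill,
# within locomotion type).

suppressPackageStartupMessages({
  library(synlab)
  library(jsonlite)
})

manifest <- read.csv("results/manifest.csv")
models <- readRDS("results/synergy_models.rds")
rank_tab <- read.csv("results/rank_table.csv")
metrics <- read.csv("results/primitive_metrics.csv")
hurst_tab <- read.csv("results/hurst_table.csv")
gait_tab <- read.csv("results/gait_table.csv")

meta_of <- function(keys) manifest[match(keys, manifest$key), ]

anova_results <- list()
run_anova <- function(name, keys, values) {
  m <- meta_of(keys)
  df <- data.frame(participant = m$participant, environment = m$environment,
                   type = m$locomotion, value = values)
  a <- scalar_anova(df)
  anova_results[[name]] <<- list(
    method = a$method,
    environment = a$effects$environment[c("F", "p")],
    type = a$effects$type[c("F", "p")],
    interaction = a$effects$interaction[c("F", "p")])
  message(sprintf("%-18s env p=%.3f  type p=%.3f  int p=%.3f  [%s]", name,
                  a$effects$environment$p, a$effects$type$p,
                  a$effects$interaction$p, a$method))
}

run_anova("rank", rank_tab$key, rank_tab$rank)
run_anova("r2", rank_tab$key, rank_tab$r2)
run_anova("hurst", hurst_tab$key, hurst_tab$h_mean)
for (v in c("stance_cv", "swing_cv", "cadence_cv", "stance_mean",
            "swing_mean", "cadence_mean")) {
  run_anova(v, gait_tab$key, gait_tab[[v]])
}
prop <- metrics[metrics$label == "propulsion", ]
run_anova("coa_propulsion", prop$key, prop$coa_points)
run_anova("fwhm_propulsion", prop$key, prop$fwhm_points)
write_json(anova_results, "results/anova_results.json", auto_unbox = TRUE,
           digits = NA)

# SPM on the propulsion primitive, overground vs treadmill, per type
labels <- read.csv("results/synergy_labels.csv")
clusters_tab <- NULL
n_cyc <- min(vapply(models, function(m) ncol(m$P) %/% 200L, integer(1)))
for (loc in c("W", "R")) {
  participants <- sort(unique(manifest$participant))
  curves <- array(NA_real_, c(length(participants), 2, n_cyc, 200))
  ok <- rep(TRUE, length(participants))
  for (pi in seq_along(participants)) {
    for (ei in 1:2) {
      env <- c("O", "T")[ei]
      key <- manifest$key[manifest$participant == participants[pi] &
                            manifest$environment == env &
                            manifest$locomotion == loc]
      j <- labels$synergy[labels$key == key &
                            labels$label == "propulsion"][1]
      if (is.na(j)) { ok[pi] <- FALSE; next }
      P <- models[[key]]$P[j, ]
      curves[pi, ei, , ] <- t(matrix(P, 200)[, seq_len(n_cyc)])
    }
  }
  curves <- curves[ok, , , , drop = FALSE]
  res <- spm_rm_anova(curves, n_resamples = 1000, seed = 42, n_perm = 1000)
  if (nrow(res$clusters) > 0) {
    clusters_tab <- rbind(clusters_tab,
                          cbind(locomotion = loc, synergy = "propulsion",
                                res$clusters))
  }
  message("SPM propulsion ", loc, ": ",
          if (nrow(res$clusters)) paste(capture.output(print(res$clusters)),
                                        collapse = " | ")
          else "no suprathreshold clusters")
}
if (!is.null(clusters_tab)) {
  write.csv(clusters_tab, "results/spm_clusters.csv", row.names = FALSE)
}
message("done")
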