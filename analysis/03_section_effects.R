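#!/usr/bin/env Rscript
# Stage 3: per-section statistics. For every participant and parameter
# (speed, COPx, COPy): one-way ANOVA across the 13 sections, all 78 Tukey
# HSD pairs with Cohen's d, then the cohort-averaged effect-size network
# (edges where the mean d across participants is at least 0.8).
#
#   Rscript analysis/03_section_effects.R

library(wheelmetrics)

files <- list.files("results/aligned", full.names = TRUE, pattern = "\\.csv$")
if (length(files) == 0) stop("no aligned runs; run 02_process_runs.R first")
aligned <- lapply(files, utils::read.csv)
names(aligned) <- sub("\\.csv$", "", basename(files))

for (param in c("v", "copx", "copy")) {
  cmps <- lapply(aligned, compare_sections, parameter = param)
  pairs <- do.call(rbind, lapply(names(cmps), function(id) {
    p <- cmps[[id]]$pairs
    p$participant <- id
    p
  }))
  utils::write.csv(pairs, sprintf("results/pairs_%s.csv", param),
                   row.names = FALSE)
  net <- effect_network(cmps)
  utils::write.csv(net, sprintf("results/edges_%s.csv", param),
                   row.names = FALSE)
  edges <- net[net$edge, ]
  cat(sprintf("%s: %d of 78 section pairs form network edges (max mean d %.2f at %d-%d)\n",
              param, nrow(edges), max(net$mean_d),
              net$i[which.max(net$mean_d)], net$j[which.max(net$mean_d)]))
}
cat("Wrote results/pairs_{v,copx,copy}.csv and results/edges_{v,copx,copy}.csv\n")
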