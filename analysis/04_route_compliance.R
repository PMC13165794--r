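#!/usr/bin/env Rscript
# Stage 4: route-compliance analysis. Pairwise R^2 between participants per
# parameter, per-participant medians/IQRs with the low-side outlier rule,
# the rank table with rank sums, and Kendall's W concordance across the
# three parameters.
#
#   Rscript analysis/04_route_compliance.R

library(wheelmetrics)

files <- list.files("results/aligned", full.names = TRUE, pattern = "\\.csv$")
if (length(files) < 3) stop("need at least 3 aligned runs; run stages 1-2 first")
aligned <- lapply(files, utils::read.csv)
names(aligned) <- sub("\\.csv$", "", basename(files))

rep <- compliance_report(aligned)
for (p in names(rep$r2)) {
  utils::write.csv(round(rep$r2[[p]], 4), sprintf("results/r2_%s.csv", p))
}
comp <- data.frame(
  participant = rownames(rep$summary$median),
  round(rep$summary$median, 3),
  iqr = round(rep$summary$iqr, 3),
  rank = rep$ranks,
  rank_sum = rep$rank_sums)
utils::write.csv(comp, "results/compliance.csv", row.names = FALSE)

con <- rep$concordance
if (requireNamespace("jsonlite", quietly = TRUE)) {
  jsonlite::write_json(
    list(rank_sums = as.list(rep$rank_sums), W = con$W, chi2 = con$chi2,
         df = con$df, p = con$p),
    "results/concordance.json", auto_unbox = TRUE, digits = 6)
}
print(rep)
if (!is.null(rep$outliers) && any(rep$outliers)) {
  flagged <- which(rep$outliers, arr.ind = TRUE)
  cat("Low-side outliers (individualistic participants):\n")
  print(flagged)
}
cat("Wrote results/r2_*.csv, results/compliance.csv, results/concordance.json\n")
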