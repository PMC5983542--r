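#!/usr/bin/env Rscript

# Step 4 — VTA-seeded generalized PPI connectivity.
#
# For each retained subject and run: ridge-deconvolves the VTA series to
# its neural signal, forms per-condition interaction regressors, and fits
# each target ROI; interaction betas are averaged across runs.
# Writes results/ppi_betas.csv.

suppressPackageStartupMessages(library(pelearn))

bundle <- read_cohort("results/cohort")
acc <- data.frame(
  subject = vapply(bundle$subjects, `[[`, "", "id"),
  accuracy = vapply(bundle$subjects, function(s)
    subject_accuracy(s$trials), numeric(1)))
retained <- apply_exclusion(acc)$retained
subjects <- Filter(function(s) s$id %in% retained, bundle$subjects)

cat("Estimating VTA-seeded connectivity for", length(subjects),
    "subjects...\n")
rows <- lapply(subjects, function(s) {
  b <- subject_gppi_betas(s)
  data.frame(subject = s$id, group = s$group,
             target = rep(rownames(b), ncol(b)),
             condition = rep(colnames(b), each = nrow(b)),
             beta = as.vector(b), row.names = NULL)
})
ppi_betas <- do.call(rbind, rows)
write.csv(ppi_betas, "results/ppi_betas.csv", row.names = FALSE)

rs <- ppi_betas[ppi_betas$target == "right_striatum", ]
cat("\nVTA - right striatum connectivity (mean beta):\n")
for (g in c("control", "mdd"))
  cat(sprintf("  %-8s gain %6.3f   loss %6.3f\n", g,
              mean(rs$beta[rs$group == g & rs$condition == "gain"]),
              mean(rs$beta[rs$group == g & rs$condition == "loss"])))
cat("Wrote results/ppi_betas.csv\n")
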