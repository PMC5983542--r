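#!/usr/bin/env Rscript

# Step 3 — ROI-level model-based GLM.
#
# Recomputes each retained subject's prediction-error series with the
# pooled learning rates, convolves onset and PE-modulator regressors with
# the canonical HRF, fits every ROI time series by OLS run-wise, and
# averages the RPE/PPE coefficients across runs.
# Writes results/glm_betas.csv.

suppressPackageStartupMessages(library(pelearn))

bundle <- read_cohort("results/cohort")
alphas <- unlist(jsonlite::read_json("results/pooled_alphas.json"))
acc <- data.frame(
  subject = vapply(bundle$subjects, `[[`, "", "id"),
  accuracy = vapply(bundle$subjects, function(s)
    subject_accuracy(s$trials), numeric(1)))
retained <- apply_exclusion(acc)$retained
subjects <- Filter(function(s) s$id %in% retained, bundle$subjects)

cat(sprintf("Extracting RPE/PPE betas for %d subjects (alphas %.2f/%.2f)\n",
            length(subjects), alphas["gain"], alphas["loss"]))
rows <- lapply(subjects, function(s) {
  b <- subject_glm_betas(s, alphas)
  data.frame(subject = s$id, group = s$group, roi = rownames(b),
             rpe_beta = b[, "rpe"], ppe_beta = b[, "ppe"],
             row.names = NULL)
})
glm_betas <- do.call(rbind, rows)
write.csv(glm_betas, "results/glm_betas.csv", row.names = FALSE)

cat("\nGroup means of the right-striatal betas:\n")
rs <- glm_betas[glm_betas$roi == "right_striatum", ]
for (g in c("control", "mdd"))
  cat(sprintf("  %-8s RPE %6.3f   PPE %6.3f\n", g,
              mean(rs$rpe_beta[rs$group == g]),
              mean(rs$ppe_beta[rs$group == g])))
cat("Wrote results/glm_betas.csv\n")
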