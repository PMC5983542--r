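#!/usr/bin/env Rscript

# Step 5 — group statistics.
#
# Runs the study's group-level tests on the tables produced by steps 1-4:
# the learning-curve mixed-effects model, the striatal and
# punishment-system mixed ANOVAs with partial eta squared, the
# right-striatal group contrast with Cohen's ds, connectivity ANOVAs,
# dose-effect partial correlations and the Fisher z group comparison.
# Writes the ANOVA tables under results/ and prints a summary.

suppressPackageStartupMessages(library(pelearn))

bundle <- read_cohort("results/cohort")
glm_betas <- read.csv("results/glm_betas.csv", stringsAsFactors = FALSE)
ppi_betas <- read.csv("results/ppi_betas.csv", stringsAsFactors = FALSE)
subjects <- Filter(function(s) s$id %in% glm_betas$subject,
                   bundle$subjects)
groups <- vapply(subjects, `[[`, "", "group")

s <- group_statistics(subjects, groups, glm_betas, ppi_betas,
                      bundle$covariates)
write.csv(as.data.frame(s$striatum_anova), "results/striatum_anova.csv",
          row.names = FALSE)
write.csv(as.data.frame(s$pe_rois_anova), "results/pe_rois_anova.csv",
          row.names = FALSE)
write.csv(s$accuracy_table, "results/accuracy_table.csv",
          row.names = FALSE)

fmt_eff <- function(a, eff) {
  r <- a[a$effect == eff, ]
  sprintf("F(%d,%d) = %.2f, p = %.3f, eta_p^2 = %.2f",
          r$df1, r$df2, r$F, r$p, r$pes)
}
cat("\n=== Behavior ===\n")
cat(sprintf("Group x Valence interaction: b = %.3f, p = %.3f\n",
            s$learning_curve$interaction_b, s$learning_curve$interaction_p))
print(s$learning_curve$slopes, row.names = FALSE)
cat("\n=== Striatal PE signals ===\n")
cat("3-way Group x Valence x Hemisphere:",
    fmt_eff(s$striatum_anova, "group x valence x hemisphere"), "\n")
cat("Right striatum Group x Valence:",
    fmt_eff(s$right_striatum_anova, "group x valence"), "\n")
cat(sprintf("Right-striatal RPE, control vs MDD: t(%d) = %.2f, p = %.3f, ds = %.2f\n",
            s$rs_contrast$df, s$rs_contrast$t, s$rs_contrast$p,
            s$rs_contrast$ds))
cat("ROI family Bonferroni threshold:", s$bonferroni$roi, "\n")
cat("\n=== Punishment-system ROIs ===\n")
for (eff in c("valence", "roi", "valence x roi", "group x valence"))
  cat(sprintf("%-18s %s\n", eff, fmt_eff(s$pe_rois_anova, eff)))
cat("\n=== VTA connectivity ===\n")
cat("VTA-right striatum Group:",
    fmt_eff(s$connectivity_anova$right_striatum, "group"), "\n")
cat("VTA-right striatum Valence:",
    fmt_eff(s$connectivity_anova$right_striatum, "valence"), "\n")
cat("\n=== Disease burden (within MDD) ===\n")
cat(sprintf("MDE count vs right-striatal RPE: partial r = %.2f (n = %d, p = %.3f)\n",
            s$cor_mde_rs_rpe$r, s$cor_mde_rs_rpe$n, s$cor_mde_rs_rpe$p))
cat(sprintf("MDE count vs habenular PPE:      partial r = %.2f (n = %d, p = %.3f)\n",
            s$cor_mde_hb_ppe$r, s$cor_mde_hb_ppe$n, s$cor_mde_hb_ppe$p))
cat(sprintf("Correlation family Bonferroni threshold: %.3f\n",
            s$bonferroni$correlations))
cat(sprintf("\nVTA-striatum RPE coupling: r = %.2f (controls) vs %.2f (MDD), z = %.2f, p = %.2f\n",
            s$vta_rs_corr$r_control, s$vta_rs_corr$r_mdd,
            s$vta_rs_corr$z, s$vta_rs_corr$p))
cat("\nTables written under results/\n")
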