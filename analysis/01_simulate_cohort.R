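#!/usr/bin/env Rscript

# Step 1 — simulate the study cohort.
#
# Generates the default synthetic cohort (26 controls, 25 MDD; 3 runs x
# 120 trials each; ROI BOLD for right/left striatum, VTA, habenula and
# right insula; clinical covariates) and writes it as plain-text files
# under results/cohort/.

suppressPackageStartupMessages(library(pelearn))

seed <- 42
spec <- cohort_spec()
cat("Simulating", spec$n_controls, "controls and", spec$n_mdd,
    "MDD subjects (seed", seed, ")...\n")
bundle <- generate_cohort(spec, seed = seed)
write_cohort(bundle, "results/cohort")

acc <- t(vapply(bundle$subjects, function(s) {
  vapply(c("gain", "loss", "neutral"), function(cc)
    100 * mean(s$trials$chose_correct[s$trials$condition == cc]),
    numeric(1))
}, numeric(3)))
grp <- vapply(bundle$subjects, `[[`, "", "group")
cat("\nMean choice accuracy (%) by group and condition:\n")
for (g in c("control", "mdd"))
  cat(sprintf("  %-8s gain %5.1f  loss %5.1f  neutral %5.1f\n", g,
              mean(acc[grp == g, "gain"]), mean(acc[grp == g, "loss"]),
              mean(acc[grp == g, "neutral"])))
cat("\nThe MDD group's lower gain accuracy reflects the planted reward",
    "learning-rate deficit;\nloss avoidance is matched by construction,",
    "and neutral sits at chance.\n")
cat("Cohort written to results/cohort/\n")
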