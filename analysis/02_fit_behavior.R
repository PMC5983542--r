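#!/usr/bin/env Rscript

# Step 2 — behavioral exclusion and Q-learning model fits.
#
# Applies the <50% accuracy exclusion, fits every retained subject by
# multi-start maximum likelihood, compares each fit against the chance
# model, and pools the learning rates that the fMRI stage will hold
# fixed. Writes results/fits.csv and results/pooled_alphas.json.

suppressPackageStartupMessages(library(pelearn))

bundle <- read_cohort("results/cohort")
acc <- data.frame(
  subject = vapply(bundle$subjects, `[[`, "", "id"),
  accuracy = vapply(bundle$subjects, function(s)
    subject_accuracy(s$trials), numeric(1)))
excl <- apply_exclusion(acc)
if (nrow(excl$excluded)) {
  cat("Excluded for accuracy < 50%:\n")
  print(excl$excluded, row.names = FALSE)
} else cat("No subject fell below the 50% accuracy criterion.\n")

subjects <- Filter(function(s) s$id %in% excl$retained, bundle$subjects)
cat("Fitting", length(subjects), "subjects...\n")
fits <- lapply(subjects, function(s) fit_subject(s$trials))

tab <- data.frame(
  subject = vapply(subjects, `[[`, "", "id"),
  group = vapply(subjects, `[[`, "", "group"),
  do.call(rbind, lapply(fits, function(f)
    as.data.frame(unclass(f)[c("alpha_gain_hat", "alpha_loss_hat",
                               "beta_hat", "nll", "nll_chance",
                               "pseudo_R2", "lr_p")]))))
dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/fits.csv", row.names = FALSE)

alphas <- c(gain = pooled_alpha(fits, "gain"),
            loss = pooled_alpha(fits, "loss"))
jsonlite::write_json(as.list(alphas), "results/pooled_alphas.json",
                     auto_unbox = TRUE, digits = NA)
cat(sprintf("\nPooled learning rates: reward %.2f, punishment %.2f\n",
            alphas["gain"], alphas["loss"]))
cat(sprintf("Model beats chance (LR test p < .05) in %d/%d subjects; ",
            sum(tab$lr_p < 0.05), nrow(tab)),
    sprintf("median pseudo-R2 %.2f\n", median(tab$pseudo_R2)))
cat("Wrote results/fits.csv and results/pooled_alphas.json\n")
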