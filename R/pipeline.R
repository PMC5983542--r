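#' Pipeline run configuration
#'
#' @param cohort A [cohort_spec()] describing the synthetic study (or
#'   `NULL` when a pre-built bundle is passed to [run_pipeline()]).
#' @param seed Master seed for the run.
#' @param outdir Optional output directory; when given, all stage tables
#'   are written as CSV plus a plain-text report and a run log.
#' @param fixed_alpha_policy `"fit_then_pool"` fits every retained subject
#'   by maximum likelihood and fixes the fMRI learning rates at the
#'   cohort means; `"fixed"` uses `fixed_alpha_gain` / `fixed_alpha_loss`
#'   directly (replication mode).
#' @param fixed_alpha_gain,fixed_alpha_loss Learning rates used by the
#'   `"fixed"` policy (defaults 0.3 and 0.4).
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(), seed = 1L, outdir = NULL,
                       fixed_alpha_policy = c("fit_then_pool", "fixed"),
                       fixed_alpha_gain = 0.3, fixed_alpha_loss = 0.4) {
  structure(list(cohort = cohort, seed = as.integer(seed), outdir = outdir,
                 fixed_alpha_policy = match.arg(fixed_alpha_policy),
                 fixed_alpha_gain = fixed_alpha_gain,
                 fixed_alpha_loss = fixed_alpha_loss),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Per-subject ROI prediction-error betas
#'
#' Recomputes the subject's fixed-alpha PE series, builds the run-wise
#' design matrices, fits each ROI by OLS and averages the RPE (gain
#' modulator) and PPE (loss modulator) coefficients across runs.
#'
#' @param sub Subject entry of a `cohort_bundle` (`trials` + `roi_bold`).
#' @param alphas Named vector `c(gain = , loss = )` of fixed learning
#'   rates.
#' @param TR Repetition time in seconds.
#' @return Matrix (ROI x c("rpe", "ppe")) of averaged betas.
#' @export
subject_glm_betas <- function(sub, alphas, TR = 2) {
  pe <- compute_pe_series(sub$trials, alphas[["gain"]], alphas[["loss"]])
  runs <- unique(pe$run)
  acc <- matrix(0, nrow = length(ROI_NAMES), ncol = 2,
                dimnames = list(ROI_NAMES, c("rpe", "ppe")))
  for (r in runs) {
    pe_r <- pe[pe$run == r, , drop = FALSE]
    bold_r <- sub$roi_bold[sub$roi_bold$run == r, , drop = FALSE]
    X <- build_design_matrix(pe_r, TR = TR, n_scans = nrow(bold_r))
    for (roi in ROI_NAMES) {
      fit <- fit_glm(bold_r[[roi]], X)
      acc[roi, "rpe"] <- acc[roi, "rpe"] + glm_beta(fit, "gain_pe")
      acc[roi, "ppe"] <- acc[roi, "ppe"] + glm_beta(fit, "loss_pe")
    }
  }
  acc / length(runs)
}

#' Per-subject VTA-seeded gPPI connectivity betas
#'
#' Builds the run-wise gPPI designs with the VTA time series as seed and
#' averages each target ROI's per-condition interaction coefficients
#' across runs.
#'
#' @inheritParams subject_glm_betas
#' @return Matrix (target ROI x condition) of averaged connectivity betas.
#' @export
subject_gppi_betas <- function(sub, TR = 2) {
  runs <- unique(sub$trials$run)
  targets <- setdiff(ROI_NAMES, "vta")
  acc <- matrix(0, nrow = length(targets), ncol = 3,
                dimnames = list(targets, TASK_CONDITIONS))
  for (r in runs) {
    ev <- sub$trials[sub$trials$run == r, , drop = FALSE]
    bold_r <- sub$roi_bold[sub$roi_bold$run == r, , drop = FALSE]
    X <- build_gppi_design(bold_r$vta, ev, TR = TR)
    for (roi in targets) {
      res <- fit_gppi(bold_r[[roi]], X)
      acc[roi, res$condition] <- acc[roi, res$condition] + res$beta
    }
  }
  acc / length(runs)
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) a cohort, applies the task-compliance exclusion,
#' fits the Q-learning model per subject (or uses fixed learning rates),
#' computes fixed-alpha PE series, estimates per-subject ROI GLM betas and
#' VTA-seeded gPPI connectivity, and runs the group statistics: the
#' learning-curve mixed-effects interaction, the striatal
#' Group x Valence x Hemisphere ANOVA with follow-ups, the
#' Group x Valence x ROI ANOVA over the punishment-system ROIs, the
#' right-striatal group contrast with Cohen's ds, the VTA-right-striatum
#' connectivity ANOVA, dose-effect partial correlations (lifetime episode
#' count vs. striatal RPE and habenular PPE betas, controlling episode
#' length), and the Fisher z comparison of VTA-striatum RPE coupling
#' correlations between groups.
#'
#' @param config A [run_config()].
#' @param bundle Optional pre-built `cohort_bundle`; when `NULL` one is
#'   generated from `config$cohort` and `config$seed`.
#' @return A list of stage results (see the pipeline vignette).
#' @export
run_pipeline <- function(config = run_config(), bundle = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(bundle))
    bundle <- stage("synthesize",
                    generate_cohort(config$cohort, config$seed))
  TR <- if (!is.null(bundle$spec)) bundle$spec$TR else 2

  accuracy <- stage("exclusion", data.frame(
    subject = vapply(bundle$subjects, `[[`, "", "id"),
    accuracy = vapply(bundle$subjects, function(s)
      subject_accuracy(s$trials), numeric(1))))
  excl <- apply_exclusion(accuracy)
  subjects <- Filter(function(s) s$id %in% excl$retained, bundle$subjects)
  groups <- vapply(subjects, `[[`, "", "group")

  fits <- NULL
  if (config$fixed_alpha_policy == "fit_then_pool") {
    fits <- stage("fit", lapply(subjects, function(s)
      tryCatch(fit_subject(s$trials), error = function(e)
        stop("subject ", s$id, ": ", conditionMessage(e), call. = FALSE))))
    alphas <- c(gain = pooled_alpha(fits, "gain"),
                loss = pooled_alpha(fits, "loss"))
  } else {
    alphas <- c(gain = config$fixed_alpha_gain,
                loss = config$fixed_alpha_loss)
  }

  glm_betas <- stage("glm", {
    rows <- lapply(seq_along(subjects), function(i) {
      b <- subject_glm_betas(subjects[[i]], alphas, TR)
      data.frame(subject = subjects[[i]]$id, group = groups[i],
                 roi = rownames(b), rpe_beta = b[, "rpe"],
                 ppe_beta = b[, "ppe"], row.names = NULL,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  ppi_betas <- stage("gppi", {
    rows <- lapply(seq_along(subjects), function(i) {
      b <- subject_gppi_betas(subjects[[i]], TR)
      data.frame(subject = subjects[[i]]$id, group = groups[i],
                 target = rep(rownames(b), ncol(b)),
                 condition = rep(colnames(b), each = nrow(b)),
                 beta = as.vector(b), row.names = NULL,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  stats <- stage("group_stats",
                 group_statistics(subjects, groups, glm_betas,
                                  ppi_betas, bundle$covariates))

  out <- list(bundle = bundle, accuracy = accuracy, exclusion = excl,
              fits = fits, alphas = alphas, glm_betas = glm_betas,
              ppi_betas = ppi_betas, stats = stats,
              config = config,
              log = list(seed = config$seed,
                         fixed_alpha_policy = config$fixed_alpha_policy,
                         alphas = alphas,
                         n_retained = length(subjects),
                         timestamp = format(Sys.time())))
  if (!is.null(config$outdir)) write_pipeline_outputs(out, config$outdir)
  out
}

# Long learning-curve table at trial level for the mixed-effects model.
learning_trial_table <- function(subjects, groups) {
  rows <- lapply(seq_along(subjects), function(i) {
    tr <- subjects[[i]]$trials
    tr <- tr[tr$condition %in% c("gain", "loss"), ]
    data.frame(subject = subjects[[i]]$id, group = groups[i],
               valence = tr$condition, trial = tr$trial_in_condition,
               choice = as.numeric(tr$chose_correct),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group-level statistics of the study
#'
#' Runs every group analysis on the per-subject tables: the mixed-effects
#' learning-curve interaction, the striatal Group x Valence x Hemisphere
#' ANOVA with right-striatum follow-up, the Group x Valence x ROI ANOVA
#' over habenula/VTA/insula, the right-striatal RPE group contrast with
#' Cohen's ds, per-target connectivity ANOVAs, dose-effect partial
#' correlations (episode count vs. striatal RPE and habenular PPE,
#' controlling episode length), the between-group Fisher z comparison of
#' VTA-striatum RPE correlations, and the Bonferroni thresholds of the
#' two test families.
#'
#' @param subjects List of retained subject entries of a `cohort_bundle`.
#' @param groups Character vector of group labels aligned with `subjects`.
#' @param glm_betas Tidy data.frame from [subject_glm_betas()] rows
#'   (`subject`, `group`, `roi`, `rpe_beta`, `ppe_beta`).
#' @param ppi_betas Tidy data.frame from [subject_gppi_betas()] rows
#'   (`subject`, `group`, `target`, `condition`, `beta`).
#' @param covariates Covariate data.frame of the cohort.
#' @return Named list of statistical results.
#' @export
group_statistics <- function(subjects, groups, glm_betas, ppi_betas,
                             covariates) {
  lc <- learning_curve_interaction(learning_trial_table(subjects, groups))

  # striatal Group x Valence (RPE/PPE beta) x Hemisphere ANOVA
  stri <- glm_betas[glm_betas$roi %in% c("right_striatum",
                                         "left_striatum"), ]
  stri_long <- data.frame(
    subject = rep(stri$subject, 2), group = rep(stri$group, 2),
    hemisphere = rep(ifelse(stri$roi == "right_striatum", "right", "left"),
                     2),
    valence = rep(c("rpe", "ppe"), each = nrow(stri)),
    value = c(stri$rpe_beta, stri$ppe_beta), stringsAsFactors = FALSE)
  striatum_anova <- mixed_anova(stri_long, "value", "group",
                                c("valence", "hemisphere"))
  rs_long <- stri_long[stri_long$hemisphere == "right", ]
  right_striatum_anova <- mixed_anova(rs_long, "value", "group", "valence")

  # punishment-system ROIs: Group x Valence x ROI
  pun <- glm_betas[glm_betas$roi %in% c("habenula", "vta",
                                        "right_insula"), ]
  pun_long <- data.frame(
    subject = rep(pun$subject, 2), group = rep(pun$group, 2),
    roi = rep(pun$roi, 2),
    valence = rep(c("rpe", "ppe"), each = nrow(pun)),
    value = c(pun$rpe_beta, pun$ppe_beta), stringsAsFactors = FALSE)
  pe_rois_anova <- mixed_anova(pun_long, "value", "group",
                               c("valence", "roi"))

  # right-striatal RPE group contrast with effect size
  rs <- glm_betas[glm_betas$roi == "right_striatum", ]
  tt <- stats::t.test(rpe_beta ~ group, data = rs, var.equal = TRUE)
  n1 <- sum(rs$group == "control"); n2 <- sum(rs$group == "mdd")
  rs_contrast <- list(
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    ds = cohens_ds_from_t(unname(tt$statistic), n1, n2),
    mean_control = mean(rs$rpe_beta[rs$group == "control"]),
    mean_mdd = mean(rs$rpe_beta[rs$group == "mdd"]))

  # VTA-seeded connectivity: Group x Valence (gain/loss) per target
  connectivity_anova <- lapply(
    setNames(nm = unique(ppi_betas$target)), function(tg) {
      d <- ppi_betas[ppi_betas$target == tg &
                       ppi_betas$condition %in% c("gain", "loss"), ]
      names(d)[names(d) == "condition"] <- "valence"
      mixed_anova(d, "beta", "group", "valence")
    })

  # dose-effect partial correlations within MDD (episode length controlled)
  mdd_cov <- covariates[covariates$group == "mdd", ]
  rs_mdd <- rs[match(mdd_cov$subject, rs$subject), ]
  hb <- glm_betas[glm_betas$roi == "habenula", ]
  hb_mdd <- hb[match(mdd_cov$subject, hb$subject), ]
  cor_mde_rs_rpe <- partial_correlation(
    mdd_cov$n_mde, rs_mdd$rpe_beta,
    data.frame(episode_months = mdd_cov$episode_months))
  cor_mde_hb_ppe <- partial_correlation(
    mdd_cov$n_mde, hb_mdd$ppe_beta,
    data.frame(episode_months = mdd_cov$episode_months))

  # VTA RPE vs right-striatal RPE coupling correlation, per group
  vta <- glm_betas[glm_betas$roi == "vta", ]
  stopifnot(identical(vta$subject, rs$subject))
  r_ctl <- cor(vta$rpe_beta[vta$group == "control"],
               rs$rpe_beta[rs$group == "control"])
  r_mdd <- cor(vta$rpe_beta[vta$group == "mdd"],
               rs$rpe_beta[rs$group == "mdd"])
  vta_rs_corr <- c(fisher_z_compare(r_ctl, sum(vta$group == "control"),
                                    r_mdd, sum(vta$group == "mdd")),
                   list(r_control = r_ctl, r_mdd = r_mdd))

  # Table-2-style accuracy block
  acc_rows <- lapply(seq_along(subjects), function(i) {
    tr <- subjects[[i]]$trials
    data.frame(subject = subjects[[i]]$id, group = groups[i],
               t(vapply(TASK_CONDITIONS, function(cc)
                 100 * mean(tr$chose_correct[tr$condition == cc]),
                 numeric(1))), stringsAsFactors = FALSE)
  })
  acc <- do.call(rbind, acc_rows)
  accuracy_table <- do.call(rbind, lapply(split(acc, acc$group),
    function(d) data.frame(group = d$group[1],
                           condition = TASK_CONDITIONS,
                           mean = vapply(TASK_CONDITIONS, function(cc)
                             mean(d[[cc]]), numeric(1)),
                           sd = vapply(TASK_CONDITIONS, function(cc)
                             sd(d[[cc]]), numeric(1)),
                           row.names = NULL)))

  list(learning_curve = lc,
       striatum_anova = striatum_anova,
       right_striatum_anova = right_striatum_anova,
       pe_rois_anova = pe_rois_anova,
       rs_contrast = rs_contrast,
       connectivity_anova = connectivity_anova,
       cor_mde_rs_rpe = cor_mde_rs_rpe,
       cor_mde_hb_ppe = cor_mde_hb_ppe,
       vta_rs_corr = vta_rs_corr,
       accuracy_table = accuracy_table,
       bonferroni = list(roi = bonferroni_adjust(0.05, 5),
                         correlations = bonferroni_adjust(0.05, 10)))
}

write_pipeline_outputs <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, f) utils::write.csv(d, file.path(outdir, f),
                                          row.names = FALSE)
  wcsv(out$accuracy, "accuracy.csv")
  wcsv(out$glm_betas, "glm_betas.csv")
  wcsv(out$ppi_betas, "ppi_betas.csv")
  if (!is.null(out$fits))
    wcsv(data.frame(subject = vapply(Filter(function(s)
      s$id %in% out$exclusion$retained, out$bundle$subjects),
      `[[`, "", "id"),
      do.call(rbind, lapply(out$fits, function(f)
        as.data.frame(unclass(f)[c("alpha_gain_hat", "alpha_loss_hat",
                                   "beta_hat", "nll", "pseudo_R2",
                                   "lr_p")])))), "fits.csv")
  wcsv(as.data.frame(out$stats$striatum_anova), "striatum_anova.csv")
  wcsv(as.data.frame(out$stats$pe_rois_anova), "pe_rois_anova.csv")
  wcsv(out$stats$accuracy_table, "accuracy_table.csv")
  jsonlite::write_json(out$log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(outdir)
}
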