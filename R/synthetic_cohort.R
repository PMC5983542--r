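#' ROI names used throughout the pipeline
#' @keywords internal
ROI_NAMES <- c("right_striatum", "left_striatum", "vta", "habenula",
               "right_insula")

#' Synthetic cohort specification
#'
#' Defines the generative study: 26 controls and 25 depressed (MDD)
#' subjects performing the 3-run task, with planted group effects — a
#' lowered MDD reward learning rate, a halved MDD right-striatal RPE
#' coupling, a reduced MDD VTA-to-right-striatum gain-condition
#' connectivity — and clinical covariates whose moments follow the study
#' sample (BDI, anhedonia/SHAPS, lifetime episode count, episode length).
#' A latent disease-burden factor loads positively on the lifetime-episode
#' count and habenula PPE coupling and negatively on the right-striatal RPE
#' coupling, inducing the planted covariate-coupling correlations
#' (target magnitude ~0.55 with equal loadings of 0.75).
#'
#' @param n_controls,n_mdd Group sizes (defaults 26, 25).
#' @param alpha_gain_mean_control Mean reward learning rate in controls
#'   (default 0.35, Beta-distributed with concentration
#'   `alpha_concentration`).
#' @param alpha_gain_delta_mdd Reduction of the MDD mean reward learning
#'   rate (default 0.25, calibrated so the simulated groups reproduce the
#'   observed reward choice-accuracy contrast of roughly 88\% vs 80\%).
#' @param alpha_loss_mean Mean punishment learning rate, equal across
#'   groups (default 0.40).
#' @param alpha_concentration Beta concentration of subject learning rates
#'   (default 20).
#' @param beta_shape,beta_rate Gamma parameters of the inverse temperature
#'   (defaults 9 and 3: mean 3, sd 1).
#' @param neural_alpha_gain,neural_alpha_loss Fixed learning rates of the
#'   canonical learner that defines the neural PE signal (defaults
#'   0.3, 0.4).
#' @param rpe_coupling,ppe_coupling Named per-ROI mean PE-coupling
#'   coefficients (BOLD a.u. per PE unit).
#' @param mdd_rpe_scale_rs Multiplier on the MDD right-striatal RPE
#'   coupling (default 0.5).
#' @param coupling_sd Between-subject sd of the PE couplings (default 0.3).
#' @param kappa_gain,kappa_loss,kappa_neutral Named per-target mean
#'   VTA-seeded neural connectivity strengths per condition.
#' @param mdd_kappa_gain_scale_rs Multiplier on the MDD VTA-to-right-
#'   striatum gain connectivity (default 0.6).
#' @param kappa_sd Between-subject sd of the connectivity strengths
#'   (default 0.1).
#' @param latent_loading Loading of the disease-burden factor (default
#'   0.75, planting correlations of ~0.75^2 = 0.56 magnitude).
#' @param noise_sd,ar1 BOLD noise innovation sd and AR(1) coefficient
#'   (defaults 1 and 0.3).
#' @param TR Repetition time in seconds (default 2).
#' @param covariate_moments Group means/sds of BDI and SHAPS and the MDD
#'   episode-count and episode-length moments.
#' @param n_mde_missing Number of MDD subjects with a masked (missing)
#'   episode count (default 7).
#' @param task A [task_config()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_controls = 26L, n_mdd = 25L,
                        alpha_gain_mean_control = 0.35,
                        alpha_gain_delta_mdd = 0.25,
                        alpha_loss_mean = 0.40,
                        alpha_concentration = 20,
                        beta_shape = 9, beta_rate = 3,
                        neural_alpha_gain = 0.3, neural_alpha_loss = 0.4,
                        rpe_coupling = c(right_striatum = 1.0,
                                         left_striatum = 1.0, vta = 0.8,
                                         habenula = 0.2, right_insula = 0.4),
                        ppe_coupling = c(right_striatum = 0.5,
                                         left_striatum = 0.5, vta = 0.8,
                                         habenula = 0.8, right_insula = 0.8),
                        mdd_rpe_scale_rs = 0.5,
                        coupling_sd = 0.3,
                        kappa_gain = c(right_striatum = 0.8,
                                       left_striatum = 0.4, habenula = 0.4,
                                       right_insula = 0.4),
                        kappa_loss = c(right_striatum = 0.3,
                                       left_striatum = 0.4, habenula = 0.4,
                                       right_insula = 0.4),
                        kappa_neutral = c(right_striatum = 0.15,
                                          left_striatum = 0.15,
                                          habenula = 0.15,
                                          right_insula = 0.15),
                        mdd_kappa_gain_scale_rs = 0.6,
                        kappa_sd = 0.1,
                        latent_loading = 0.75,
                        noise_sd = 1, ar1 = 0.3, TR = 2,
                        covariate_moments = list(
                          bdi = c(control_mean = 0.44, control_sd = 0.71,
                                  mdd_mean = 26.26, mdd_sd = 9.21),
                          shaps = c(control_mean = 18.6, control_sd = 4.49,
                                    mdd_mean = 33.40, mdd_sd = 4.22),
                          n_mde = c(mean = 3.72, sd = 3.06),
                          episode_months = c(mean = 11.52, sd = 15.41)),
                        n_mde_missing = 7L,
                        task = task_config()) {
  if (n_controls < 2L || n_mdd < 2L)
    stop("group sizes must be >= 2", call. = FALSE)
  if (latent_loading < 0 || latent_loading > 1)
    stop("latent_loading must lie in [0, 1]", call. = FALSE)
  structure(as.list(environment()), class = "cohort_spec")
}

# Beta draw with a given mean and concentration, kept strictly inside (0,1).
rbeta_mean <- function(n, mean, concentration) {
  pmin(pmax(rbeta(n, mean * concentration, (1 - mean) * concentration),
            1e-3), 1 - 1e-3)
}

# Planted seed-by-condition neural interaction for one run: the seed's
# pre-convolution neural signal gated by each condition's scan indicator
# and scaled by that condition's connectivity strength.
ppi_truth_neural <- function(seed_neural, events, kappas, TR, n_scans) {
  u <- numeric(n_scans)
  for (cond in TASK_CONDITIONS) {
    on <- events$onset[events$condition == cond]
    if (length(on) == 0L) next
    ind <- as.numeric(stick_vector(on, rep(1, length(on)), TR, n_scans) > 0)
    u <- u + kappas[[cond]] * seed_neural * ind
  }
  u
}

#' Generate a full synthetic cohort
#'
#' Simulates every subject's behavior (Q-learning agent on a fresh task
#' sequence), ROI BOLD (PE-coupled neural signal convolved with the
#' canonical HRF plus AR(1) noise, with a planted VTA-seeded per-condition
#' connectivity into the target ROIs), and clinical covariates, storing
#' the ground-truth parameters of every generated quantity. Fully
#' reproducible from `(spec, seed)`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer master seed.
#' @return An object of class `cohort_bundle`: `subjects` (list with
#'   `id`, `group`, `trials`, `roi_bold`, `pe`), `covariates` data.frame,
#'   `ground_truth` data.frame (true parameters and couplings per
#'   subject), `spec`, `seed`.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    n <- spec$n_controls + spec$n_mdd
    group <- rep(c("control", "mdd"), c(spec$n_controls, spec$n_mdd))
    ids <- sprintf("sub-%03d", seq_len(n))
    rho <- spec$latent_loading
    resid_load <- sqrt(1 - rho^2)
    mde_missing_idx <- sample(which(group == "mdd"),
                              min(spec$n_mde_missing, spec$n_mdd))
    subjects <- vector("list", n)
    cov_rows <- vector("list", n)
    gt_rows <- vector("list", n)
    for (i in seq_len(n)) {
      g <- group[i]
      is_mdd <- g == "mdd"
      latent <- rnorm(1)                  # disease-burden factor (MDD use)
      a_gain_mean <- spec$alpha_gain_mean_control -
        if (is_mdd) spec$alpha_gain_delta_mdd else 0
      alpha_gain <- rbeta_mean(1, a_gain_mean, spec$alpha_concentration)
      alpha_loss <- rbeta_mean(1, spec$alpha_loss_mean,
                               spec$alpha_concentration)
      beta <- rgamma(1, spec$beta_shape, spec$beta_rate)
      params <- agent_params(alpha_gain, alpha_loss, 0, beta)
      trials <- simulate_subject(params,
                                 generate_trial_sequence(spec$task),
                                 spec$task)
      pe <- compute_pe_series(trials, spec$neural_alpha_gain,
                              spec$neural_alpha_loss)
      # subject PE couplings: group means, latent loadings for the planted
      # dose-effect correlations (MDD only), independent noise otherwise
      rpe_c <- spec$rpe_coupling
      ppe_c <- spec$ppe_coupling
      if (is_mdd)
        rpe_c["right_striatum"] <- rpe_c["right_striatum"] *
          spec$mdd_rpe_scale_rs
      rpe_sub <- ppe_sub <- numeric(length(ROI_NAMES))
      names(rpe_sub) <- names(ppe_sub) <- ROI_NAMES
      for (roi in ROI_NAMES) {
        e1 <- rnorm(1); e2 <- rnorm(1)
        rpe_dev <- if (is_mdd && roi == "right_striatum")
          -rho * latent + resid_load * e1 else e1
        ppe_dev <- if (is_mdd && roi == "habenula")
          rho * latent + resid_load * e2 else e2
        rpe_sub[roi] <- rpe_c[roi] + spec$coupling_sd * rpe_dev
        ppe_sub[roi] <- ppe_c[roi] + spec$coupling_sd * ppe_dev
      }
      # subject VTA-seeded connectivity strengths per condition
      kap <- list(gain = spec$kappa_gain, loss = spec$kappa_loss,
                  neutral = spec$kappa_neutral)
      if (is_mdd)
        kap$gain["right_striatum"] <- kap$gain["right_striatum"] *
          spec$mdd_kappa_gain_scale_rs
      targets <- names(spec$kappa_gain)
      kap_sub <- lapply(kap, function(k)
        k + spec$kappa_sd * rnorm(length(k)))
      # ROI BOLD, run by run
      bold_runs <- vector("list", spec$task$n_runs)
      for (r in seq_len(spec$task$n_runs)) {
        pe_r <- pe[pe$run == r, , drop = FALSE]
        n_scans <- default_n_scans(pe_r$onset, spec$TR)
        vta <- simulate_roi_bold(pe_r, spec$TR, n_scans,
                                 rpe_coupling = rpe_sub["vta"],
                                 ppe_coupling = ppe_sub["vta"],
                                 noise_sd = spec$noise_sd, ar1 = spec$ar1)
        seed_neural <- attr(vta, "neural")
        roi_cols <- list(vta = as.numeric(vta))
        for (roi in targets) {
          kappas <- lapply(kap_sub, function(k) k[[roi]])
          extra <- ppi_truth_neural(seed_neural, pe_r, kappas,
                                    spec$TR, n_scans)
          roi_cols[[roi]] <- as.numeric(
            simulate_roi_bold(pe_r, spec$TR, n_scans,
                              rpe_coupling = rpe_sub[roi],
                              ppe_coupling = ppe_sub[roi],
                              noise_sd = spec$noise_sd, ar1 = spec$ar1,
                              extra_neural = extra))
        }
        bold_runs[[r]] <- data.frame(run = r, scan = seq_len(n_scans),
                                     roi_cols[ROI_NAMES])
      }
      # clinical covariates
      cm <- spec$covariate_moments
      bdi <- if (is_mdd) rnorm(1, cm$bdi["mdd_mean"], cm$bdi["mdd_sd"])
             else max(0, rnorm(1, cm$bdi["control_mean"],
                               cm$bdi["control_sd"]))
      shaps <- rnorm(1, cm$shaps[if (is_mdd) "mdd_mean" else "control_mean"],
                     cm$shaps[if (is_mdd) "mdd_sd" else "control_sd"])
      if (is_mdd) {
        e <- rnorm(1)
        n_mde <- max(0, round(cm$n_mde["mean"] +
                                cm$n_mde["sd"] *
                                (rho * latent + resid_load * e)))
        epi_sdlog <- sqrt(log(1 + (cm$episode_months["sd"] /
                                     cm$episode_months["mean"])^2))
        episode_months <- rlnorm(1, log(cm$episode_months["mean"]) -
                                   epi_sdlog^2 / 2, epi_sdlog)
        if (i %in% mde_missing_idx) n_mde <- NA_real_
      } else {
        n_mde <- NA_real_
        episode_months <- NA_real_
      }
      subjects[[i]] <- list(id = ids[i], group = g, trials = trials,
                            pe = pe,
                            roi_bold = do.call(rbind, bold_runs))
      cov_rows[[i]] <- data.frame(subject = ids[i], group = g, bdi = bdi,
                                  shaps = shaps, n_mde = n_mde,
                                  episode_months = episode_months,
                                  stringsAsFactors = FALSE)
      gt_rows[[i]] <- data.frame(subject = ids[i], group = g,
                                 alpha_gain = alpha_gain,
                                 alpha_loss = alpha_loss, beta = beta,
                                 latent = latent,
                                 t(setNames(rpe_sub,
                                            paste0("rpe_", ROI_NAMES))),
                                 t(setNames(ppe_sub,
                                            paste0("ppe_", ROI_NAMES))),
                                 t(unlist(lapply(names(kap_sub),
                                   function(cc)
                                     setNames(kap_sub[[cc]],
                                              paste0("kappa_", cc, "_",
                                                     names(kap_sub[[cc]])))))),
                                 stringsAsFactors = FALSE)
    }
    gt <- do.call(rbind, gt_rows)
    structure(list(subjects = subjects,
                   covariates = do.call(rbind, cov_rows),
                   ground_truth = gt,
                   spec = spec, seed = seed),
              class = "cohort_bundle")
  })
}

#' Write / read a cohort bundle as plain-text files
#'
#' Writes one events TSV per subject and run, one ROI time-series CSV per
#' subject (one column per ROI plus `run` and `scan`), a covariates CSV
#' and a ground-truth JSON file.
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly (writer); a reconstructed bundle without
#'   `pe` series (reader; recompute with [compute_pe_series()]).
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in bundle$subjects) {
    for (r in unique(s$trials$run))
      write_events_tsv(s$trials[s$trials$run == r, ],
                       file.path(dir, sprintf("%s_run-%d_events.tsv",
                                              s$id, r)))
    utils::write.csv(s$roi_bold,
                     file.path(dir, paste0(s$id, "_roi_bold.csv")),
                     row.names = FALSE)
  }
  utils::write.csv(bundle$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  jsonlite::write_json(bundle$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       digits = NA, dataframe = "columns")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  covariates <- utils::read.csv(file.path(dir, "covariates.csv"),
                                stringsAsFactors = FALSE)
  subjects <- lapply(covariates$subject, function(id) {
    ev <- list.files(dir, sprintf("^%s_run-\\d+_events\\.tsv$", id),
                     full.names = TRUE)
    trials <- do.call(rbind, lapply(sort(ev), read_events_tsv))
    list(id = id, group = covariates$group[covariates$subject == id],
         trials = trials,
         roi_bold = utils::read.csv(
           file.path(dir, paste0(id, "_roi_bold.csv")),
           stringsAsFactors = FALSE))
  })
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path))
    as.data.frame(jsonlite::read_json(gt_path, simplifyVector = TRUE))
  else NULL
  structure(list(subjects = subjects, covariates = covariates,
                 ground_truth = gt, spec = NULL, seed = NULL),
            class = "cohort_bundle")
}
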