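# One small completed run shared by several fixtures
glm_fixture_pe <- function(seed = 71, tpc = 20) {
  cfg <- task_config(n_runs = 1, trials_per_condition_per_run = tpc)
  rec <- simulate_subject(agent_params(0.3, 0.4, 0, 3),
                          generate_trial_sequence(cfg, seed), cfg,
                          seed = seed + 1)
  compute_pe_series(rec, 0.3, 0.4)
}

test_that("canonical HRF starts at zero, peaks at 1 near 5 s", {
  k <- canonical_hrf(hrf_spec(dt = 0.01))
  expect_equal(k$h[1], 0)
  expect_equal(max(k$h), 1)
  expect_lt(abs(k$t[which.max(k$h)] - 5), 0.15)
  expect_gt(sum(k$h) * 0.01, 0)      # integrates to a positive value
  expect_error(hrf_spec(peak_disp = 0), "positive")
  expect_error(hrf_spec(dt = -1), "positive")
})

test_that("design matrix centers modulators and handles empty conditions", {
  pe <- glm_fixture_pe()
  X <- build_design_matrix(pe)
  expect_named(as.data.frame(X$X),
               c("gain_onset", "gain_pe", "loss_onset", "loss_pe",
                 "neutral_onset", "neutral_pe", "intercept"))
  # pre-convolution centering: a constant modulator must vanish entirely
  pe_const <- pe
  pe_const$rpe[pe_const$condition == "gain"] <- 0.7
  Xc <- build_design_matrix(pe_const)
  expect_true(all(abs(Xc$X[, "gain_pe"]) < 1e-12))
  gain_only <- pe[pe$condition == "gain", ]
  X2 <- build_design_matrix(gain_only)
  expect_setequal(X2$empty_conditions, c("loss", "neutral"))
  expect_true(all(X2$X[, "loss_onset"] == 0))
})

test_that("a unit impulse reproduces the sampled HRF kernel", {
  pe <- data.frame(run = 1, condition = c("gain", "gain"),
                   onset = c(0, 200), q_chosen = 0, pe_raw = c(1, -1),
                   rpe = c(1, -1), ppe = NA_real_)
  X <- build_design_matrix(pe, TR = 2, n_scans = 150)
  h <- canonical_hrf(hrf_spec(dt = 2))$h
  # first event has centered modulator +1: its segment is the kernel
  expect_equal(X$X[seq_along(h), "gain_pe"], h, tolerance = 1e-12)
})

test_that("duplicate onsets are rejected", {
  pe <- data.frame(run = 1, condition = "gain", onset = c(10, 10),
                   q_chosen = 0, pe_raw = c(1, 0.5), rpe = c(1, 0.5),
                   ppe = NA_real_)
  expect_error(build_design_matrix(pe, n_scans = 40), "duplicate")
})

test_that("convolution is linear in the event set", {
  pe <- glm_fixture_pe()
  half1 <- pe[seq(1, nrow(pe), 2), ]
  half2 <- pe[seq(2, nrow(pe), 2), ]
  n <- pelearn:::default_n_scans(pe$onset, 2)
  col <- function(d) {
    on <- d$onset[d$condition == "gain"]
    pelearn:::convolve_scan(
      pelearn:::stick_vector(on, rep(1, length(on)), 2, n),
      pelearn:::hrf_kernel_tr(2))
  }
  expect_equal(col(pe), col(half1) + col(half2), tolerance = 1e-10)
})

test_that("noiseless GLM recovers coefficients to machine precision", {
  pe <- glm_fixture_pe()
  X <- build_design_matrix(pe)
  keep <- colSums(abs(X$X)) > 0
  b_true <- seq_len(sum(keep)) / 10
  y <- as.numeric(X$X[, keep] %*% b_true)
  fit <- fit_glm(y, X)
  expect_equal(fit$coefficients$beta[keep], b_true, tolerance = 1e-9)
  expect_equal(fit$df, X$n_scans - sum(keep))
  expect_error(fit_glm(y[-1], X), "scans")
})

test_that("rank-deficient designs name the collinear columns", {
  X <- cbind(a = rnorm(30), b = 1:30, c = 2 * (1:30))
  expect_error(fit_glm(rnorm(30), X), "c")
})

test_that("OLS confidence intervals attain nominal coverage", {
  set.seed(73)
  n <- 60
  X <- cbind(x = rnorm(n), intercept = 1)
  covered <- replicate(1000, {
    y <- 2 * X[, "x"] + rnorm(n)
    f <- fit_glm(y, X)
    ci <- f$coefficients$beta[1] +
      c(-1, 1) * qt(0.975, f$df) * f$coefficients$se[1]
    ci[1] <= 2 && 2 <= ci[2]
  })
  expect_lt(abs(mean(covered) - 0.95), 0.02)
})

test_that("GLM t statistics are t distributed under the null", {
  pe <- glm_fixture_pe()
  X <- build_design_matrix(pe)
  set.seed(79)
  tstats <- replicate(1000, {
    f <- fit_glm(rnorm(X$n_scans), X)
    f$coefficients$t[f$coefficients$term == "gain_pe"]
  })
  df <- X$n_scans - sum(colSums(abs(X$X)) > 0)
  ks <- suppressWarnings(ks.test(tstats, pt, df = df))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted BOLD couplings are recovered by the GLM", {
  pe <- glm_fixture_pe(seed = 83, tpc = 40)
  X <- build_design_matrix(pe)
  recover <- function(coupling, nseeds) {
    mean(vapply(seq_len(nseeds), function(s) {
      y <- simulate_roi_bold(pe, rpe_coupling = coupling, noise_sd = 1,
                             seed = 1000 + s)
      glm_beta <- fit_glm(as.numeric(y), X)$coefficients
      glm_beta$beta[glm_beta$term == "gain_pe"]
    }, numeric(1)))
  }
  expect_lt(abs(recover(0, 150)), 0.02)
  expect_lt(abs(recover(1, 150) - 1), 0.05)
  y1 <- simulate_roi_bold(pe, rpe_coupling = 1, noise_sd = 1, ar1 = 0.3,
                          seed = 4)
  y2 <- simulate_roi_bold(pe, rpe_coupling = 1, noise_sd = 1, ar1 = 0.3,
                          seed = 4)
  expect_identical(as.numeric(y1), as.numeric(y2))
})

test_that("ridge deconvolution inverts convolution on smooth signals", {
  n <- 200
  u <- sin(seq(0, 6 * pi, length.out = n)) +
    0.5 * cos(seq(0, 2 * pi, length.out = n))
  C <- pelearn:::conv_matrix(n, 2)
  y <- as.numeric(C %*% u)
  uh <- pelearn:::deconvolve_bold(y, 2)
  # the last kernel-length of samples is unidentifiable under causal
  # convolution (h(0) = 0), so the identity holds on the interior
  idx <- seq_len(n - 16)
  expect_lt(sqrt(sum((uh[idx] - u[idx])^2) / sum(u[idx]^2)), 0.05)
})

test_that("gPPI interaction columns follow their definitions", {
  pe <- glm_fixture_pe(seed = 89)
  n <- pelearn:::default_n_scans(pe$onset, 2)
  ev <- pe[pe$condition != "neutral", ]  # no neutral events
  y_seed <- simulate_roi_bold(ev, n_scans = n, noise_sd = 0.1, seed = 5)
  X <- build_gppi_design(as.numeric(y_seed), ev, TR = 2)
  expect_true(all(X$X[, "neutral_ppi"] == 0))
  # constant seed neural signal: interaction proportional to psych column
  # (interior scans; the causal window's tail is unidentifiable)
  C <- pelearn:::conv_matrix(n, 2)
  y_const <- as.numeric(C %*% rep(1, n))
  Xc <- build_gppi_design(y_const, ev, TR = 2, lambda = 1e-8)
  keep <- abs(Xc$X[, "gain_psych"]) > 0.05 & seq_len(n) <= n - 17
  ratio <- Xc$X[keep, "gain_ppi"] / Xc$X[keep, "gain_psych"]
  expect_lt(diff(range(ratio)), 1e-4)
})

test_that("planted condition-specific connectivity is recovered", {
  pe <- glm_fixture_pe(seed = 97, tpc = 40)
  n <- pelearn:::default_n_scans(pe$onset, 2)
  betas <- t(vapply(1:100, function(s) {
    seed_bold <- simulate_roi_bold(pe, n_scans = n, rpe_coupling = 0.8,
                                   ppe_coupling = 0.8, noise_sd = 0.2,
                                   seed = 300 + s)
    extra <- pelearn:::ppi_truth_neural(
      attr(seed_bold, "neural"), pe,
      list(gain = 0.8, loss = 0, neutral = 0), 2, n)
    target <- simulate_roi_bold(pe, n_scans = n, rpe_coupling = 0.3,
                                ppe_coupling = 0.3, noise_sd = 0.2,
                                seed = 700 + s, extra_neural = extra)
    res <- fit_gppi(as.numeric(target),
                    build_gppi_design(as.numeric(seed_bold), pe, TR = 2))
    setNames(res$beta, res$condition)
  }, c(gain = 0, loss = 0, neutral = 0)))
  expect_gte(mean(betas[, "gain"] > 0 & betas[, "gain"] > betas[, "loss"]),
             0.95)
  expect_lt(abs(mean(betas[, "loss"])), 0.15)
})

test_that("symmetric couplings leave no gain/loss asymmetry", {
  pe <- glm_fixture_pe(seed = 101)
  n <- pelearn:::default_n_scans(pe$onset, 2)
  diffs <- vapply(1:60, function(s) {
    seed_bold <- simulate_roi_bold(pe, n_scans = n, rpe_coupling = 0.5,
                                   ppe_coupling = 0.5, noise_sd = 0.3,
                                   seed = 40 + s)
    extra <- pelearn:::ppi_truth_neural(
      attr(seed_bold, "neural"), pe,
      list(gain = 0.5, loss = 0.5, neutral = 0.5), 2, n)
    target <- simulate_roi_bold(pe, n_scans = n, noise_sd = 0.3,
                                seed = 900 + s, extra_neural = extra)
    res <- fit_gppi(as.numeric(target),
                    build_gppi_design(as.numeric(seed_bold), pe, TR = 2))
    res$beta[res$condition == "gain"] - res$beta[res$condition == "loss"]
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)) + 0.05)
})
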