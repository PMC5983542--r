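#' Canonical double-gamma HRF specification
#'
#' Parameters of the canonical hemodynamic response function: a gamma
#' density peaking ~5 s after the event minus a scaled gamma undershoot.
#' Shapes are `delay / dispersion` as in the conventional parameterization.
#'
#' @param peak_delay,undershoot_delay Delays in seconds (defaults 6, 16).
#' @param peak_disp,undershoot_disp Dispersions in seconds (defaults 1, 1).
#' @param undershoot_ratio Relative undershoot amplitude (default 1/6).
#' @param duration Kernel support in seconds (default 32).
#' @param dt Sampling step in seconds (default 0.1).
#' @return An object of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_delay = 6, undershoot_delay = 16,
                     peak_disp = 1, undershoot_disp = 1,
                     undershoot_ratio = 1 / 6,
                     duration = 32, dt = 0.1) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (peak_disp <= 0 || undershoot_disp <= 0)
    stop("dispersions must be positive", call. = FALSE)
  structure(list(peak_delay = peak_delay,
                 undershoot_delay = undershoot_delay,
                 peak_disp = peak_disp, undershoot_disp = undershoot_disp,
                 undershoot_ratio = undershoot_ratio,
                 duration = duration, dt = dt),
            class = "hrf_spec")
}

#' Sample the canonical HRF kernel
#'
#' Double-gamma difference sampled on `seq(0, duration, by = dt)` and
#' peak-normalized to 1. The kernel is 0 at t = 0 and integrates to a
#' positive value.
#'
#' @param spec An [hrf_spec()].
#' @return List with `t` (seconds) and `h` (kernel values).
#' @export
canonical_hrf <- function(spec = hrf_spec()) {
  stopifnot(inherits(spec, "hrf_spec"))
  t <- seq(0, spec$duration, by = spec$dt)
  h <- stats::dgamma(t, shape = spec$peak_delay / spec$peak_disp,
                     scale = spec$peak_disp) -
    spec$undershoot_ratio *
    stats::dgamma(t, shape = spec$undershoot_delay / spec$undershoot_disp,
                  scale = spec$undershoot_disp)
  h <- h / max(h)
  list(t = t, h = h)
}

# Kernel sampled on the scan grid (t = 0, TR, 2 TR, ...).
hrf_kernel_tr <- function(TR, spec = hrf_spec()) {
  spec$dt <- TR
  canonical_hrf(spec)$h
}

# Stick (impulse) vector on the scan grid: each event's amplitude is added
# at the scan bin nearest its onset. Regressor construction and the BOLD
# generator share this so planted effects are exactly representable.
stick_vector <- function(onsets, amplitudes, TR, n_scans) {
  if (any(onsets < 0) || any(onsets >= n_scans * TR))
    stop("event onsets must lie within the scan window", call. = FALSE)
  bins <- pmin(pmax(round(onsets / TR) + 1L, 1L), n_scans)
  u <- numeric(n_scans)
  for (i in seq_along(bins)) u[bins[i]] <- u[bins[i]] + amplitudes[i]
  u
}

# Causal convolution of a scan-grid signal with a kernel, truncated to
# n_scans samples.
convolve_scan <- function(u, kernel) {
  convolve(u, rev(kernel), type = "open")[seq_along(u)]
}

# Lower-triangular Toeplitz operator of the scan-grid HRF: y = C %*% neural.
conv_matrix <- function(n_scans, TR, spec = hrf_spec()) {
  h <- hrf_kernel_tr(TR, spec)
  C <- matrix(0, n_scans, n_scans)
  for (k in seq_along(h)) {
    idx <- seq_len(n_scans - k + 1)
    C[cbind(idx + k - 1, idx)] <- h[k]
  }
  C
}

pe_modulator <- function(pe) {
  switch(unique(pe$condition)[1],
         gain = pe$rpe, loss = pe$ppe, neutral = pe$pe_raw)
}

#' Build a first-level design matrix with PE parametric modulators
#'
#' For each condition, an onset regressor (impulse train at feedback
#' onsets convolved with the HRF) and a parametric-modulator regressor
#' (impulses scaled by the condition's mean-centered prediction error,
#' convolved with the HRF): the gain-condition modulator is the RPE, the
#' loss-condition modulator the sign-flipped PPE, the neutral modulator the
#' raw PE. Modulators are mean-centered per condition before convolution,
#' with no further orthogonalization. An intercept column is appended.
#'
#' @param pe A `pe_series` from [compute_pe_series()] for one run.
#' @param TR Repetition time in seconds (default 2).
#' @param n_scans Number of scans; defaults to covering all events plus a
#'   24 s tail.
#' @param spec An [hrf_spec()].
#' @return An object of class `design_matrix`: `X` (n_scans x columns),
#'   `TR`, `n_scans`, `empty_conditions`.
#' @export
build_design_matrix <- function(pe, TR = 2, n_scans = NULL,
                                spec = hrf_spec()) {
  if (is.null(n_scans)) n_scans <- default_n_scans(pe$onset, TR)
  if (any(pe$onset >= n_scans * TR))
    stop("all onsets must precede the end of the scan window", call. = FALSE)
  h <- hrf_kernel_tr(TR, spec)
  cols <- list()
  empty <- character(0)
  for (cond in TASK_CONDITIONS) {
    sub <- pe[pe$condition == cond, , drop = FALSE]
    if (nrow(sub) == 0L) {
      empty <- c(empty, cond)
      cols[[paste0(cond, "_onset")]] <- numeric(n_scans)
      cols[[paste0(cond, "_pe")]] <- numeric(n_scans)
      next
    }
    if (anyDuplicated(sub$onset))
      stop("duplicate event onsets in condition ", cond, call. = FALSE)
    mod <- pe_modulator(sub)
    mod <- mod - mean(mod)
    cols[[paste0(cond, "_onset")]] <-
      convolve_scan(stick_vector(sub$onset, rep(1, nrow(sub)), TR, n_scans), h)
    cols[[paste0(cond, "_pe")]] <-
      convolve_scan(stick_vector(sub$onset, mod, TR, n_scans), h)
  }
  cols$intercept <- rep(1, n_scans)
  X <- do.call(cbind, cols)
  structure(list(X = X, TR = TR, n_scans = n_scans,
                 empty_conditions = empty),
            class = "design_matrix")
}

default_n_scans <- function(onsets, TR) as.integer(ceiling((max(onsets) + 24) / TR))

design_X <- function(X) {
  if (inherits(X, "design_matrix")) X$X else as.matrix(X)
}

#' Ordinary least-squares GLM on an ROI time series
#'
#' @param y Numeric BOLD vector, length `n_scans`.
#' @param X A `design_matrix` or plain numeric matrix with column names.
#' @return An object of class `glm_result`: `coefficients` data.frame
#'   (`term`, `beta`, `se`, `t`), `df`, `sigma2`.
#' @export
fit_glm <- function(y, X) {
  M <- design_X(X)
  if (length(y) != nrow(M))
    stop("length(y) must equal the number of scans (",
         nrow(M), "), got ", length(y), call. = FALSE)
  keep <- colSums(abs(M)) > 0          # all-zero columns (empty conditions)
  Mk <- M[, keep, drop = FALSE]
  qr_x <- qr(Mk)
  if (qr_x$rank < ncol(Mk)) {
    bad <- colnames(Mk)[qr_x$pivot[(qr_x$rank + 1):ncol(Mk)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- lm.fit(Mk, y)
  df <- length(y) - qr_x$rank
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- solve(crossprod(Mk))
  se <- sqrt(sigma2 * diag(XtXinv))
  beta <- fit$coefficients
  coefs <- data.frame(term = colnames(M), beta = NA_real_, se = NA_real_,
                      t = NA_real_, stringsAsFactors = FALSE)
  coefs$beta[keep] <- beta
  coefs$se[keep] <- se
  coefs$t[keep] <- beta / se
  structure(list(coefficients = coefs, df = df, sigma2 = sigma2),
            class = "glm_result")
}

glm_beta <- function(fit, term) {
  fit$coefficients$beta[match(term, fit$coefficients$term)]
}

# Pre-convolution neural signal on the scan grid for one run: condition
# onset amplitudes plus PE couplings times the mean-centered modulators.
neural_signal <- function(pe, TR, n_scans,
                          rpe_coupling = 0, ppe_coupling = 0,
                          onset_amplitudes = c(gain = 1, loss = 1,
                                               neutral = 1)) {
  u <- numeric(n_scans)
  for (cond in TASK_CONDITIONS) {
    sub <- pe[pe$condition == cond, , drop = FALSE]
    if (nrow(sub) == 0L) next
    u <- u + stick_vector(sub$onset,
                          rep(onset_amplitudes[[cond]], nrow(sub)),
                          TR, n_scans)
    coup <- switch(cond, gain = rpe_coupling, loss = ppe_coupling, 0)
    if (coup != 0) {
      mod <- pe_modulator(sub)
      mod <- mod - mean(mod)
      u <- u + coup * stick_vector(sub$onset, mod, TR, n_scans)
    }
  }
  u
}

#' Simulate an ROI BOLD time series with planted PE coupling
#'
#' Builds a neural signal on the scan grid — condition onset amplitudes
#' plus `rpe_coupling` (gain trials) and `ppe_coupling` (loss trials) times
#' the mean-centered PE modulators, plus any `extra_neural` component (used
#' for planted seed-by-condition connectivity) — convolves it with the
#' canonical HRF, and adds AR(1) Gaussian noise.
#'
#' @param pe A `pe_series` for one run.
#' @param TR,n_scans Scan grid (defaults as in [build_design_matrix()]).
#' @param rpe_coupling,ppe_coupling Planted modulator coefficients.
#' @param onset_amplitudes Named per-condition event amplitudes.
#' @param noise_sd Innovation standard deviation of the AR(1) noise.
#' @param ar1 AR(1) coefficient in \[0, 1).
#' @param seed Integer seed (`NULL` consumes the current RNG stream).
#' @param extra_neural Optional scan-grid vector added to the neural signal
#'   before convolution.
#' @param spec An [hrf_spec()].
#' @return Numeric BOLD vector of length `n_scans`, with the pre-convolution
#'   neural signal attached as attribute `"neural"`.
#' @export
simulate_roi_bold <- function(pe, TR = 2, n_scans = NULL,
                              rpe_coupling = 0, ppe_coupling = 0,
                              onset_amplitudes = c(gain = 1, loss = 1,
                                                   neutral = 1),
                              noise_sd = 1, ar1 = 0, seed = NULL,
                              extra_neural = NULL, spec = hrf_spec()) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (ar1 < 0 || ar1 >= 1) stop("ar1 must lie in [0, 1)", call. = FALSE)
  if (is.null(n_scans)) n_scans <- default_n_scans(pe$onset, TR)
  u <- neural_signal(pe, TR, n_scans, rpe_coupling, ppe_coupling,
                     onset_amplitudes)
  if (!is.null(extra_neural)) u <- u + extra_neural
  y <- convolve_scan(u, hrf_kernel_tr(TR, spec))
  with_seed(seed, {
    if (noise_sd > 0) {
      eps <- rnorm(n_scans, sd = noise_sd)
      if (ar1 > 0) eps <- as.numeric(stats::filter(eps, ar1,
                                                   method = "recursive"))
      y <- y + eps
    }
    structure(y, neural = u)
  })
}

.op_cache <- new.env(parent = emptyenv())

# Ridge deconvolution operator M = (C'C + lambda I)^-1 C' for the scan-grid
# HRF convolution C, cached per (n_scans, TR, lambda, HRF). lambda defaults
# to 0.1 times the mean diagonal of C'C (0.1 trace scaling).
ridge_deconv_operator <- function(n_scans, TR, spec = hrf_spec(),
                                  lambda = NULL) {
  key <- paste(n_scans, TR, if (is.null(lambda)) "def" else lambda,
               paste(unlist(spec), collapse = ","), sep = "|")
  cached <- .op_cache[[key]]
  if (!is.null(cached)) return(cached)
  C <- conv_matrix(n_scans, TR, spec)
  CtC <- crossprod(C)
  if (is.null(lambda)) lambda <- 0.1 * mean(diag(CtC))
  A <- CtC + diag(lambda, n_scans)
  # min eigenvalue >= lambda, so the row-sum norm over lambda bounds the
  # condition number from above
  cond_bound <- max(rowSums(abs(A))) / lambda
  if (!is.finite(cond_bound) || cond_bound > 1e10)
    stop("deconvolution ill-conditioned (condition number bound ",
         format(cond_bound, digits = 3), ")", call. = FALSE)
  op <- list(M = solve(A, t(C)), C = C, lambda = lambda)
  .op_cache[[key]] <- op
  op
}

# Ridge deconvolution of a BOLD series: neural = M %*% y.
deconvolve_bold <- function(y, TR, spec = hrf_spec(), lambda = NULL) {
  op <- ridge_deconv_operator(length(y), TR, spec, lambda)
  as.numeric(op$M %*% y)
}

#' Build a generalized-PPI design matrix
#'
#' Columns: per-condition psychological regressors (HRF-convolved event
#' trains), the physiological seed time series, and per-condition
#' interaction terms formed at the neural level — the seed is ridge-
#' deconvolved against the HRF operator, multiplied by the condition's
#' scan-grid indicator, and re-convolved — plus an intercept.
#'
#' @param seed_bold Seed-ROI BOLD vector (length `n_scans`).
#' @param events Event table with `condition` and `onset` for the run.
#' @param TR Repetition time (default 2).
#' @param spec An [hrf_spec()].
#' @param lambda Ridge penalty for the deconvolution (default 0.1 times the
#'   mean diagonal of the convolution Gram matrix).
#' @return A `design_matrix` with columns `<cond>_psych`, `seed_physio`,
#'   `<cond>_ppi`, `intercept`.
#' @export
build_gppi_design <- function(seed_bold, events, TR = 2,
                              spec = hrf_spec(), lambda = NULL) {
  n_scans <- length(seed_bold)
  if (any(events$onset >= n_scans * TR))
    stop("event onsets must lie within the seed series", call. = FALSE)
  h <- hrf_kernel_tr(TR, spec)
  op <- ridge_deconv_operator(n_scans, TR, spec, lambda)
  C <- op$C
  neural_seed <- as.numeric(op$M %*% seed_bold)
  cols <- list()
  for (cond in TASK_CONDITIONS) {
    on <- events$onset[events$condition == cond]
    ind <- as.numeric(stick_vector(on, rep(1, length(on)), TR, n_scans) > 0)
    cols[[paste0(cond, "_psych")]] <- convolve_scan(ind, h)
    cols[[paste0(cond, "_ppi")]] <- as.numeric(C %*% (neural_seed * ind))
  }
  cols$seed_physio <- as.numeric(seed_bold)
  cols$intercept <- rep(1, n_scans)
  X <- do.call(cbind, cols[c(paste0(TASK_CONDITIONS, "_psych"),
                             "seed_physio",
                             paste0(TASK_CONDITIONS, "_ppi"),
                             "intercept")])
  structure(list(X = X, TR = TR, n_scans = n_scans,
                 empty_conditions = character(0)),
            class = "design_matrix")
}

#' Fit the gPPI model to a target ROI
#'
#' Ordinary least squares of the target BOLD on the gPPI design; the
#' per-condition interaction coefficients are the condition-specific
#' seed-target connectivity values, with the psychological and
#' physiological main effects partialed out.
#'
#' @param target_bold Target-ROI BOLD vector.
#' @param ppi_design Design from [build_gppi_design()].
#' @return An object of class `ppi_result`: data.frame with `condition`,
#'   `beta`, `se`, `t`.
#' @export
fit_gppi <- function(target_bold, ppi_design) {
  fit <- fit_glm(target_bold, ppi_design)
  cf <- fit$coefficients
  ppi <- cf[grepl("_ppi$", cf$term), ]
  out <- data.frame(condition = sub("_ppi$", "", ppi$term),
                    beta = ppi$beta, se = ppi$se, t = ppi$t,
                    stringsAsFactors = FALSE)
  class(out) <- c("ppi_result", "data.frame")
  out
}
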