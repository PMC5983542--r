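condition_codes <- c(gain = 0L, loss = 1L, neutral = 2L)

#' Negative log-likelihood of a subject's choices
#'
#' Walks the Q-learning recursion along the subject's actual choices and
#' outcomes (values reset at run boundaries, only the chosen stimulus
#' updated) and accumulates -log softmax probability of each observed
#' choice. Gain, loss and neutral trials all contribute; under 0-coded
#' neutral outcomes each neutral trial contributes ln 2. Probabilities are
#' clamped to \[1e-12, 1 - 1e-12\] against underflow.
#'
#' @param params An [agent_params()].
#' @param record Completed trial data.frame.
#' @return Negative log-likelihood in nats.
#' @export
negative_log_likelihood <- function(params, record) {
  stopifnot(inherits(params, "agent_params"))
  if (nrow(record) == 0L) stop("empty trial record", call. = FALSE)
  if (any(is.na(record$chose_correct)))
    stop("record contains unfilled choices", call. = FALSE)
  qlik_nll_cpp(condition_codes[record$condition],
               as.integer(record$chose_correct),
               record$outcome, as.integer(record$run),
               params$alpha_gain, params$alpha_loss, params$alpha_neutral,
               params$beta)
}

#' Compare a fitted model against the chance model
#'
#' The chance model (beta = 0) predicts every choice at probability 1/2, so
#' its negative log-likelihood is `n_trials * ln 2`. Reports the
#' likelihood-ratio statistic 2 (nll_chance - nll) against a chi-square
#' with `k_free_params` degrees of freedom, and the pseudo-R2
#' 1 - nll / nll_chance.
#'
#' @param nll Fitted negative log-likelihood (nats).
#' @param n_trials Number of choices entering the likelihood.
#' @param k_free_params Free parameters of the fitted model (default 3:
#'   alpha_gain, alpha_loss, shared beta).
#' @return List with `nll_chance`, `pseudo_R2`, `lr_statistic`, `lr_p`.
#' @export
chance_comparison <- function(nll, n_trials, k_free_params = 3L) {
  if (n_trials <= 0) stop("n_trials must be positive", call. = FALSE)
  nll_chance <- n_trials * log(2)
  if (nll > nll_chance + 1e-8)
    warning("nll exceeds chance nll; optimizer may have failed",
            call. = FALSE)
  lr <- 2 * (nll_chance - nll)
  list(nll_chance = nll_chance,
       pseudo_R2 = 1 - nll / nll_chance,
       lr_statistic = lr,
       lr_p = pchisq(max(lr, 0), df = k_free_params, lower.tail = FALSE))
}

#' Maximum-likelihood fit of the Q-learning model to one subject
#'
#' Bounded L-BFGS-B optimization of (alpha_gain, alpha_loss, beta) from a
#' fixed deterministic grid of starting points; the best local optimum is
#' returned, ties broken by lower negative log-likelihood then lower beta.
#' The neutral learning rate is fixed at 0 (neutral outcomes carry no
#' value signal), so the model has 3 free parameters. Refitting an
#' identical record is bit-identical (no unseeded randomness).
#'
#' When the fitted beta is near zero the likelihood is flat in alpha; the
#' result carries `alpha_identifiable = FALSE` when the numerical alpha
#' gradient at the optimum is below tolerance.
#'
#' @param record Completed trial data.frame for one subject.
#' @param alpha_bounds,beta_bounds Box constraints (defaults \[0,1\] and
#'   \[0,20\]).
#' @param alpha_starts,beta_starts Deterministic start grids; starts use
#'   alpha_gain = alpha_loss = each alpha start crossed with each beta
#'   start.
#' @return An object of class `fit_result`: `alpha_gain_hat`,
#'   `alpha_loss_hat`, `beta_hat`, `nll`, `nll_chance`, `pseudo_R2`,
#'   `lr_statistic`, `lr_p`, `n_trials`, `alpha_identifiable`.
#' @export
fit_subject <- function(record,
                        alpha_bounds = c(0, 1),
                        beta_bounds = c(0, 20),
                        alpha_starts = seq(0.1, 0.9, by = 0.2),
                        beta_starts = c(0.5, 2, 5, 10)) {
  cond <- condition_codes[record$condition]
  chose <- as.integer(record$chose_correct)
  out <- record$outcome
  run <- as.integer(record$run)
  obj <- function(par)
    qlik_nll_cpp(cond, chose, out, run, par[1], par[2], 0, par[3])
  lower <- c(alpha_bounds[1], alpha_bounds[1], beta_bounds[1])
  upper <- c(alpha_bounds[2], alpha_bounds[2], beta_bounds[2])
  best <- NULL
  fails <- character(0)
  for (a0 in alpha_starts) for (b0 in beta_starts) {
    res <- tryCatch(
      optim(c(a0, a0, b0), obj, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(factr = 1e-8 / .Machine$double.eps)),
      error = function(e) e)
    if (inherits(res, "error")) {
      fails <- c(fails, conditionMessage(res))
      next
    }
    if (is.null(best) ||
        res$value < best$value - 1e-10 ||
        (abs(res$value - best$value) <= 1e-10 && res$par[3] < best$par[3]))
      best <- res
  }
  if (is.null(best))
    stop("all optimizer starts failed: ",
         paste(unique(fails), collapse = "; "), call. = FALSE)
  n_trials <- nrow(record)
  cc <- chance_comparison(best$value, n_trials, k_free_params = 3L)
  # numerical alpha gradients at the optimum; flat alpha axis => unidentifiable
  h <- 1e-5
  g <- vapply(1:2, function(i) {
    p1 <- best$par; p2 <- best$par
    p1[i] <- min(p1[i] + h, upper[i]); p2[i] <- max(p2[i] - h, lower[i])
    (obj(p1) - obj(p2)) / (p1[i] - p2[i])
  }, numeric(1))
  structure(list(alpha_gain_hat = best$par[1],
                 alpha_loss_hat = best$par[2],
                 beta_hat = best$par[3],
                 nll = best$value,
                 nll_chance = cc$nll_chance,
                 pseudo_R2 = cc$pseudo_R2,
                 lr_statistic = cc$lr_statistic,
                 lr_p = cc$lr_p,
                 n_trials = n_trials,
                 alpha_identifiable = !(best$par[3] < 0.05 &&
                                          max(abs(g)) < 1e-3)),
            class = "fit_result")
}

#' Pool learning rates across subjects
#'
#' Arithmetic mean of the per-subject maximum-likelihood learning rates for
#' one valence, across all retained subjects of both groups; the pooled
#' values are fed, fixed, to [compute_pe_series()] for the fMRI stage.
#'
#' @param fits List of `fit_result` objects.
#' @param valence `"gain"` or `"loss"`.
#' @return The pooled (mean) learning rate.
#' @export
pooled_alpha <- function(fits, valence = c("gain", "loss")) {
  valence <- match.arg(valence)
  if (length(fits) == 0L) stop("empty fit list", call. = FALSE)
  field <- paste0("alpha_", valence, "_hat")
  mean(vapply(fits, function(f) f[[field]], numeric(1)))
}

#' Fixed-learning-rate prediction-error series
#'
#' Recomputes the Q recursion from zero along a subject's actual choices
#' and outcomes using fixed, cohort-level learning rates (one per valence),
#' and derives the signed prediction-error regressors used for fMRI:
#' on gain trials `rpe = outcome - Q` (positive for unexpected reward); on
#' loss trials `ppe = -(outcome - Q)` (positive for unexpected punishment,
#' so a positive fitted coefficient means greater activation to unexpected
#' punishment). Neutral trials carry the raw prediction error, identically
#' zero under 0-coded outcomes.
#'
#' @param record Completed trial data.frame for one subject.
#' @param alpha_fixed_gain,alpha_fixed_loss Fixed learning rates in \[0,1\].
#' @return A data.frame (class `pe_series`) with `run`, `condition`,
#'   `onset`, `q_chosen` (before update), `pe_raw`, `rpe` (NA off gain
#'   trials), `ppe` (NA off loss trials).
#' @export
compute_pe_series <- function(record, alpha_fixed_gain = 0.3,
                              alpha_fixed_loss = 0.4) {
  if (any(c(alpha_fixed_gain, alpha_fixed_loss) < 0) ||
      any(c(alpha_fixed_gain, alpha_fixed_loss) > 1))
    stop("fixed alphas must lie in [0, 1]", call. = FALSE)
  if (any(is.na(record$chose_correct)))
    stop("record contains unfilled choices", call. = FALSE)
  params <- agent_params(alpha_fixed_gain, alpha_fixed_loss, 0, beta = 0)
  n <- nrow(record)
  q_chosen <- numeric(n)
  pe_raw <- numeric(n)
  q <- matrix(0, nrow = 3, ncol = 2,
              dimnames = list(TASK_CONDITIONS, c("incorrect", "correct")))
  cur_run <- NA_integer_
  for (t in seq_len(n)) {
    if (!identical(record$run[t], cur_run)) {
      cur_run <- record$run[t]
      q[] <- 0
    }
    cond <- record$condition[t]
    col <- if (record$chose_correct[t]) "correct" else "incorrect"
    q_chosen[t] <- q[cond, col]
    upd <- update_q(q[cond, col], record$outcome[t],
                    alpha_for(params, cond))
    pe_raw[t] <- upd$pe
    q[cond, col] <- upd$q_new
  }
  out <- data.frame(run = record$run,
                    condition = record$condition,
                    onset = record$onset,
                    q_chosen = q_chosen,
                    pe_raw = pe_raw,
                    rpe = ifelse(record$condition == "gain", pe_raw, NA_real_),
                    ppe = ifelse(record$condition == "loss", -pe_raw,
                                 NA_real_),
                    stringsAsFactors = FALSE)
  class(out) <- c("pe_series", "data.frame")
  out
}
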