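#' Q-learning agent parameters
#'
#' One learning rate per valence plus a shared softmax inverse temperature.
#' The neutral learning rate exists for completeness but is inert under
#' 0-coded neutral outcomes (prediction errors are identically zero there).
#'
#' @param alpha_gain,alpha_loss,alpha_neutral Learning rates in \[0, 1\].
#' @param beta Inverse temperature, finite and >= 0; larger values make
#'   choice more deterministic.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(alpha_gain, alpha_loss, alpha_neutral = 0,
                         beta = 3) {
  a <- c(alpha_gain, alpha_loss, alpha_neutral)
  if (any(!is.finite(a)) || any(a < 0) || any(a > 1))
    stop("learning rates must lie in [0, 1]", call. = FALSE)
  if (!is.finite(beta) || beta < 0)
    stop("beta must be finite and >= 0", call. = FALSE)
  structure(list(alpha_gain = alpha_gain, alpha_loss = alpha_loss,
                 alpha_neutral = alpha_neutral, beta = beta),
            class = "agent_params")
}

#' Softmax choice probability
#'
#' Probability of choosing option a over option b given their expected
#' values, under the logistic (two-option softmax) rule
#' p(a) = 1 / (1 + exp(-beta (Q_a - Q_b))).
#'
#' @param q_a,q_b Expected values of the two options.
#' @param beta Inverse temperature (>= 0).
#' @return Probability of choosing a, in (0, 1). Vectorized.
#' @export
choice_probability <- function(q_a, q_b, beta) {
  if (any(!is.finite(q_a)) || any(!is.finite(q_b)) || any(!is.finite(beta)))
    stop("inputs must be finite", call. = FALSE)
  if (any(beta < 0)) stop("beta must be >= 0", call. = FALSE)
  1 / (1 + exp(-beta * (q_a - q_b)))
}

#' Delta-rule value update
#'
#' Computes the prediction error and the updated expected value for the
#' chosen stimulus: pe = outcome - q; q_new = q + alpha * pe. Only the
#' chosen stimulus is ever updated (no counterfactual learning).
#'
#' @param q Current expected value.
#' @param outcome Received outcome (normalized currency units).
#' @param alpha Learning rate in \[0, 1\].
#' @return List with `q_new` and `pe`.
#' @export
update_q <- function(q, outcome, alpha) {
  if (any(alpha < 0) || any(alpha > 1))
    stop("alpha must lie in [0, 1]", call. = FALSE)
  pe <- outcome - q
  list(q_new = q + alpha * pe, pe = pe)
}

alpha_for <- function(params, condition) {
  switch(condition,
         gain = params$alpha_gain,
         loss = params$alpha_loss,
         neutral = params$alpha_neutral)
}

#' Simulate a subject performing the task
#'
#' Plays a Q-learning agent through a generated trial sequence: expected
#' values start at 0 and are reset at each run boundary (each run uses new
#' stimulus pairs), choices are drawn from the softmax rule and outcomes
#' from the task contingency. The seeded random stream is consumed in trial
#' order: one uniform for the choice, then (gain/loss trials only) one
#' uniform for the outcome.
#'
#' @param params An [agent_params()].
#' @param sequence Trial table from [generate_trial_sequence()].
#' @param config The [task_config()] that produced `sequence`.
#' @param seed Integer seed (`NULL` consumes the current RNG stream).
#' @return The trial table with `chose_correct` and `outcome` filled in.
#' @export
simulate_subject <- function(params, sequence, config = task_config(),
                             seed = NULL) {
  stopifnot(inherits(params, "agent_params"))
  with_seed(seed, {
    n <- nrow(sequence)
    chose <- logical(n)
    outcome <- numeric(n)
    q <- matrix(0, nrow = 3, ncol = 2,
                dimnames = list(TASK_CONDITIONS, c("incorrect", "correct")))
    cur_run <- NA_integer_
    for (t in seq_len(n)) {
      if (!identical(sequence$run[t], cur_run)) {
        cur_run <- sequence$run[t]
        q[] <- 0
      }
      cond <- sequence$condition[t]
      p_correct <- choice_probability(q[cond, "correct"],
                                      q[cond, "incorrect"], params$beta)
      chose[t] <- runif(1) < p_correct
      outcome[t] <- sample_outcome(cond, chose[t], config)
      col <- if (chose[t]) "correct" else "incorrect"
      q[cond, col] <- update_q(q[cond, col], outcome[t],
                               alpha_for(params, cond))$q_new
    }
    sequence$chose_correct <- chose
    sequence$outcome <- outcome
    sequence
  })
}
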