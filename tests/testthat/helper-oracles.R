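# Independent oracles and small fixtures shared across tests. These
# deliberately re-derive quantities with different code paths than the
# package (plogis instead of the logistic closed form, list-based state
# instead of matrices) so agreement is informative.

# Brute-force negative log-likelihood: step-by-step Q recursion with
# per-(run, condition, option) state kept in a nested list.
oracle_nll <- function(record, alpha_gain, alpha_loss, alpha_neutral,
                       beta) {
  q <- list()
  nll <- 0
  for (t in seq_len(nrow(record))) {
    run <- as.character(record$run[t])
    cond <- record$condition[t]
    key_c <- paste(run, cond, "correct")
    key_i <- paste(run, cond, "incorrect")
    if (is.null(q[[key_c]])) q[[key_c]] <- 0
    if (is.null(q[[key_i]])) q[[key_i]] <- 0
    p_correct <- plogis(beta * (q[[key_c]] - q[[key_i]]))
    p <- if (record$chose_correct[t]) p_correct else 1 - p_correct
    p <- min(max(p, 1e-12), 1 - 1e-12)
    nll <- nll - log(p)
    alpha <- c(gain = alpha_gain, loss = alpha_loss,
               neutral = alpha_neutral)[[cond]]
    key <- if (record$chose_correct[t]) key_c else key_i
    q[[key]] <- q[[key]] + alpha * (record$outcome[t] - q[[key]])
  }
  nll
}

# Brute-force PE series over one subject's record (same state layout as
# oracle_nll; Q values reset per run by construction of the keys).
oracle_pe_series <- function(record, alpha_gain, alpha_loss) {
  q <- list()
  pe <- numeric(nrow(record))
  for (t in seq_len(nrow(record))) {
    cond <- record$condition[t]
    key <- paste(record$run[t], cond,
                 if (record$chose_correct[t]) "correct" else "incorrect")
    if (is.null(q[[key]])) q[[key]] <- 0
    pe[t] <- record$outcome[t] - q[[key]]
    alpha <- c(gain = alpha_gain, loss = alpha_loss, neutral = 0)[[cond]]
    q[[key]] <- q[[key]] + alpha * pe[t]
  }
  pe
}

# Hand-made completed record: gain trials in one run with given outcomes,
# all choices "correct".
gain_record <- function(outcomes, run = 1L) {
  data.frame(run = run,
             trial_in_condition = seq_along(outcomes),
             condition = "gain",
             onset = 6 * (seq_along(outcomes) - 1),
             chose_correct = TRUE,
             outcome = outcomes,
             stringsAsFactors = FALSE)
}

# Exact forward enumeration of the (Q, choice, outcome) process for a
# gain-only block: returns P(choose correct) at each of the first
# n_trials trials, by expanding all 4 branches (choice x outcome) per
# trial with exact probabilities.
oracle_gain_choice_probs <- function(n_trials, alpha, beta, p_good) {
  probs <- numeric(n_trials)
  states <- list(list(qc = 0, qi = 0, w = 1))
  for (t in seq_len(n_trials)) {
    nxt <- list()
    p_t <- 0
    for (s in states) {
      pc <- plogis(beta * (s$qc - s$qi))
      p_t <- p_t + s$w * pc
      for (choice in c(TRUE, FALSE)) {
        p_choice <- if (choice) pc else 1 - pc
        p_better <- if (choice) p_good else 1 - p_good
        for (better in c(TRUE, FALSE)) {
          w <- s$w * p_choice * (if (better) p_better else 1 - p_better)
          if (w < 1e-12) next
          r <- if (better) 1 else 0
          st <- s
          if (choice) st$qc <- st$qc + alpha * (r - st$qc)
          else st$qi <- st$qi + alpha * (r - st$qi)
          st$w <- w
          nxt[[length(nxt) + 1L]] <- st
        }
      }
    }
    # merge identical (qc, qi) states to keep the expansion tractable
    keys <- vapply(nxt, function(s)
      paste(signif(s$qc, 12), signif(s$qi, 12)), "")
    states <- lapply(split(seq_along(nxt), keys), function(idx) {
      s <- nxt[[idx[1]]]
      s$w <- sum(vapply(nxt[idx], `[[`, 0, "w"))
      s
    })
    probs[t] <- p_t
  }
  probs
}

# Split-plot sums-of-squares oracle for a balanced two-group design with
# one two-level within factor: returns F statistics for group, within and
# interaction computed from first principles.
oracle_split_plot <- function(value, group, within, subject) {
  d <- data.frame(value, group, within, subject)
  grand <- mean(d$value)
  n_s <- length(unique(d$subject))
  n_w <- length(unique(d$within))
  subj_means <- tapply(d$value, d$subject, mean)
  subj_group <- tapply(as.character(d$group), d$subject, unique)
  grp_means <- tapply(d$value, d$group, mean)
  w_means <- tapply(d$value, d$within, mean)
  cell_means <- tapply(d$value, list(d$group, d$within), mean)
  n_per_g <- table(subj_group)
  ss_group <- n_w * sum(n_per_g * (grp_means[names(n_per_g)] - grand)^2)
  ss_subj <- n_w * sum((subj_means - grp_means[subj_group])^2)
  ss_w <- n_s * sum((w_means - grand)^2)
  ss_gw <- 0
  for (g in rownames(cell_means)) for (w in colnames(cell_means))
    ss_gw <- ss_gw + n_per_g[[g]] *
      (cell_means[g, w] - grp_means[[g]] - w_means[[w]] + grand)^2
  ss_tot <- sum((d$value - grand)^2)
  ss_err_w <- ss_tot - ss_group - ss_subj - ss_w - ss_gw
  df_g <- length(n_per_g) - 1
  df_s <- n_s - length(n_per_g)
  df_w <- n_w - 1
  df_gw <- df_g * df_w
  df_ew <- df_s * df_w
  list(F_group = (ss_group / df_g) / (ss_subj / df_s),
       F_within = (ss_w / df_w) / (ss_err_w / df_ew),
       F_interaction = (ss_gw / df_gw) / (ss_err_w / df_ew),
       df = c(df_g, df_s, df_w, df_gw, df_ew))
}

# Small cohort specification for fast end-to-end tests.
tiny_cohort_spec <- function(...) {
  cohort_spec(n_controls = 6L, n_mdd = 6L, n_mde_missing = 1L,
              task = task_config(n_runs = 2L,
                                 trials_per_condition_per_run = 12L),
              ...)
}
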