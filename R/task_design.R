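#' Task conditions
#'
#' The probabilistic instrumental learning task has three interleaved
#' conditions; each presents a fixed pair of stimuli of which one (the
#' "correct" stimulus) yields the better outcome of the pair with
#' probability `p_good`.
#' @keywords internal
TASK_CONDITIONS <- c("gain", "loss", "neutral")

#' Task configuration
#'
#' Describes the structure of the instrumental learning task: three runs of
#' 120 trials (40 gain, 40 loss, 40 neutral by default), with an 80/20
#' outcome contingency on each stimulus pair. Monetary outcomes are coded in
#' normalized currency units: the $10 gain maps to +1, the -$10 loss to -1,
#' and $0/nothing to 0 (`dollars_per_unit` records the conversion).
#'
#' @param n_runs Number of task runs (default 3).
#' @param trials_per_condition_per_run Trials per condition in each run
#'   (default 40, i.e. 120 trials per run).
#' @param p_good Probability that choosing the correct stimulus yields the
#'   condition's better outcome (default 0.8).
#' @param outcome_magnitudes Named list, per condition, of `c(better, worse)`
#'   outcomes in normalized currency units.
#' @param iti Mean inter-trial interval in seconds (default 6).
#' @param iti_jitter Half-width of the uniform onset jitter in seconds
#'   (default 1); onsets are spaced `iti + U(-iti_jitter, iti_jitter)`.
#' @param max_condition_run Maximum allowed run-length of identical
#'   consecutive conditions in the pseudo-random interleaving (default 4).
#' @param dollars_per_unit Dollars represented by one normalized unit
#'   (default 10; documentation only).
#' @return An object of class `task_config`.
#' @export
task_config <- function(n_runs = 3L,
                        trials_per_condition_per_run = 40L,
                        p_good = 0.8,
                        outcome_magnitudes = list(
                          gain    = c(better = 1,  worse = 0),
                          loss    = c(better = 0,  worse = -1),
                          neutral = c(better = 0,  worse = 0)),
                        iti = 6,
                        iti_jitter = 1,
                        max_condition_run = 4L,
                        dollars_per_unit = 10) {
  n_runs <- as.integer(n_runs)
  trials_per_condition_per_run <- as.integer(trials_per_condition_per_run)
  if (is.na(n_runs) || n_runs < 1L)
    stop("n_runs must be a positive integer", call. = FALSE)
  if (is.na(trials_per_condition_per_run) || trials_per_condition_per_run < 1L)
    stop("trials_per_condition_per_run must be a positive integer",
         call. = FALSE)
  if (!is.numeric(p_good) || p_good <= 0 || p_good >= 1)
    stop("p_good must lie strictly between 0 and 1", call. = FALSE)
  if (!all(TASK_CONDITIONS %in% names(outcome_magnitudes)))
    stop("outcome_magnitudes must name gain, loss and neutral", call. = FALSE)
  for (cond in TASK_CONDITIONS) {
    m <- outcome_magnitudes[[cond]]
    if (m[["better"]] < m[["worse"]])
      stop("better outcome must be >= worse outcome in condition ", cond,
           call. = FALSE)
  }
  if (iti <= 0 || iti_jitter < 0 || iti_jitter >= iti)
    stop("need iti > 0 and 0 <= iti_jitter < iti", call. = FALSE)
  structure(list(n_runs = n_runs,
                 trials_per_condition_per_run = trials_per_condition_per_run,
                 conditions = TASK_CONDITIONS,
                 p_good = p_good,
                 outcome_magnitudes = outcome_magnitudes,
                 iti = iti, iti_jitter = iti_jitter,
                 max_condition_run = as.integer(max_condition_run),
                 dollars_per_unit = dollars_per_unit),
            class = "task_config")
}

# One pseudo-random condition order for a run, with no more than
# max_run identical consecutive conditions. Sequential construction with
# rejection-and-retry on the rare dead ends.
interleave_conditions <- function(n_per_condition, max_run) {
  for (attempt in 1:1000) {
    remaining <- setNames(rep(n_per_condition, 3L), TASK_CONDITIONS)
    out <- character(3L * n_per_condition)
    run_len <- 0L
    last <- ""
    ok <- TRUE
    for (i in seq_along(out)) {
      avail <- names(remaining)[remaining > 0L]
      if (run_len >= max_run) avail <- setdiff(avail, last)
      if (length(avail) == 0L) { ok <- FALSE; break }
      pick <- if (length(avail) == 1L) avail else
        avail[sample.int(length(avail), 1L)]
      out[i] <- pick
      remaining[pick] <- remaining[pick] - 1L
      run_len <- if (identical(pick, last)) run_len + 1L else 1L
      last <- pick
    }
    if (ok) return(out)
  }
  stop("could not interleave conditions under the run-length constraint",
       call. = FALSE)
}

#' Generate a pseudo-random trial sequence
#'
#' Builds the full trial table for one subject: per run, equal numbers of
#' gain, loss and neutral trials in pseudo-random order (bounded run-length),
#' with the left/right screen position of the correct stimulus
#' counterbalanced exactly within each condition and run, and jittered
#' trial onsets. Choices and outcomes are left unfilled (`NA`); see
#' [simulate_subject()].
#'
#' @param config A [task_config()].
#' @param seed Integer seed (`NULL` consumes the current RNG stream).
#' @return A data.frame with one row per trial: `run`, `trial_in_condition`
#'   (1-based within condition and run), `condition`, `onset` (seconds from
#'   run start), `position_left_is_correct`, `chose_correct` (`NA`),
#'   `outcome` (`NA`).
#' @export
generate_trial_sequence <- function(config = task_config(), seed = NULL) {
  stopifnot(inherits(config, "task_config"))
  with_seed(seed, {
    npc <- config$trials_per_condition_per_run
    runs <- lapply(seq_len(config$n_runs), function(r) {
      cond <- interleave_conditions(npc, config$max_condition_run)
      n <- length(cond)
      gaps <- config$iti +
        runif(n, -config$iti_jitter, config$iti_jitter)
      onset <- cumsum(gaps) - gaps[1]
      # exact 50/50 left-placement of the correct stimulus per condition
      left <- logical(n)
      tic <- integer(n)
      for (cc in TASK_CONDITIONS) {
        idx <- which(cond == cc)
        tic[idx] <- seq_along(idx)
        half <- rep(c(TRUE, FALSE), length.out = length(idx))
        left[idx] <- sample(half)
      }
      data.frame(run = r, trial_in_condition = tic, condition = cond,
                 onset = onset, position_left_is_correct = left,
                 chose_correct = NA, outcome = NA_real_,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, runs)
  })
}

#' Sample trial outcomes
#'
#' Draws feedback for one or more trials under the task contingency:
#' choosing the correct stimulus yields the condition's better outcome with
#' probability `p_good`, otherwise the worse outcome; the incorrect stimulus
#' has the reversed contingency. Neutral trials always yield 0 (both "$0"
#' and "nothing" are coded 0), so no random draw is consumed for them.
#'
#' @param condition Character vector of conditions.
#' @param chose_correct Logical vector, recycled against `condition`.
#' @param config A [task_config()].
#' @return Numeric vector of outcomes in normalized currency units.
#' @export
sample_outcome <- function(condition, chose_correct, config = task_config()) {
  stopifnot(inherits(config, "task_config"))
  n <- max(length(condition), length(chose_correct))
  condition <- rep_len(condition, n)
  chose_correct <- rep_len(as.logical(chose_correct), n)
  if (!all(condition %in% TASK_CONDITIONS))
    stop("unknown condition", call. = FALSE)
  out <- numeric(n)
  live <- condition != "neutral"
  if (any(live)) {
    p_better <- ifelse(chose_correct[live], config$p_good, 1 - config$p_good)
    got_better <- runif(sum(live)) < p_better
    mags <- config$outcome_magnitudes
    out[live] <- mapply(function(cond, gb)
      if (gb) mags[[cond]][["better"]] else mags[[cond]][["worse"]],
      condition[live], got_better)
  }
  out
}

#' Per-condition learning curve
#'
#' Averages a subject's choices across runs at each within-condition trial
#' position, giving the trial-by-trial proportion of correct choices
#' (for the loss condition "correct" means avoidance of the high-punishment
#' stimulus, which is how `chose_correct` is coded).
#'
#' @param records Completed trial data.frame for one subject.
#' @param condition Condition to extract (`"gain"`, `"loss"` or `"neutral"`).
#' @return Numeric vector of length `trials_per_condition_per_run`, each
#'   element in \[0, 1\].
#' @export
compute_learning_curve <- function(records, condition) {
  stopifnot(condition %in% TASK_CONDITIONS)
  rec <- records[records$condition == condition, ]
  if (nrow(rec) == 0L) stop("no trials for condition ", condition,
                            call. = FALSE)
  if (any(is.na(rec$chose_correct)))
    stop("records contain unfilled choices", call. = FALSE)
  positions <- sort(unique(rec$trial_in_condition))
  per_run <- table(rec$run)
  if (length(unique(per_run)) != 1L)
    stop("unequal trial counts across runs for condition ", condition,
         call. = FALSE)
  expected <- seq_len(max(positions))
  missing <- setdiff(expected, positions)
  if (length(missing) > 0L)
    stop("missing trial positions: ", paste(missing, collapse = ", "),
         call. = FALSE)
  vapply(expected, function(k)
    mean(rec$chose_correct[rec$trial_in_condition == k]), numeric(1))
}

#' Per-subject task accuracy
#'
#' Pools the gain-condition correct-choice rate and the loss-condition
#' avoidance rate (neutral trials are unlearnable under 0-coded outcomes and
#' are excluded from the criterion).
#'
#' @param records Completed trial data.frame for one subject.
#' @return Mean of the gain and loss accuracy rates.
#' @export
subject_accuracy <- function(records) {
  mean(c(mean(records$chose_correct[records$condition == "gain"]),
         mean(records$chose_correct[records$condition == "loss"])))
}

#' Apply the task-compliance exclusion criterion
#'
#' Subjects whose accuracy, averaged across runs, falls strictly below 50%
#' are excluded as non-compliant; accuracy exactly at 50% is retained.
#'
#' @param accuracy_by_subject data.frame with columns `subject` and
#'   `accuracy` (proportion in \[0, 1\]).
#' @param threshold Exclusion threshold (default 0.5, strict `<`).
#' @return A list with `retained` (subject ids), `excluded` (data.frame of
#'   excluded subjects and their accuracies) and `threshold`.
#' @export
apply_exclusion <- function(accuracy_by_subject, threshold = 0.5) {
  if (nrow(accuracy_by_subject) == 0L)
    stop("empty cohort", call. = FALSE)
  stopifnot(all(c("subject", "accuracy") %in% names(accuracy_by_subject)))
  drop <- accuracy_by_subject$accuracy < threshold
  list(retained = accuracy_by_subject$subject[!drop],
       excluded = accuracy_by_subject[drop, , drop = FALSE],
       threshold = threshold)
}

#' Read a task configuration from a JSON file
#'
#' The file may override any subset of the [task_config()] defaults;
#' `outcome_magnitudes` entries are named `better`/`worse` per condition.
#'
#' @param path JSON file path.
#' @return A [task_config()].
#' @export
task_config_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$outcome_magnitudes))
    raw$outcome_magnitudes <- lapply(raw$outcome_magnitudes, unlist)
  do.call(task_config, raw)
}

#' Write / read trial events as BIDS-style TSV
#'
#' Columns: `onset`, `duration`, `run`, `condition`, `chose_correct`,
#' `outcome`, `trial_in_condition`. Events use zero duration (feedback
#' onsets treated as impulses).
#'
#' @param records Trial data.frame.
#' @param path Output file path.
#' @return `path`, invisibly (writer); the trial data.frame (reader).
#' @export
write_events_tsv <- function(records, path) {
  out <- data.frame(onset = records$onset,
                    duration = 0,
                    run = records$run,
                    condition = records$condition,
                    chose_correct = as.integer(records$chose_correct),
                    outcome = records$outcome,
                    trial_in_condition = records$trial_in_condition)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  d$chose_correct <- as.logical(d$chose_correct)
  d
}
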