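#' Build the canonical two-stage Markov decision task
#'
#' Constructs the sequential two-choice task: a single stage-1 state, four
#' stage-2 states and three outcome states keyed by their monetary reward
#' (0, 10 or 25 yen). Every (state, action) pair leads to one of two
#' successors with probabilities 0.7 (common transition) and 0.3 (rare
#' transition). For model fitting the rewards are rescaled to 0, 0.4 and 1.
#'
#' The layout is chosen so that under backward induction the stage-1 right
#' action is optimal with Q*(S0, right) = 14.5 yen and the best stage-2
#' state-action value is 17.5 yen (left in the common successor of right).
#' The same layout ships as a YAML file (`inst/extdata/canonical_task.yaml`)
#' readable with [read_task_config()], so alternative layouts can be supplied.
#'
#' @return An object of class `twostep_task`: a list with elements
#'   `states` (list with `stage1`, `stage2`, `outcomes`), `actions`,
#'   `transitions` (data frame `state`, `action`, `next_state`, `prob`),
#'   `reward_yen`, `reward_scaled` (named by outcome state) and `n_trials`.
#' @examples
#' task <- two_step_task()
#' ground_truth_values(task, units = "yen")
#' @export
two_step_task <- function() {
  tr <- function(state, a, s_common, s_rare, p = 0.7) {
    data.frame(state = state, action = a,
               next_state = c(s_common, s_rare),
               prob = c(p, 1 - p), stringsAsFactors = FALSE)
  }
  transitions <- rbind(
    tr("S0", "left", "L1", "L2"),
    tr("S0", "right", "R1", "R2"),
    tr("L1", "left", "O10", "O0"),
    tr("L1", "right", "O0", "O10"),
    tr("L2", "left", "O10", "O25"),
    tr("L2", "right", "O0", "O10"),
    tr("R1", "left", "O25", "O0"),
    tr("R1", "right", "O0", "O25"),
    tr("R2", "left", "O0", "O25"),
    tr("R2", "right", "O0", "O10")
  )
  task <- structure(list(
    states = list(stage1 = "S0",
                  stage2 = c("L1", "L2", "R1", "R2"),
                  outcomes = c("O0", "O10", "O25")),
    actions = c("left", "right"),
    transitions = transitions,
    reward_yen = c(O0 = 0, O10 = 10, O25 = 25),
    reward_scaled = c(O0 = 0, O10 = 0.4, O25 = 1),
    n_trials = 200L
  ), class = "twostep_task")
  validate_task(task)
  task
}

#' Validate a two-stage task configuration
#'
#' Checks the structural invariants: per (state, action) exactly two
#' successors with probabilities summing to 1, rewards restricted to
#' 0/10/25 yen, and the scaled reward map restricted to 0/0.4/1.
#'
#' @param task A `twostep_task` object.
#' @return `task`, invisibly; errors describe the violated invariant.
#' @export
validate_task <- function(task) {
  stopifnot(inherits(task, "twostep_task"))
  tr <- task$transitions
  nonterminal <- c(task$states$stage1, task$states$stage2)
  for (s in nonterminal) for (a in task$actions) {
    rows <- tr[tr$state == s & tr$action == a, , drop = FALSE]
    if (nrow(rows) != 2L)
      stop(sprintf("(%s, %s) must have exactly two successors, found %d",
                   s, a, nrow(rows)))
    if (abs(sum(rows$prob) - 1) > 1e-12)
      stop(sprintf("transition probabilities for (%s, %s) sum to %g, not 1",
                   s, a, sum(rows$prob)))
  }
  s2succ <- tr$next_state[tr$state == task$states$stage1]
  if (!all(s2succ %in% task$states$stage2))
    stop("stage-1 successors must be stage-2 states")
  outsucc <- tr$next_state[tr$state %in% task$states$stage2]
  if (!all(outsucc %in% task$states$outcomes))
    stop("stage-2 successors must be outcome states")
  if (!all(task$reward_yen %in% c(0, 10, 25)))
    stop("rewards must be 0, 10 or 25 yen")
  if (!all(task$reward_scaled %in% c(0, 0.4, 1)))
    stop("scaled rewards must be 0, 0.4 or 1")
  invisible(task)
}

#' Read a task layout from a YAML configuration file
#'
#' @param path Path to a YAML file mirroring the `twostep_task` fields
#'   (see `system.file("extdata", "canonical_task.yaml", package = "twostep")`).
#' @return A validated `twostep_task` object.
#' @export
read_task_config <- function(path) {
  y <- yaml::read_yaml(path)
  transitions <- do.call(rbind, lapply(y$transitions, function(row) {
    data.frame(state = row$state, action = row$action,
               next_state = row[["next"]], prob = row$prob,
               stringsAsFactors = FALSE)
  }))
  task <- structure(list(
    states = list(stage1 = y$states$stage1,
                  stage2 = unlist(y$states$stage2),
                  outcomes = unlist(y$states$outcomes)),
    actions = unlist(y$actions),
    transitions = transitions,
    reward_yen = unlist(y$reward_yen),
    reward_scaled = unlist(y$reward_scaled),
    n_trials = as.integer(y$n_trials)
  ), class = "twostep_task")
  validate_task(task)
  task
}

#' Optimal state-action values by backward induction
#'
#' Computes the ground-truth Q* table of the two-stage task: stage-2 values
#' are probability-weighted outcome rewards, stage-1 values propagate the
#' stage-2 maxima (outcome states are terminal, so no further bootstrap).
#'
#' @param task A `twostep_task`.
#' @param units `"yen"` (0/10/25) or `"scaled"` (0/0.4/1).
#' @return Data frame with columns `state`, `action`, `q`.
#' @examples
#' gt <- ground_truth_values(two_step_task(), "yen")
#' gt[gt$state == "S0", ]  # right action worth 14.5 yen
#' @export
ground_truth_values <- function(task, units = c("yen", "scaled")) {
  units <- match.arg(units)
  validate_task(task)
  rew <- if (units == "yen") task$reward_yen else task$reward_scaled
  tr <- task$transitions
  q2 <- expand.grid(state = task$states$stage2, action = task$actions,
                    stringsAsFactors = FALSE)
  q2$q <- mapply(function(s, a) {
    rows <- tr[tr$state == s & tr$action == a, ]
    sum(rows$prob * rew[rows$next_state])
  }, q2$state, q2$action)
  v2 <- tapply(q2$q, q2$state, max)
  q1 <- expand.grid(state = task$states$stage1, action = task$actions,
                    stringsAsFactors = FALSE)
  q1$q <- mapply(function(s, a) {
    rows <- tr[tr$state == s & tr$action == a, ]
    sum(rows$prob * v2[rows$next_state])
  }, q1$state, q1$action)
  out <- rbind(q1, q2)
  rownames(out) <- NULL
  out
}

#' Sample a successor state
#'
#' Draws the next state for a (state, action) pair from the task's
#' transition probabilities using R's random number stream.
#'
#' @param task A `twostep_task`.
#' @param state,action State identifier and action.
#' @param n Number of draws.
#' @return Character vector of successor state identifiers.
#' @export
sample_transition <- function(task, state, action, n = 1L) {
  rows <- task$transitions[task$transitions$state == state &
                             task$transitions$action == action, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop(sprintf("unknown (state, action) pair: (%s, %s)", state, action))
  rows$next_state[1L + (stats::runif(n) >= rows$prob[1L])]
}

# transition label: the high-probability successor is the common one
transition_label <- function(prob) ifelse(prob >= 0.5, "common", "rare")

#' Simulate one task episode under an arbitrary policy
#'
#' Rolls one trial of the task forward under `policy` and returns a fully
#' populated trial record. Used by the simulation study and the synthetic
#' cohort generator; also convenient for uniform-policy baselines.
#'
#' @param task A `twostep_task`.
#' @param policy A function `(state) -> named numeric` of action
#'   probabilities (names = actions, summing to 1).
#' @param trial_index 1-based trial counter stored in the record.
#' @return One-row data frame with columns `trial`, `a1`, `s2`, `transition`,
#'   `a2`, `s3`, `reward_yen`.
#' @export
simulate_episode <- function(task, policy, trial_index = 1L) {
  pick <- function(state) {
    p <- policy(state)
    if (abs(sum(p) - 1) > 1e-9)
      stop(sprintf("policy probabilities at %s sum to %g, not 1",
                   state, sum(p)))
    sample(names(p), 1L, prob = p)
  }
  s1 <- task$states$stage1
  a1 <- pick(s1)
  rows1 <- task$transitions[task$transitions$state == s1 &
                              task$transitions$action == a1, ]
  k1 <- 1L + (stats::runif(1) >= rows1$prob[1L])
  s2 <- rows1$next_state[k1]
  a2 <- pick(s2)
  rows2 <- task$transitions[task$transitions$state == s2 &
                              task$transitions$action == a2, ]
  k2 <- 1L + (stats::runif(1) >= rows2$prob[1L])
  s3 <- rows2$next_state[k2]
  data.frame(trial = trial_index, a1 = a1, s2 = s2,
             transition = transition_label(rows1$prob[k1]),
             a2 = a2, s3 = s3,
             reward_yen = unname(task$reward_yen[s3]),
             stringsAsFactors = FALSE)
}

# --- internal encodings shared by the compiled likelihood/simulator --------

# Flatten the task into the fixed-topology arrays used by the C++ core.
# Successor "slots" follow the row order of the transition table.
task_arrays <- function(task) {
  validate_task(task)
  if (length(task$states$stage2) != 4L)
    stop("compiled core requires exactly four stage-2 states")
  tr <- task$transitions
  s1 <- task$states$stage1
  s1succ <- matrix(0L, 2, 2)   # [action, slot] -> stage-2 index 0..3
  s1prob <- matrix(0, 2, 2)
  for (ai in 1:2) {
    rows <- tr[tr$state == s1 & tr$action == task$actions[ai], ]
    s1succ[ai, ] <- match(rows$next_state, task$states$stage2) - 1L
    s1prob[ai, ] <- rows$prob
  }
  er <- numeric(16); eryen <- numeric(16); s2prob <- numeric(16)
  outidx <- integer(16)        # outcome index 0..2
  for (si in 1:4) for (ai in 1:2) for (k in 1:2) {
    rows <- tr[tr$state == task$states$stage2[si] &
                 tr$action == task$actions[ai], ]
    idx <- (si - 1) + 4 * (ai - 1) + 8 * (k - 1) + 1
    er[idx] <- task$reward_scaled[rows$next_state[k]]
    eryen[idx] <- task$reward_yen[rows$next_state[k]]
    s2prob[idx] <- rows$prob[k]
    outidx[idx] <- match(rows$next_state[k], task$states$outcomes) - 1L
  }
  list(s1succ = s1succ, s1prob = s1prob, er = er, eryen = eryen,
       s2prob = s2prob, outidx = outidx)
}

# Encode a trial-log data frame into 0-based integer vectors for the C++
# core; errors name the offending row.
encode_trials <- function(trials, task) {
  arr <- task_arrays(task)
  tr <- task$transitions
  s1 <- task$states$stage1
  n <- nrow(trials)
  a1 <- match(trials$a1, task$actions)
  a2 <- match(trials$a2, task$actions)
  s2 <- match(trials$s2, task$states$stage2)
  if (anyNA(a1) || anyNA(a2))
    stop(sprintf("unknown action label in trial row %d",
                 which(is.na(a1) | is.na(a2))[1]))
  if (anyNA(s2))
    stop(sprintf("unknown stage-2 state in trial row %d", which(is.na(s2))[1]))
  slot1 <- integer(n); slot2 <- integer(n)
  for (i in seq_len(n)) {
    rows1 <- tr[tr$state == s1 & tr$action == trials$a1[i], ]
    k1 <- match(trials$s2[i], rows1$next_state)
    rows2 <- tr[tr$state == trials$s2[i] & tr$action == trials$a2[i], ]
    k2 <- match(trials$s3[i], rows2$next_state)
    if (is.na(k1))
      stop(sprintf("row %d: %s is not a successor of (%s, %s)",
                   i, trials$s2[i], s1, trials$a1[i]))
    if (is.na(k2))
      stop(sprintf("row %d: %s is not a successor of (%s, %s)",
                   i, trials$s3[i], trials$s2[i], trials$a2[i]))
    slot1[i] <- k1; slot2[i] <- k2
  }
  rsc <- unname(task$reward_scaled[trials$s3])
  list(a1 = a1 - 1L, s2 = s2 - 1L, slot1 = slot1 - 1L,
       a2 = a2 - 1L, slot2 = slot2 - 1L, rsc = rsc, arr = arr)
}
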