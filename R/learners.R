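#' Learner parameters for the HYBRID family
#'
#' Bundles the free parameters of the SARSA / FORWARD / HYBRID learners:
#' model-free learning rate `alpha`, model-based (transition) learning rate
#' `eta`, softmax inverse temperature `beta` and model-based weight `w`.
#' The temporal discount `gamma` is fixed at 1 — the task has no delayed
#' choices within a trial sequence that would require discounting.
#'
#' @param alpha Model-free learning rate, in (0, 1).
#' @param eta Model-based learning rate, in (0, 1).
#' @param beta Inverse temperature, in (0, 10); small values give
#'   exploratory choice.
#' @param w Model-based weight in \[0, 1\]; `w = 0` is pure SARSA,
#'   `w = 1` pure FORWARD.
#' @return A `learner_params` list.
#' @export
learner_params <- function(alpha = 0.2, eta = 0.2, beta = 5, w = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1, eta >= 0, eta <= 1,
            beta >= 0, beta <= 10)
  if (w < 0 || w > 1) stop("w must lie in [0, 1]")
  structure(list(alpha = alpha, eta = eta, beta = beta, w = w, gamma = 1),
            class = "learner_params")
}

#' Initial learner state
#'
#' All SARSA and FORWARD state-action values start at 0 and the estimated
#' transition probabilities at 0.5/0.5 for every (state, action) pair, so a
#' fresh agent is indifferent at every choice.
#'
#' @param task A `twostep_task`.
#' @param params A `learner_params` object.
#' @return A `learner_state` list with elements `q_sarsa` and `q_fwd`
#'   (matrices state x action) and `t_hat` (data frame mirroring the task's
#'   transition table with estimated probabilities `p`).
#' @export
init_learner_state <- function(task, params = learner_params()) {
  states <- c(task$states$stage1, task$states$stage2)
  q <- matrix(0, nrow = length(states), ncol = length(task$actions),
              dimnames = list(states, task$actions))
  t_hat <- task$transitions[, c("state", "action", "next_state")]
  t_hat$p <- 0.5
  structure(list(q_sarsa = q, q_fwd = q, t_hat = t_hat, params = params),
            class = "learner_state")
}

#' SARSA temporal-difference update
#'
#' Applies one reward-prediction-error update
#' `Q(s,a) <- Q(s,a) + alpha * delta` with
#' `delta = r + gamma * Q(s', a') - Q(s,a)` (gamma fixed at 1; the
#' bootstrap term is 0 when `s_next` is terminal).
#'
#' @param state A `learner_state`.
#' @param s,a State and action being updated.
#' @param r_next Reward received on transition, in scaled units.
#' @param s_next,a_next Successor state and the action chosen there;
#'   both `NULL` for terminal transitions.
#' @return List with the updated `state` and the prediction error `delta`.
#' @export
sarsa_update <- function(state, s, a, r_next, s_next = NULL, a_next = NULL) {
  boot <- if (is.null(s_next)) 0 else state$q_sarsa[s_next, a_next]
  delta <- r_next + state$params$gamma * boot - state$q_sarsa[s, a]
  state$q_sarsa[s, a] <- state$q_sarsa[s, a] + state$params$alpha * delta
  list(state = state, delta_rpe = delta)
}

#' FORWARD transition-model update
#'
#' State-prediction-error update of the estimated transition probabilities:
#' the observed successor's entry moves toward 1 by
#' `eta * (1 - T(s,a,s'))` and the non-visited successor's entry is scaled
#' by `(1 - eta)`, so each row remains a probability distribution.
#'
#' @param state A `learner_state`.
#' @param s,a State and action taken.
#' @param s_observed The successor actually reached.
#' @return List with the updated `state` and `delta_spe = 1 - T(s,a,s')`.
#' @export
forward_transition_update <- function(state, s, a, s_observed) {
  th <- state$t_hat
  sel <- th$state == s & th$action == a
  if (!any(sel & th$next_state == s_observed))
    stop(sprintf("%s is not a successor of (%s, %s)", s_observed, s, a))
  obs <- sel & th$next_state == s_observed
  delta <- 1 - th$p[obs]
  th$p[obs] <- th$p[obs] + state$params$eta * delta
  th$p[sel & !obs] <- (1 - state$params$eta) * th$p[sel & !obs]
  state$t_hat <- th
  list(state = state, delta_spe = delta)
}

#' FORWARD state-action values from the learned transition model
#'
#' Backward sweep through the two-stage tree:
#' `Q_FWD(s,a) = sum_s' T(s,a,s') * (E[r(s')] + max_a' Q_FWD(s',a'))`
#' where `E[r]` is the known scaled reward for outcome states and 0 for
#' stage-2 states, and the max over an empty action set is 0.
#'
#' @param state A `learner_state`.
#' @param task A `twostep_task`.
#' @return The `learner_state` with `q_fwd` recomputed.
#' @export
forward_values <- function(state, task) {
  th <- state$t_hat
  q <- state$q_fwd
  q[] <- 0
  for (s in task$states$stage2) for (a in task$actions) {
    rows <- th[th$state == s & th$action == a, ]
    q[s, a] <- sum(rows$p * task$reward_scaled[rows$next_state])
  }
  v2 <- apply(q[task$states$stage2, , drop = FALSE], 1, max)
  for (a in task$actions) {
    rows <- th[th$state == task$states$stage1 & th$action == a, ]
    q[task$states$stage1, a] <- sum(rows$p * v2[rows$next_state])
  }
  state$q_fwd <- q
  state
}

#' Combine FORWARD and SARSA values
#'
#' Elementwise convex combination
#' `Q_HYB = w * Q_FWD + (1 - w) * Q_SARSA`.
#'
#' @param q_fwd,q_sarsa Value tables with identical dimensions.
#' @param w Model-based weight in \[0, 1\].
#' @return The hybrid value table.
#' @export
hybrid_values <- function(q_fwd, q_sarsa, w) {
  if (w < 0 || w > 1) stop("w must lie in [0, 1]")
  w * q_fwd + (1 - w) * q_sarsa
}

#' Softmax choice probabilities
#'
#' `P(a) = exp(beta * Q(a)) / sum_a' exp(beta * Q(a'))`, computed with
#' max-subtraction for overflow safety.
#'
#' @param q Numeric vector of action values for one state.
#' @param beta Inverse temperature, non-negative.
#' @return Probability vector of the same length (names preserved).
#' @export
softmax_probs <- function(q, beta) {
  stopifnot(beta >= 0, all(is.finite(q)))
  x <- beta * q
  e <- exp(x - max(x))
  e / sum(e)
}

#' Process one observed trial (teacher-forced)
#'
#' Emits the choice probabilities of the recorded actions under the current
#' hybrid values, then applies the trial's learning: both transition-model
#' updates, a FORWARD value recomputation, and the two SARSA updates
#' (stage 1 with reward 0 bootstrapping on the chosen stage-2 action,
#' stage 2 with the scaled outcome reward and terminal bootstrap 0).
#'
#' This is the transparent reference path; [trial_loglik()] runs the same
#' recursion in compiled code.
#'
#' @param state A `learner_state`.
#' @param trial One-row data frame with `a1`, `s2`, `a2`, `s3`.
#' @param task A `twostep_task`.
#' @return List with updated `state`, `p1` and `p2` (probabilities of the
#'   observed choices) and the prediction errors `delta_rpe1`, `delta_rpe2`,
#'   `delta_spe1`, `delta_spe2`.
#' @export
process_trial <- function(state, trial, task) {
  s1 <- task$states$stage1
  qh <- hybrid_values(state$q_fwd, state$q_sarsa, state$params$w)
  p1 <- softmax_probs(qh[s1, ], state$params$beta)[[trial$a1]]
  p2 <- softmax_probs(qh[trial$s2, ], state$params$beta)[[trial$a2]]

  u1 <- forward_transition_update(state, s1, trial$a1, trial$s2)
  u2 <- forward_transition_update(u1$state, trial$s2, trial$a2, trial$s3)
  state <- forward_values(u2$state, task)

  r1 <- sarsa_update(state, s1, trial$a1, r_next = 0,
                     s_next = trial$s2, a_next = trial$a2)
  r2 <- sarsa_update(r1$state, trial$s2, trial$a2,
                     r_next = unname(task$reward_scaled[trial$s3]))
  list(state = r2$state, p1 = p1, p2 = p2,
       delta_spe1 = u1$delta_spe, delta_spe2 = u2$delta_spe,
       delta_rpe1 = r1$delta_rpe, delta_rpe2 = r2$delta_rpe)
}

#' Act one episode generatively
#'
#' Samples both choices from the softmax over current hybrid values, samples
#' the task's transitions, then applies the same learning updates as
#' [process_trial()].
#'
#' @param state A `learner_state`.
#' @param task A `twostep_task`.
#' @param trial_index 1-based trial counter for the record.
#' @return List with `trial` (a one-row trial record) and the updated
#'   `state`.
#' @export
act_episode <- function(state, task, trial_index = 1L) {
  s1 <- task$states$stage1
  qh <- hybrid_values(state$q_fwd, state$q_sarsa, state$params$w)
  beta <- state$params$beta
  a1 <- sample(task$actions, 1L, prob = softmax_probs(qh[s1, ], beta))
  rows1 <- task$transitions[task$transitions$state == s1 &
                              task$transitions$action == a1, ]
  k1 <- 1L + (stats::runif(1) >= rows1$prob[1L])
  s2 <- rows1$next_state[k1]
  a2 <- sample(task$actions, 1L, prob = softmax_probs(qh[s2, ], beta))
  rows2 <- task$transitions[task$transitions$state == s2 &
                              task$transitions$action == a2, ]
  k2 <- 1L + (stats::runif(1) >= rows2$prob[1L])
  s3 <- rows2$next_state[k2]
  trial <- data.frame(trial = trial_index, a1 = a1, s2 = s2,
                      transition = transition_label(rows1$prob[k1]),
                      a2 = a2, s3 = s3,
                      reward_yen = unname(task$reward_yen[s3]),
                      stringsAsFactors = FALSE)
  res <- process_trial(state, trial, task)
  list(trial = trial, state = res$state)
}
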