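# Bridging between the R-level learner_state and the flat arrays used by the
# compiled likelihood / simulator.

# state name -> 0-based index over c(stage1, stage2)
state_index <- function(task) {
  stats::setNames(seq_along(c(task$states$stage1, task$states$stage2)) - 1L,
                  c(task$states$stage1, task$states$stage2))
}

# learner_state -> list(qs, qf = length 10, th = length 20)
state_to_flat <- function(state, task) {
  si <- state_index(task)
  qs <- numeric(10); qf <- numeric(10)
  for (s in names(si)) for (ai in 1:2) {
    qs[si[[s]] + 5 * (ai - 1) + 1] <- state$q_sarsa[s, task$actions[ai]]
    qf[si[[s]] + 5 * (ai - 1) + 1] <- state$q_fwd[s, task$actions[ai]]
  }
  th <- numeric(20)
  tt <- state$t_hat
  for (s in names(si)) for (ai in 1:2) {
    rows <- which(tt$state == s & tt$action == task$actions[ai])
    for (k in 1:2)
      th[si[[s]] + 5 * (ai - 1) + 10 * (k - 1) + 1] <- tt$p[rows[k]]
  }
  list(qs = qs, qf = qf, th = th)
}

flat_to_state <- function(qs, qf, th, task, params) {
  state <- init_learner_state(task, params)
  si <- state_index(task)
  for (s in names(si)) for (ai in 1:2) {
    state$q_sarsa[s, task$actions[ai]] <- qs[si[[s]] + 5 * (ai - 1) + 1]
    state$q_fwd[s, task$actions[ai]] <- qf[si[[s]] + 5 * (ai - 1) + 1]
  }
  tt <- state$t_hat
  for (s in names(si)) for (ai in 1:2) {
    rows <- which(tt$state == s & tt$action == task$actions[ai])
    for (k in 1:2)
      tt$p[rows[k]] <- th[si[[s]] + 5 * (ai - 1) + 10 * (k - 1) + 1]
  }
  state$t_hat <- tt
  state
}

full_params <- function(par_free, model) {
  switch(model,
         hybrid = c(alpha = par_free[[1]], eta = par_free[[2]],
                    beta = par_free[[3]], w = par_free[[4]]),
         sarsa = c(alpha = par_free[[1]], eta = 0.5,
                   beta = par_free[[2]], w = 0),
         forward = c(alpha = 0.5, eta = par_free[[1]],
                     beta = par_free[[2]], w = 1))
}

free_names <- function(model) {
  switch(model, hybrid = c("alpha", "eta", "beta", "w"),
         sarsa = c("alpha", "beta"), forward = c("eta", "beta"))
}

#' Teacher-forced negative log-likelihood of a trial log
#'
#' Sums `-log P(a1) - log P(a2)` over trials, with choice probabilities
#' emitted before each trial's learning updates. The SARSA model is the
#' `w = 0` path of the HYBRID recursion and FORWARD the `w = 1` path
#' (the silent value tables still update). The recursion runs in compiled
#' code; [process_trial()] is the equivalent step-by-step R path.
#'
#' @param params A `learner_params` (or named vector with `alpha`, `eta`,
#'   `beta`, `w`).
#' @param trials Trial-log data frame with columns `a1`, `s2`, `a2`, `s3`.
#' @param task A `twostep_task`.
#' @param init A `learner_state` to start from; default fresh.
#' @param model One of `"hybrid"`, `"sarsa"`, `"forward"`; overrides `w`
#'   (0 for SARSA, 1 for FORWARD).
#' @param per_trial If `TRUE` also return per-trial log-probabilities.
#' @return List with `nll`, `end_state` (a `learner_state`) and, when
#'   requested, `lp1`/`lp2`.
#' @export
trial_loglik <- function(params, trials, task, init = NULL,
                         model = c("hybrid", "sarsa", "forward"),
                         per_trial = FALSE) {
  model <- match.arg(model)
  p <- if (is.list(params)) {
    c(alpha = params$alpha, eta = params$eta, beta = params$beta, w = params$w)
  } else {
    params[c("alpha", "eta", "beta", "w")]
  }
  if (model == "sarsa") p[["w"]] <- 0
  if (model == "forward") p[["w"]] <- 1
  lp <- learner_params(p[["alpha"]], p[["eta"]], p[["beta"]], p[["w"]])
  if (is.null(init)) init <- init_learner_state(task, lp)
  flat <- state_to_flat(init, task)
  if (nrow(trials) == 0L)
    return(list(nll = 0, end_state = init))
  enc <- encode_trials(trials, task)
  res <- nll_hybrid_cpp(unlist(p), enc$a1, enc$s2, enc$slot1, enc$a2,
                        enc$slot2, enc$rsc, enc$arr$s1succ, enc$arr$er,
                        flat$qs, flat$qf, flat$th, per_trial)
  out <- list(nll = res$nll,
              end_state = flat_to_state(res$qs, res$qf, res$th, task, lp))
  if (per_trial) { out$lp1 <- res$lp1; out$lp2 <- res$lp2 }
  out
}
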