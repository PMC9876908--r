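# Independent straight-line oracles, written against the model equations
# directly (nested named lists, explicit loops) and sharing no code with the
# package internals.

# Teacher-forced NLL of a trial log under the HYBRID learner.
oracle_nll <- function(alpha, eta, beta, w, trials, task) {
  s1 <- task$states$stage1
  states <- c(s1, task$states$stage2)
  acts <- task$actions
  succ <- function(s, a) {
    r <- task$transitions[task$transitions$state == s &
                            task$transitions$action == a, ]
    r$next_state
  }
  Qs <- list(); Qf <- list(); Tm <- list()
  for (s in states) for (a in acts) {
    Qs[[s]][[a]] <- 0
    Qf[[s]][[a]] <- 0   # FORWARD values start at 0, recomputed post-update
    for (sn in succ(s, a)) Tm[[s]][[a]][[sn]] <- 0.5
  }
  rew <- task$reward_scaled
  nll <- 0
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    qh <- function(s, a) w * Qf[[s]][[a]] + (1 - w) * Qs[[s]][[a]]
    p1 <- exp(beta * qh(s1, tr$a1)) /
      (exp(beta * qh(s1, acts[1])) + exp(beta * qh(s1, acts[2])))
    p2 <- exp(beta * qh(tr$s2, tr$a2)) /
      (exp(beta * qh(tr$s2, acts[1])) + exp(beta * qh(tr$s2, acts[2])))
    nll <- nll - log(p1) - log(p2)
    # transition-model updates
    for (sn in succ(s1, tr$a1)) {
      Tm[[s1]][[tr$a1]][[sn]] <-
        if (sn == tr$s2) Tm[[s1]][[tr$a1]][[sn]] +
          eta * (1 - Tm[[s1]][[tr$a1]][[sn]])
        else (1 - eta) * Tm[[s1]][[tr$a1]][[sn]]
    }
    for (sn in succ(tr$s2, tr$a2)) {
      Tm[[tr$s2]][[tr$a2]][[sn]] <-
        if (sn == tr$s3) Tm[[tr$s2]][[tr$a2]][[sn]] +
          eta * (1 - Tm[[tr$s2]][[tr$a2]][[sn]])
        else (1 - eta) * Tm[[tr$s2]][[tr$a2]][[sn]]
    }
    # FORWARD values recomputed from the updated transition model
    for (s in task$states$stage2) for (a in acts) {
      v <- 0
      for (sn in succ(s, a)) v <- v + Tm[[s]][[a]][[sn]] * rew[[sn]]
      Qf[[s]][[a]] <- v
    }
    for (a in acts) {
      v <- 0
      for (sn in succ(s1, a))
        v <- v + Tm[[s1]][[a]][[sn]] * max(Qf[[sn]][[acts[1]]],
                                           Qf[[sn]][[acts[2]]])
      Qf[[s1]][[a]] <- v
    }
    # SARSA updates: stage 1 bootstraps on the chosen stage-2 action
    d1 <- 0 + Qs[[tr$s2]][[tr$a2]] - Qs[[s1]][[tr$a1]]
    Qs[[s1]][[tr$a1]] <- Qs[[s1]][[tr$a1]] + alpha * d1
    d2 <- rew[[tr$s3]] - Qs[[tr$s2]][[tr$a2]]
    Qs[[tr$s2]][[tr$a2]] <- Qs[[tr$s2]][[tr$a2]] + alpha * d2
    nll
  }
  nll
}

# Ground-truth Q* by brute-force enumeration of all two-step outcome paths.
oracle_ground_truth <- function(task, units = "yen") {
  rew <- if (units == "yen") task$reward_yen else task$reward_scaled
  tt <- task$transitions
  s1 <- task$states$stage1
  acts <- task$actions
  q2 <- list()
  for (s in task$states$stage2) for (a in acts) {
    rows <- tt[tt$state == s & tt$action == a, ]
    v <- 0
    for (k in seq_len(nrow(rows)))
      v <- v + rows$prob[k] * rew[[rows$next_state[k]]]
    q2[[paste(s, a)]] <- v
  }
  out <- list()
  for (a in acts) {
    rows <- tt[tt$state == s1 & tt$action == a, ]
    v <- 0
    for (k in seq_len(nrow(rows))) {
      s2 <- rows$next_state[k]
      v <- v + rows$prob[k] * max(q2[[paste(s2, acts[1])]],
                                  q2[[paste(s2, acts[2])]])
    }
    out[[paste(s1, a)]] <- v
  }
  c(out, q2)
}

# Moving mean with a truncated centered window, direct double loop.
oracle_moving_average <- function(x, window = 20L) {
  n <- length(x)
  before <- window %/% 2L
  after <- window - before - 1L
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0; cnt <- 0
    for (j in seq_len(n)) {
      if (j >= i - before && j <= i + after) { acc <- acc + x[j]; cnt <- cnt + 1 }
    }
    out[i] <- acc / cnt
  }
  out
}

# A random valid task layout: shuffled outcome assignments and a random
# common-transition probability per (state, action).
random_task <- function() {
  task <- two_step_task()
  tt <- task$transitions
  for (s in task$states$stage2) for (a in task$actions) {
    rows <- which(tt$state == s & tt$action == a)
    tt$next_state[rows] <- sample(task$states$outcomes, 2, replace = TRUE)
    p <- sample(c(0.6, 0.7, 0.8, 1.0), 1)
    tt$prob[rows] <- c(p, 1 - p)
  }
  for (a in task$actions) {
    rows <- which(tt$state == task$states$stage1 & tt$action == a)
    p <- sample(c(0.6, 0.7, 0.8), 1)
    tt$prob[rows] <- c(p, 1 - p)
  }
  task$transitions <- tt
  task
}

# A short fuzzed-but-valid trial log sampled uniformly over legal paths.
random_trials <- function(n, task = two_step_task()) {
  tt <- task$transitions
  s1 <- task$states$stage1
  rows <- lapply(seq_len(n), function(i) {
    a1 <- sample(task$actions, 1)
    r1 <- tt[tt$state == s1 & tt$action == a1, ]
    k1 <- sample(1:2, 1)
    s2 <- r1$next_state[k1]
    a2 <- sample(task$actions, 1)
    r2 <- tt[tt$state == s2 & tt$action == a2, ]
    k2 <- sample(1:2, 1)
    s3 <- r2$next_state[k2]
    data.frame(trial = i, a1 = a1, s2 = s2,
               transition = ifelse(r1$prob[k1] >= 0.5, "common", "rare"),
               a2 = a2, s3 = s3,
               reward_yen = unname(task$reward_yen[s3]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
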