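task <- two_step_task()

test_that("SARSA update applies the prediction-error rule", {
  st <- init_learner_state(task, learner_params(alpha = 0.5))
  r <- sarsa_update(st, "R1", "left", r_next = 1)   # terminal next
  expect_equal(r$delta_rpe, 1)
  expect_equal(r$state$q_sarsa["R1", "left"], 0.5)
  # only the updated cell changes
  changed <- r$state$q_sarsa != st$q_sarsa
  expect_equal(sum(changed), 1L)

  st0 <- init_learner_state(task, learner_params(alpha = 0))
  r0 <- sarsa_update(st0, "R1", "left", r_next = 1)
  expect_equal(r0$state$q_sarsa, st0$q_sarsa)
  expect_equal(r0$delta_rpe, 1)

  # repeated terminal updates converge geometrically to the reward
  st <- init_learner_state(task, learner_params(alpha = 0.3))
  for (i in 1:100) st <- sarsa_update(st, "L1", "left", r_next = 0.4)$state
  expect_equal(st$q_sarsa["L1", "left"], 0.4, tolerance = 1e-10)
  # non-terminal bootstrap uses Q(s', a')
  st$q_sarsa["R1", "right"] <- 0.9
  r <- sarsa_update(st, "S0", "left", 0, "R1", "right")
  expect_equal(r$delta_rpe, 0.9 - 0)
})

test_that("transition-model update preserves row stochasticity", {
  st <- init_learner_state(task, learner_params(eta = 0.2))
  r <- forward_transition_update(st, "S0", "right", "R1")
  expect_equal(r$delta_spe, 0.5)
  th <- r$state$t_hat
  sel <- th$state == "S0" & th$action == "right"
  expect_equal(th$p[sel], c(0.6, 0.4))

  st1 <- init_learner_state(task, learner_params(eta = 1))
  r1 <- forward_transition_update(st1, "S0", "right", "R2")
  th1 <- r1$state$t_hat
  expect_equal(th1$p[th1$state == "S0" & th1$action == "right"], c(0, 1))

  expect_error(forward_transition_update(st, "S0", "right", "L1"),
               "not a successor")

  # fuzzed sequences keep every row summing to 1
  set.seed(21)
  st <- init_learner_state(task, learner_params(eta = 0.37))
  tt <- task$transitions
  for (i in 1:200) {
    row <- tt[sample(nrow(tt), 1), ]
    st <- forward_transition_update(st, row$state, row$action,
                                    row$next_state)$state
  }
  sums <- tapply(st$t_hat$p, paste(st$t_hat$state, st$t_hat$action), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(st$t_hat$p >= 0 & st$t_hat$p <= 1))
})

test_that("FORWARD values reduce to backward induction at the true model", {
  st <- init_learner_state(task)
  st$t_hat$p <- task$transitions$prob       # oracle transition knowledge
  st <- forward_values(st, task)
  gt <- ground_truth_values(task, "scaled")
  for (i in seq_len(nrow(gt)))
    expect_equal(st$q_fwd[gt$state[i], gt$action[i]], gt$q[i])

  # uniform beliefs mix the two outcomes equally
  st <- forward_values(init_learner_state(task), task)
  expect_equal(st$q_fwd["R1", "left"], 0.5 * 1 + 0.5 * 0)

  zero <- task
  zero$reward_scaled[] <- 0
  stz <- forward_values(init_learner_state(zero), zero)
  expect_true(all(stz$q_fwd == 0))
})

test_that("hybrid combination is the convex mixture", {
  st <- forward_values(init_learner_state(task), task)
  qf <- st$q_fwd
  qs <- st$q_sarsa + 0.3
  expect_equal(hybrid_values(qf, qs, 0), qs)
  expect_equal(hybrid_values(qf, qs, 1), qf)
  expect_equal(hybrid_values(matrix(0.7), matrix(0.3), 0.5), matrix(0.5))
  expect_error(hybrid_values(qf, qs, 1.2), "w must")
  set.seed(8)
  for (i in 1:20) {
    a <- matrix(runif(10), 5); b <- matrix(runif(10), 5)
    w <- runif(1)
    h <- hybrid_values(a, b, w)
    expect_true(all(h >= pmin(a, b) - 1e-12 & h <= pmax(a, b) + 1e-12))
  }
})

test_that("softmax has the closed form and is monotone in beta", {
  expect_equal(softmax_probs(c(0.4, 0.4), 3), c(0.5, 0.5))
  expect_equal(softmax_probs(c(2, -1), 0), c(0.5, 0.5))
  p <- softmax_probs(c(0.7, 0.3), 5)
  expect_equal(p[1], 1 / (1 + exp(-2)), tolerance = 1e-10)
  betas <- seq(0, 10, by = 0.5)
  ps <- vapply(betas, function(b) softmax_probs(c(0.6, 0.2), b)[1],
               numeric(1))
  expect_true(all(diff(ps) >= 0))
  expect_equal(sum(softmax_probs(c(1000, 999), 10)), 1)  # overflow-safe
})

test_that("trial processing emits probabilities before learning", {
  trial <- data.frame(trial = 1, a1 = "right", s2 = "R1",
                      transition = "common", a2 = "left", s3 = "O25",
                      reward_yen = 25)
  st <- init_learner_state(task, learner_params(0.5, 0.2, 5, 0.5))
  r <- process_trial(st, trial, task)
  expect_equal(r$p1, 0.5)       # fresh agent is indifferent at any beta
  expect_equal(r$p2, 0.5)
  expect_equal(r$delta_spe1, 0.5)
  expect_equal(r$delta_spe2, 0.5)
  expect_equal(r$delta_rpe1, 0)            # Q(s2, a2) still 0 at stage 1
  expect_equal(r$delta_rpe2, 1)            # scaled 25-yen reward

  # zero learning rates: the first trial still replaces the neutral
  # FORWARD table with the one implied by the (unchanged) uniform
  # transition beliefs, after which everything is frozen
  st <- init_learner_state(task, learner_params(0, 0, 5, 0.5))
  probs <- replicate(6, {
    r <- process_trial(st, trial, task)
    st <<- r$state
    c(r$p1, r$p2)
  })
  expect_equal(probs[, 1], c(0.5, 0.5))
  for (j in 3:6) expect_equal(probs[, j], probs[, 2])
})

test_that("single fuzzed trials match the straight-line oracle", {
  set.seed(31)
  for (i in 1:10) {
    trials <- random_trials(1, task)
    st <- init_learner_state(task, learner_params(0.5, 0.2, 5, 0.5))
    r <- process_trial(st, trials[1, ], task)
    expect_equal(-log(r$p1) - log(r$p2),
                 oracle_nll(0.5, 0.2, 5, 0.5, trials, task),
                 tolerance = 1e-12)
  }
})

test_that("w = 0 ignores FORWARD values and w = 1 ignores SARSA values", {
  set.seed(12)
  trials <- random_trials(15, task)
  base <- init_learner_state(task, learner_params(0.4, 0.3, 4, 0))
  skew <- base
  skew$t_hat$p <- rep(c(0.9, 0.1), 10)     # wildly different beliefs
  l1 <- trial_loglik(learner_params(0.4, 0.3, 4, 0), trials, task, base)
  l2 <- trial_loglik(learner_params(0.4, 0.3, 4, 0), trials, task, skew)
  expect_equal(l1$nll, l2$nll)             # SARSA path blind to t_hat

  base <- init_learner_state(task, learner_params(0.4, 0.3, 4, 1))
  skew <- base
  skew$q_sarsa[] <- runif(10)
  l1 <- trial_loglik(learner_params(0.4, 0.3, 4, 1), trials, task, base)
  l2 <- trial_loglik(learner_params(0.4, 0.3, 4, 1), trials, task, skew)
  expect_equal(l1$nll, l2$nll)             # FORWARD path blind to q_sarsa
})

test_that("generative episodes are seed-reproducible and start unbiased", {
  st <- init_learner_state(task, learner_params(0.2, 0.2, 5, 0.5))
  set.seed(77); e1 <- act_episode(st, task)
  set.seed(77); e2 <- act_episode(st, task)
  expect_identical(e1$trial, e2$trial)

  set.seed(14)
  first <- replicate(400, act_episode(st, task)$trial$a1)
  expect_lt(abs(mean(first == "right") - 0.5), 0.08)

  # sharp values plus high beta pin the first action
  stq <- init_learner_state(task, learner_params(0.2, 0.2, 10, 0))
  stq$q_sarsa["S0", "right"] <- 1
  set.seed(15)
  first <- replicate(200, act_episode(stq, task)$trial$a1)
  expect_gt(mean(first == "right"), 0.98)
})
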