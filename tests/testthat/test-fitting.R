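task <- two_step_task()

test_that("posterior objective has the closed prior form on empty data", {
  empty <- random_trials(1, task)[0, ]
  val <- neg_log_posterior(c(alpha = 0.5, eta = 0.5, beta = 3, w = 0.5),
                           empty, task)
  expected <- -log(1.5) - log(1.5) - dgamma(3, shape = 2, scale = 3,
                                            log = TRUE)
  expect_equal(val, expected, tolerance = 1e-12)
  expect_equal(dbeta(0.5, 2, 2), 1.5)   # anchor for the closed form

  # data can only add likelihood mass on top of the prior penalty
  set.seed(2)
  trials <- random_trials(10, task)
  expect_gte(neg_log_posterior(c(alpha = 0.5, eta = 0.5, beta = 3,
                                 w = 0.5), trials, task),
             expected)
  expect_error(neg_log_posterior(c(alpha = 0, eta = 0.5, beta = 3,
                                   w = 0.5), empty, task),
               "bound")
})

test_that("rate parameterization of the inverse-temperature prior differs", {
  ps <- prior_spec(beta_parameterization = "scale")
  pr <- prior_spec(beta_parameterization = "rate")
  expect_equal(ps$modes[["beta"]], 3)
  expect_equal(pr$modes[["beta"]], 1 / 3)
})

test_that("empty-data MAP sits at the analytic prior modes", {
  empty <- random_trials(1, task)[0, ]
  set.seed(10)
  fit <- fit_map_block(empty, task, n_restarts = 4)
  expect_equal(fit$params[["alpha"]], 0.5, tolerance = 1e-4)
  expect_equal(fit$params[["eta"]], 0.5, tolerance = 1e-4)
  expect_equal(fit$params[["beta"]], 3, tolerance = 1e-4)
})

test_that("refitting from the optimum is idempotent", {
  set.seed(13)
  sim <- simulate_hybrid_agent(task, 0.2, 0.2, 5, 0.5, n_trials = 40)
  f1 <- fit_map_block(sim$trials, task, n_restarts = 5)
  f2 <- fit_map_block(sim$trials, task, start = f1$params, n_restarts = 1)
  expect_equal(f2$nlp, f1$nlp, tolerance = 1e-6)
  expect_true(f1$convergence)
})

test_that("blockwise fit returns one entry per block with carryover", {
  set.seed(19)
  sim <- simulate_hybrid_agent(task, 0.25, 0.3, 5, 0.6, n_trials = 200)
  fit <- fit_learner(sim$trials, "hybrid", task, n_restarts = 5,
                     n_restarts_later = 3)
  expect_s3_class(fit, "rl_fit")
  expect_equal(nrow(fit$estimates), 5L)
  expect_equal(dim(coef(fit)), c(5L, 4L))
  expect_true(all(fit$estimates$alpha > 0 & fit$estimates$alpha < 1))
  expect_true(all(fit$estimates$beta > 0 & fit$estimates$beta < 10))
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), -sum(fit$estimates$nll))
  expect_equal(attr(ll, "df"), 20)
  # predict returns the teacher-forced probabilities of the fitted data
  pr <- predict(fit)
  expect_equal(nrow(pr), 200L)
  expect_true(all(pr$p1 > 0 & pr$p1 < 1))
  blk1 <- pr[pr$block == 1, ]
  p1 <- unlist(fit$estimates[1, c("alpha", "eta", "beta", "w")])
  expect_equal(-sum(log(blk1$p1)) - sum(log(blk1$p2)),
               fit$estimates$nll[1], tolerance = 1e-8)
  # simulate() round-trips through the fitted parameters
  s <- simulate(fit, nsim = 2, seed = 4)
  expect_length(s, 2)
  expect_equal(nrow(s[[1]]), 200L)
})

test_that("without carryover the blocks are fitted in isolation", {
  set.seed(23)
  sim <- simulate_hybrid_agent(task, 0.25, 0.3, 5, 0.6, n_trials = 80)
  set.seed(1)
  fit <- fit_learner(sim$trials, "hybrid", task, carryover = FALSE,
                     n_restarts = 5)
  set.seed(1)
  b2 <- fit_map_block(sim$trials[41:80, ], task, n_restarts = 5)
  # block 2 must be reproducible from its own trials alone
  expect_equal(unlist(fit$estimates[2, c("alpha", "eta", "beta", "w")]),
               b2$params, tolerance = 1e-5)
})

test_that("fixed-effects fitting reduces to the individual fit for n = 1", {
  set.seed(29)
  sim <- simulate_hybrid_agent(task, 0.2, 0.3, 5, 0.5, n_trials = 80)
  set.seed(2)
  fe <- fit_fixed_effects(list(sim$trials), "hybrid", task,
                          n_restarts = 5, n_restarts_later = 3)
  set.seed(2)
  fi <- fit_learner(sim$trials, "hybrid", task, n_restarts = 5,
                    n_restarts_later = 3)
  expect_equal(as.matrix(fe$estimates[, c("alpha", "eta", "beta", "w")]),
               coef(fi)[1:2, ], tolerance = 1e-4, ignore_attr = TRUE)

  # duplicating a participant leaves the argmin unchanged when the prior
  # scales with the group (objective is exactly doubled)
  set.seed(3)
  fe1 <- fit_fixed_effects(list(sim$trials), "hybrid", task,
                           n_restarts = 5, n_restarts_later = 3,
                           prior_weight = "per_participant")
  set.seed(3)
  fe2 <- fit_fixed_effects(list(sim$trials, sim$trials), "hybrid", task,
                           n_restarts = 5, n_restarts_later = 3,
                           prior_weight = "per_participant")
  expect_equal(as.matrix(fe2$estimates[, c("alpha", "eta", "beta", "w")]),
               as.matrix(fe1$estimates[, c("alpha", "eta", "beta", "w")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("pooled fixed-effects estimates sit between the extremes of a
           heterogeneous pair", {
  set.seed(31)
  lo <- simulate_hybrid_agent(task, 0.2, 0.2, 5, 0.1, n_trials = 40)
  hi <- simulate_hybrid_agent(task, 0.2, 0.2, 5, 0.9, n_trials = 40)
  set.seed(4)
  fe <- fit_fixed_effects(list(lo$trials, hi$trials), "hybrid", task,
                          n_restarts = 8)
  set.seed(4)
  flo <- fit_map_block(lo$trials, task, n_restarts = 8)
  set.seed(4)
  fhi <- fit_map_block(hi$trials, task, n_restarts = 8)
  rng <- range(flo$params[["w"]], fhi$params[["w"]])
  expect_gte(fe$estimates$w[1], rng[1] - 0.1)
  expect_lte(fe$estimates$w[1], rng[2] + 0.1)
})

test_that("BIC has its closed form", {
  expect_equal(bic(100, 4, 400), 200 + 4 * log(400))
  expect_equal(bic(57.3, 0, 80), 114.6)
  expect_error(bic(10, 2, 0), "positive")
})

test_that("parameter correlations are symmetric with unit diagonal", {
  fake_fit <- function(a, e, b, w) {
    structure(list(estimates = data.frame(block = 1, alpha = a, eta = e,
                                          beta = b, w = w)),
              class = "rl_fit")
  }
  # alpha and eta perfectly monotone, w anti-monotone with alpha
  fits <- Map(fake_fit, a = c(.1, .2, .3, .4), e = c(.2, .3, .5, .6),
              b = c(5, 2, 7, 1), w = c(.9, .7, .5, .2))
  m <- parameter_correlations(fits, 1)
  expect_equal(m["alpha", "eta"], 1)
  expect_equal(m["alpha", "w"], -1)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 4))
  expect_error(parameter_correlations(fits[1:2], 1), "three")

  fits_const <- Map(fake_fit, a = c(.1, .2, .3), e = c(.5, .5, .5),
                    b = c(5, 2, 7), w = c(.9, .7, .5))
  expect_warning(mc <- parameter_correlations(fits_const, 1), "constant")
  expect_true(is.na(mc["eta", "alpha"]))
  expect_equal(mc["eta", "eta"], 1)
})

test_that("recovery report summarizes matched estimates", {
  set.seed(37)
  true <- data.frame(alpha = runif(20), eta = runif(20),
                     beta = runif(20, 0, 10), w = runif(20))
  r <- recovery_report(true, true)
  expect_equal(r$bias, rep(0, 4))
  expect_equal(r$rmse, rep(0, 4))
  expect_equal(r$rho, rep(1, 4))
  shuffled <- true[sample(nrow(true)), ]
  rs <- recovery_report(true, shuffled)
  expect_true(all(abs(rs$rho) < 0.6))
  expect_error(recovery_report(true, true[1:3, ]), "mismatch")
})
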