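#' Simulate one HYBRID agent through the task
#'
#' Generative roll-out of a HYBRID learner (compiled core). Parameters may
#' be scalars or per-trial vectors, so blockwise schedules — e.g. a
#' model-based weight of 1 in the first block and 0.5 thereafter — cost
#' nothing. Uses R's random number stream.
#'
#' @param task A `twostep_task`.
#' @param alpha,eta,beta,w Scalars or vectors of length `n_trials`.
#' @param n_trials Number of trials; defaults to the longest parameter
#'   vector, or the task's `n_trials` for scalars.
#' @param init Optional `learner_state` to start from.
#' @return List with `trials` (trial-log data frame), `q1_left`/`q1_right`
#'   (per-trial hybrid stage-1 values at emission time), `surprise1`
#'   (1 minus the estimated probability of the observed stage-1
#'   transition, before that trial's update) and `end_state`.
#' @export
simulate_hybrid_agent <- function(task, alpha = 0.2, eta = 0.2, beta = 5,
                                  w = 0.5, n_trials = NULL, init = NULL) {
  if (is.null(n_trials))
    n_trials <- max(length(alpha), length(eta), length(beta), length(w),
                    if (max(lengths(list(alpha, eta, beta, w))) == 1L)
                      task$n_trials else 0L)
  alpha <- rep_len(alpha, n_trials); eta <- rep_len(eta, n_trials)
  beta <- rep_len(beta, n_trials); w <- rep_len(w, n_trials)
  arr <- task_arrays(task)
  if (is.null(init)) init <- init_learner_state(task)
  flat <- state_to_flat(init, task)
  res <- sim_hybrid_cpp(alpha, eta, beta, w, arr$s1succ, arr$s1prob,
                        arr$er, arr$s2prob, arr$outidx, flat$qs, flat$qf,
                        flat$th)
  s2 <- task$states$stage2[res$s2 + 1L]
  p_taken <- arr$s1prob[cbind(res$a1 + 1L, res$slot1 + 1L)]
  s3 <- task$states$outcomes[res$out + 1L]
  trials <- data.frame(
    trial = seq_len(n_trials),
    a1 = task$actions[res$a1 + 1L], s2 = s2,
    transition = transition_label(p_taken),
    a2 = task$actions[res$a2 + 1L], s3 = s3,
    reward_yen = unname(task$reward_yen[s3]),
    stringsAsFactors = FALSE)
  lp <- learner_params(alpha[n_trials], eta[n_trials], beta[n_trials],
                       w[n_trials])
  list(trials = trials, q1_left = res$q1l, q1_right = res$q1r,
       surprise1 = res$surprise1,
       end_state = flat_to_state(res$qs, res$qf, res$th, task, lp))
}

#' Specification of a weight-schedule simulation
#'
#' The model-based schedule sets the HYBRID weight to 1 for the first
#' block and 0.5 thereafter; the model-free schedule starts at 0 instead.
#' The remaining parameters default to the fixed-effects estimates used in
#' fixed-effects analyses of this task family (alpha = eta = 0.2, beta = 5).
#'
#' @param schedule `"model_based"`, `"model_free"` or a numeric vector of
#'   per-block weights.
#' @param alpha,eta,beta Fixed learner parameters.
#' @param n_reps Number of repetitions (independent agents).
#' @param n_trials,block_size Session layout; schedule length must equal
#'   `n_trials / block_size`.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(schedule = c("model_based", "model_free"),
                     alpha = 0.2, eta = 0.2, beta = 5.0, n_reps = 1000L,
                     n_trials = 200L, block_size = 40L) {
  n_blocks <- n_trials %/% block_size
  if (is.character(schedule)) {
    schedule <- match.arg(schedule)
    w <- c(if (schedule == "model_based") 1 else 0,
           rep(0.5, n_blocks - 1L))
  } else {
    w <- schedule
    if (length(w) != n_blocks) stop("schedule length must equal n_blocks")
  }
  if (any(w < 0 | w > 1)) stop("weights must lie in [0, 1]")
  structure(list(w_schedule = w, alpha = alpha, eta = eta, beta = beta,
                 n_reps = as.integer(n_reps), n_trials = as.integer(n_trials),
                 block_size = as.integer(block_size)), class = "sim_spec")
}

#' Run a weight-schedule simulation
#'
#' Simulates `n_reps` independent HYBRID agents under the given blockwise
#' weight schedule and records, per repetition and trial, the obtained
#' reward and the stage-1 hybrid values of both actions at emission time.
#'
#' @param spec A [sim_spec()].
#' @param task A `twostep_task`.
#' @param seed Optional seed for reproducibility.
#' @return A `schedule_sim` list with matrices `reward_yen`, `q1_right`,
#'   `q1_left` (repetitions x trials) and the `spec`.
#' @export
run_weight_schedule_sim <- function(spec, task = two_step_task(),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_trials
  w_t <- rep(spec$w_schedule, each = spec$block_size)
  rew <- q1r <- q1l <- matrix(NA_real_, spec$n_reps, n)
  for (r in seq_len(spec$n_reps)) {
    sim <- simulate_hybrid_agent(task, spec$alpha, spec$eta, spec$beta,
                                 w_t, n_trials = n)
    rew[r, ] <- sim$trials$reward_yen
    q1r[r, ] <- sim$q1_right
    q1l[r, ] <- sim$q1_left
  }
  structure(list(spec = spec, reward_yen = rew, q1_right = q1r,
                 q1_left = q1l), class = "schedule_sim")
}

#' Stage-1 value difference Q(1,R) - Q(1,L)
#'
#' @param sim A `schedule_sim`.
#' @return Matrix (repetitions x trials) of per-trial value differences;
#'   the first trial is 0 by construction (fresh agents are indifferent).
#' @export
q_difference <- function(sim) sim$q1_right - sim$q1_left

#' Fit an origin-constrained sigmoid to a learning curve
#'
#' Nonlinear least squares for `y = a / (1 + exp(-b x)) - a / 2`, which
#' passes through the origin by construction. The plateau `a` enters
#' linearly for fixed slope `b`, so `a` is profiled out analytically and
#' `b` found by bounded one-dimensional minimization — no starting values
#' are needed.
#'
#' @param x Trial indices.
#' @param y Value-difference series.
#' @param b_max Upper bound on the slope search (default 5).
#' @return List with `a` (plateau), `b` (slope, the learning-speed
#'   statistic), `rss` and `converged` (FALSE for degenerate input, a
#'   non-positive plateau, or a slope at the search boundary).
#' @export
fit_origin_sigmoid <- function(x, y, b_max = 5) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(y) == 0)
    return(list(a = NA_real_, b = NA_real_, rss = NA_real_,
                converged = FALSE))
  rss_b <- function(b) {
    g <- 1 / (1 + exp(-b * x)) - 0.5
    den <- sum(g * g)
    if (den < 1e-12) return(sum(y^2))
    a <- sum(g * y) / den
    sum((y - a * g)^2)
  }
  opt <- stats::optimize(rss_b, interval = c(1e-6, b_max), tol = 1e-10)
  b <- opt$minimum
  g <- 1 / (1 + exp(-b * x)) - 0.5
  a <- sum(g * y) / sum(g * g)
  conv <- is.finite(a) && a > 0 && b > 2e-6 && b < b_max - 1e-4
  list(a = a, b = b, rss = opt$objective, converged = conv)
}

#' Rank-sum comparison of learning-speed slopes
#'
#' Two-sample Wilcoxon rank-sum test of the sigmoid slopes of two
#' simulated learner populations, with the normal-approximation z
#' statistic (positive when the first sample is stochastically larger).
#'
#' @param slopes_a,slopes_b Numeric slope samples.
#' @return List with `statistic` (rank-sum W of the first sample), `z` and
#'   the two-sided `p.value`.
#' @export
compare_learning_speed <- function(slopes_a, slopes_b) {
  stopifnot(length(slopes_a) > 0, length(slopes_b) > 0)
  if (stats::sd(c(slopes_a, slopes_b)) == 0)
    return(list(statistic = NA_real_, z = NA_real_, p.value = NA_real_,
                tied = TRUE))
  n1 <- length(slopes_a); n2 <- length(slopes_b)
  r <- rank(c(slopes_a, slopes_b))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sig <- sqrt(n1 * n2 / 12 *
                ((n1 + n2 + 1) - sum(ties^3 - ties) /
                   ((n1 + n2) * (n1 + n2 - 1))))
  z <- (W - mu) / sig
  list(statistic = W, z = z, p.value = 2 * stats::pnorm(-abs(z)),
       tied = FALSE)
}

#' Simulation from group-wise fitted parameters
#'
#' Simulates a cohort of HYBRID agents per group from per-block parameter
#' sets (e.g. the fixed-effects estimates of the proself and prosocial
#' groups) and summarizes early-session reward gain and learning-speed
#' slopes for comparison.
#'
#' @param params_a,params_b Data frames with columns `block`, `alpha`,
#'   `eta`, `beta`, `w` (one row per block).
#' @param task A `twostep_task`.
#' @param n_reps Repetitions per group.
#' @param block_size Trials per block.
#' @param seed Optional seed.
#' @param labels Group labels for the output.
#' @return List with `summary` (per group: mean first-block reward, median
#'   slope, slope fit counts), `reward_test` (two-sample t-test on
#'   per-repetition first-block mean reward) and `slope_test`
#'   ([compare_learning_speed()] output, group a vs b).
#' @export
recovery_sim_from_group_params <- function(params_a, params_b,
                                           task = two_step_task(),
                                           n_reps = 200L, block_size = 40L,
                                           seed = NULL,
                                           labels = c("a", "b")) {
  if (!is.null(seed)) set.seed(seed)
  run_group <- function(pars) {
    expand <- function(v) rep(v, each = block_size)
    n <- nrow(pars) * block_size
    early <- numeric(n_reps)
    slopes <- rep(NA_real_, n_reps)
    for (r in seq_len(n_reps)) {
      sim <- simulate_hybrid_agent(task, expand(pars$alpha),
                                   expand(pars$eta), expand(pars$beta),
                                   expand(pars$w), n_trials = n)
      early[r] <- mean(sim$trials$reward_yen[seq_len(block_size)])
      f <- fit_origin_sigmoid(seq_len(n), sim$q1_right - sim$q1_left)
      if (f$converged) slopes[r] <- f$b
    }
    list(early = early, slopes = slopes[!is.na(slopes)],
         n_failed = sum(is.na(slopes)))
  }
  ga <- run_group(params_a)
  gb <- run_group(params_b)
  summary <- data.frame(
    group = labels,
    mean_early_reward = c(mean(ga$early), mean(gb$early)),
    median_slope = c(stats::median(ga$slopes), stats::median(gb$slopes)),
    n_slope_fits = c(length(ga$slopes), length(gb$slopes)),
    n_failed_fits = c(ga$n_failed, gb$n_failed))
  list(summary = summary,
       reward_test = stats::t.test(ga$early, gb$early),
       slope_test = compare_learning_speed(ga$slopes, gb$slopes))
}
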