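#' Prior specification for MAP estimation
#'
#' Regularizing priors for the learning parameters: beta(2, 2) on both
#' learning rates and a gamma prior on the inverse temperature. The gamma
#' prior defaults to shape 2 and scale 3 (mode 3, mean 6), consistent with
#' inverse temperatures of roughly 3-6 under the bound `beta < 10`; the
#' shape/rate reading is selectable. The model-based weight `w` receives no
#' prior penalty — it is only bound-constrained.
#'
#' @param alpha_shape,eta_shape Length-2 shape vectors of the beta priors.
#' @param beta_shape Gamma shape.
#' @param beta_scale Gamma scale (or rate, see `beta_parameterization`).
#' @param beta_parameterization `"scale"` (default) or `"rate"`.
#' @return A `prior_spec` list with a `log_density(param_name, value)`
#'   function.
#' @export
prior_spec <- function(alpha_shape = c(2, 2), eta_shape = c(2, 2),
                       beta_shape = 2, beta_scale = 3,
                       beta_parameterization = c("scale", "rate")) {
  beta_parameterization <- match.arg(beta_parameterization)
  sc <- if (beta_parameterization == "scale") beta_scale else 1 / beta_scale
  ld <- function(param, value) {
    switch(param,
           alpha = stats::dbeta(value, alpha_shape[1], alpha_shape[2],
                                log = TRUE),
           eta = stats::dbeta(value, eta_shape[1], eta_shape[2], log = TRUE),
           beta = stats::dgamma(value, shape = beta_shape, scale = sc,
                                log = TRUE),
           w = 0)
  }
  structure(list(alpha_shape = alpha_shape, eta_shape = eta_shape,
                 beta_shape = beta_shape, beta_scale = sc,
                 log_density = ld,
                 modes = c(alpha = (alpha_shape[1] - 1) /
                             (sum(alpha_shape) - 2),
                           eta = (eta_shape[1] - 1) / (sum(eta_shape) - 2),
                           beta = max(0, (beta_shape - 1) * sc))),
            class = "prior_spec")
}

#' Negative log posterior density
#'
#' The MAP objective: teacher-forced negative log-likelihood plus the
#' negative log prior densities of the model's free parameters (the weight
#' `w` contributes nothing).
#'
#' @param params Named vector or `learner_params` with the full parameter
#'   set.
#' @param trials Trial-log data frame (may have zero rows).
#' @param task A `twostep_task`.
#' @param priors A [prior_spec()].
#' @param model `"hybrid"`, `"sarsa"` or `"forward"`.
#' @param init Optional initial `learner_state`.
#' @return The scalar objective value.
#' @export
neg_log_posterior <- function(params, trials, task, priors = prior_spec(),
                              model = "hybrid", init = NULL) {
  if (is.list(params))
    params <- c(alpha = params$alpha, eta = params$eta, beta = params$beta,
                w = params$w)
  check_bounds(params, model)
  nll <- trial_loglik(params, trials, task, init = init, model = model)$nll
  pen <- -sum(vapply(free_names(model), function(nm)
    priors$log_density(nm, params[[nm]]), numeric(1)))
  nll + pen
}

check_bounds <- function(params, model) {
  nm <- free_names(model)
  lo <- c(alpha = 0, eta = 0, beta = 0, w = 0)
  hi <- c(alpha = 1, eta = 1, beta = 10, w = 1)
  open <- setdiff(nm, "w")
  bad <- params[open] <= lo[open] | params[open] >= hi[open]
  if (any(bad))
    stop(sprintf("parameter %s outside its open bound",
                 paste(open[bad], collapse = ", ")))
  if ("w" %in% nm && (params[["w"]] < 0 || params[["w"]] > 1))
    stop("w outside [0, 1]")
  invisible(TRUE)
}

# bounds on the free-parameter vector, kept strictly inside the open
# constraints for the box-constrained optimizer
free_bounds <- function(model, eps = 1e-6) {
  nm <- free_names(model)
  lo <- c(alpha = eps, eta = eps, beta = eps, w = eps)[nm]
  hi <- c(alpha = 1 - eps, eta = 1 - eps, beta = 10 - eps, w = 1 - eps)[nm]
  list(lower = lo, upper = hi)
}

# --- internal fast path -----------------------------------------------------
# The optimizer evaluates the likelihood thousands of times per block, so the
# trial log is encoded once and the compiled core called directly.

fresh_flat <- function(task) {
  state_to_flat(init_learner_state(task), task)
}

# returns list(nll_fn(full_params) -> nll, end_fn(full_params) -> flat state)
make_block_objective <- function(trials, task, flat) {
  if (nrow(trials) == 0L) {
    return(list(nll = function(full) 0, end = function(full) flat))
  }
  enc <- encode_trials(trials, task)
  nll <- function(full) {
    nll_hybrid_cpp(full, enc$a1, enc$s2, enc$slot1, enc$a2, enc$slot2,
                   enc$rsc, enc$arr$s1succ, enc$arr$er, flat$qs, flat$qf,
                   flat$th, FALSE)$nll
  }
  end <- function(full) {
    r <- nll_hybrid_cpp(full, enc$a1, enc$s2, enc$slot1, enc$a2, enc$slot2,
                        enc$rsc, enc$arr$s1succ, enc$arr$er, flat$qs,
                        flat$qf, flat$th, FALSE)
    list(qs = r$qs, qf = r$qf, th = r$th, nll = r$nll)
  }
  list(nll = nll, end = end)
}

lhs_starts <- function(start, nm, bounds, n_restarts) {
  starts <- matrix(pmin(pmax(start[nm], bounds$lower), bounds$upper),
                   nrow = 1, dimnames = list(NULL, nm))
  if (n_restarts > 1) {
    u <- lhs::randomLHS(n_restarts - 1L, length(nm))
    extra <- sweep(sweep(u, 2, bounds$upper - bounds$lower, "*"),
                   2, bounds$lower, "+")
    colnames(extra) <- nm
    starts <- rbind(starts, extra)
  }
  starts
}

run_starts <- function(obj, starts, bounds) {
  best <- NULL
  converged <- FALSE
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                   lower = bounds$lower, upper = bounds$upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
    if (res$convergence == 0) converged <- TRUE
  }
  if (is.null(best)) stop("all optimizer starts failed")
  list(best = best, converged = converged)
}

#' MAP fit of one block of trials
#'
#' Box-constrained minimization of [neg_log_posterior()] (`optim` with
#' L-BFGS-B) from multiple starts: the supplied start first, then
#' Latin-hypercube draws within the bounds. The best converged solution is
#' kept; if no start converges the best found is returned flagged.
#'
#' @param trials Trial-log data frame for the block.
#' @param task A `twostep_task`.
#' @param init_state `learner_state` carried into the block (`NULL` =
#'   fresh).
#' @param start Named vector of full starting parameters; default = prior
#'   modes with `w = 0.5`.
#' @param priors A [prior_spec()].
#' @param model `"hybrid"`, `"sarsa"` or `"forward"`.
#' @param n_restarts Total number of optimizer starts.
#' @return List with `params` (full named vector), `nll`, `nlp`,
#'   `end_state`, `convergence` (TRUE if any start converged) and
#'   `n_restarts_used`.
#' @export
fit_map_block <- function(trials, task, init_state = NULL, start = NULL,
                          priors = prior_spec(), model = "hybrid",
                          n_restarts = 10) {
  nm <- free_names(model)
  bounds <- free_bounds(model)
  if (is.null(start))
    start <- c(priors$modes, w = 0.5)
  flat <- if (is.null(init_state)) fresh_flat(task)
          else if (is.list(init_state) && !is.null(init_state$qs)) init_state
          else state_to_flat(init_state, task)
  blk <- make_block_objective(trials, task, flat)
  obj <- function(par_free) {
    full <- full_params(par_free, model)
    blk$nll(full) - sum(vapply(nm, function(p)
      priors$log_density(p, full[[p]]), numeric(1)))
  }
  starts <- lhs_starts(start, nm, bounds, n_restarts)
  opt <- run_starts(obj, starts, bounds)
  full <- full_params(opt$best$par, model)
  end <- blk$end(full)
  lp <- learner_params(full[["alpha"]], full[["eta"]], full[["beta"]],
                       full[["w"]])
  end_state <- if (nrow(trials) == 0L) init_learner_state(task, lp)
               else flat_to_state(end$qs, end$qf, end$th, task, lp)
  list(params = full, nll = if (nrow(trials) == 0L) 0 else end$nll,
       nlp = opt$best$value, end_state = end_state,
       end_flat = if (nrow(trials) == 0L) flat
                  else list(qs = end$qs, qf = end$qf, th = end$th),
       convergence = opt$converged, n_restarts_used = nrow(starts))
}

#' Blockwise MAP fit of one participant's session
#'
#' Divides the session into blocks (default 40 trials), fits each block by
#' MAP and, when `carryover` is on, passes both the fitted parameters (as
#' the next block's optimizer start) and the learner state at the block's
#' last trial — recomputed by replaying the block under its fitted
#' parameters — into the next block.
#'
#' @param data Trial-log data frame for one participant (columns `a1`,
#'   `s2`, `a2`, `s3`; a single `participant_id` if present), or a
#'   `participant_dataset` from [generate_cohort()].
#' @param model `"hybrid"` (default), `"sarsa"` or `"forward"`.
#' @param task A `twostep_task`.
#' @param block_size Trials per block.
#' @param carryover Carry values and parameters across blocks (default
#'   TRUE).
#' @param priors A [prior_spec()].
#' @param n_restarts Optimizer starts for the first block.
#' @param n_restarts_later Starts for subsequent blocks (first start is the
#'   previous block's estimate).
#' @return An object of class `rl_fit`; see [summary.rl_fit()],
#'   [coef.rl_fit()], [predict.rl_fit()], [simulate.rl_fit()].
#' @examples
#' \donttest{
#' task <- two_step_task()
#' set.seed(1)
#' agent <- simulate_hybrid_agent(task, alpha = 0.2, eta = 0.2, beta = 5,
#'                                w = rep(0.5, 200))
#' fit <- fit_learner(agent$trials, model = "hybrid", task = task)
#' coef(fit)
#' }
#' @export
fit_learner <- function(data, model = c("hybrid", "sarsa", "forward"),
                        task = two_step_task(), block_size = 40L,
                        carryover = TRUE, priors = prior_spec(),
                        n_restarts = 10, n_restarts_later = 5) {
  model <- match.arg(model)
  if (inherits(data, "participant_dataset")) data <- data$trials
  if (!is.null(data$participant_id) &&
      length(unique(data$participant_id)) > 1L)
    stop("data contains several participants; fit them one at a time")
  n <- nrow(data)
  if (n < block_size) stop("need at least one full block of trials")
  n_blocks <- n %/% block_size
  blocks <- split(seq_len(n_blocks * block_size),
                  rep(seq_len(n_blocks), each = block_size))

  est <- vector("list", n_blocks)
  states <- vector("list", n_blocks)
  state <- NULL
  start <- NULL
  for (b in seq_len(n_blocks)) {
    fit <- fit_map_block(data[blocks[[b]], , drop = FALSE], task,
                         init_state = if (carryover) state else NULL,
                         start = start, priors = priors, model = model,
                         n_restarts = if (b == 1 || !carryover) n_restarts
                                      else n_restarts_later)
    est[[b]] <- data.frame(block = b, t(fit$params), nll = fit$nll,
                           nlp = fit$nlp, convergence = fit$convergence,
                           n_restarts = fit$n_restarts_used)
    states[[b]] <- fit$end_state
    if (carryover) { state <- fit$end_flat; start <- fit$params }
  }
  estimates <- do.call(rbind, est)
  k <- length(free_names(model))
  estimates$bic <- bic(estimates$nll, k, 2L * block_size)
  structure(list(call = match.call(), model = model, task = task,
                 data = data, block_size = block_size,
                 carryover = carryover, priors = priors,
                 estimates = estimates, end_states = states,
                 k = k, n_trials = n_blocks * block_size),
            class = "rl_fit")
}

#' Fixed-effects group fit
#'
#' Per block, minimizes the sum of all group members' negative
#' log-likelihoods plus the prior penalty, with each participant's
#' learner state carried over individually under the shared fitted
#' parameters. By default the penalty is applied once in total — the
#' regularization of a shared parameter set should not grow with group
#' size — but a per-participant weighting is selectable (under it, fitting
#' a duplicated participant returns exactly the single-participant
#' estimates).
#'
#' @param datasets List of trial-log data frames or `participant_dataset`
#'   objects (one per participant).
#' @param model,task,block_size,priors,n_restarts,n_restarts_later As in
#'   [fit_learner()].
#' @param prior_weight `"once"` (default) or `"per_participant"`.
#' @return List of class `rl_fe_fit` with `estimates` (one row per block:
#'   shared parameters, pooled `nll`, `bic` on the pooled observations)
#'   and bookkeeping fields.
#' @export
fit_fixed_effects <- function(datasets,
                              model = c("hybrid", "sarsa", "forward"),
                              task = two_step_task(), block_size = 40L,
                              priors = prior_spec(), n_restarts = 10,
                              n_restarts_later = 5,
                              prior_weight = c("once", "per_participant")) {
  model <- match.arg(model)
  prior_weight <- match.arg(prior_weight)
  trials_list <- lapply(datasets, function(d)
    if (inherits(d, "participant_dataset")) d$trials else d)
  if (length(trials_list) == 0L) stop("empty group")
  n <- min(vapply(trials_list, nrow, integer(1)))
  n_blocks <- n %/% block_size
  nm <- free_names(model)
  bounds <- free_bounds(model)

  flats <- rep(list(fresh_flat(task)), length(trials_list))
  est <- vector("list", n_blocks)
  start <- c(prior_spec()$modes, w = 0.5)
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1) * block_size + 1):(b * block_size)
    blks <- lapply(seq_along(trials_list), function(i)
      make_block_objective(trials_list[[i]][idx, , drop = FALSE], task,
                           flats[[i]]))
    pw <- if (prior_weight == "once") 1 else length(trials_list)
    obj <- function(par_free) {
      full <- full_params(par_free, model)
      nll <- 0
      for (blk in blks) nll <- nll + blk$nll(full)
      nll - pw * sum(vapply(nm, function(p)
        priors$log_density(p, full[[p]]), numeric(1)))
    }
    nr <- if (b == 1) n_restarts else n_restarts_later
    starts <- lhs_starts(start, nm, bounds, nr)
    opt <- run_starts(obj, starts, bounds)
    full <- full_params(opt$best$par, model)
    nll <- 0
    for (i in seq_along(blks)) {
      end <- blks[[i]]$end(full)
      nll <- nll + end$nll
      flats[[i]] <- list(qs = end$qs, qf = end$qf, th = end$th)
    }
    n_obs <- 2L * block_size * length(trials_list)
    est[[b]] <- data.frame(block = b, t(full), nll = nll,
                           nlp = opt$best$value, n_obs = n_obs,
                           bic = bic(nll, length(nm), n_obs))
    start <- full
  }
  structure(list(model = model, estimates = do.call(rbind, est),
                 n_participants = length(trials_list),
                 block_size = block_size, k = length(nm)),
            class = "rl_fe_fit")
}

#' Bayesian information criterion
#'
#' `BIC = 2 * nll + k * log(n_obs)`; each trial contributes two
#' observations (one choice per stage).
#'
#' @param nll Negative log-likelihood.
#' @param k_params Number of free parameters.
#' @param n_obs Number of observations.
#' @return Numeric BIC value(s).
#' @export
bic <- function(nll, k_params, n_obs) {
  if (any(n_obs <= 0)) stop("n_obs must be positive")
  2 * nll + k_params * log(n_obs)
}

#' Pooled BIC model comparison across a cohort
#'
#' Per candidate model and 40-trial block, pools the cohort's teacher-forced
#' negative log-likelihood and reports
#' `BIC = 2 * NLL_pooled + k * log(n_obs_total)` with `k` the model's
#' parameter count. With `method = "individual"` (default) the pooled NLL
#' comes from per-participant blockwise MAP fits — each participant keeps
#' their own parameters, but the penalty counts the model's parameters
#' once, the convention commonly used when a single criterion per model is
#' computed from all participants' data. With `method = "fixed"` one
#' parameter set per block is shared across the group
#' ([fit_fixed_effects()]), making the penalty exact for the fitted
#' parameters.
#'
#' @param datasets List of trial-log data frames or `participant_dataset`s.
#' @param models Character vector of models to compare.
#' @param task,block_size,priors As in [fit_learner()].
#' @param n_restarts,n_restarts_later Optimizer starts passed through.
#' @param method `"individual"` or `"fixed"` (see Details).
#' @return Data frame with columns `model`, `block`, `nll`, `k`, `n_obs`,
#'   `bic`.
#' @export
compare_models <- function(datasets,
                           models = c("sarsa", "forward", "hybrid"),
                           task = two_step_task(), block_size = 40L,
                           priors = prior_spec(), n_restarts = 10,
                           n_restarts_later = 5,
                           method = c("individual", "fixed")) {
  method <- match.arg(method)
  out <- lapply(models, function(m) {
    if (method == "fixed") {
      fe <- fit_fixed_effects(datasets, model = m, task = task,
                              block_size = block_size, priors = priors,
                              n_restarts = n_restarts,
                              n_restarts_later = n_restarts_later)
      return(data.frame(model = m, block = fe$estimates$block,
                        nll = fe$estimates$nll, k = fe$k,
                        n_obs = fe$estimates$n_obs,
                        bic = fe$estimates$bic))
    }
    nll <- NULL
    for (d in datasets) {
      f <- fit_learner(d, m, task, block_size = block_size,
                       priors = priors, n_restarts = n_restarts,
                       n_restarts_later = n_restarts_later)
      nll <- if (is.null(nll)) f$estimates$nll else nll + f$estimates$nll
    }
    k <- length(free_names(m))
    n_obs <- 2L * block_size * length(datasets)
    data.frame(model = m, block = seq_along(nll), nll = nll, k = k,
               n_obs = n_obs, bic = bic(nll, k, n_obs))
  })
  do.call(rbind, out)
}

#' Spearman correlations between fitted parameters
#'
#' Rank-correlation matrix of the per-participant estimates of one block.
#' Constant parameter columns give `NA` entries and a warning rather than a
#' silent 0.
#'
#' @param fits List of `rl_fit` objects (one per participant).
#' @param block Block number.
#' @return 4x4 symmetric matrix over alpha, eta, beta, w with unit
#'   diagonal.
#' @export
parameter_correlations <- function(fits, block = 1L) {
  if (length(fits) < 3L) stop("need at least three participants")
  pars <- t(vapply(fits, function(f) {
    e <- f$estimates[f$estimates$block == block, ]
    c(alpha = e$alpha, eta = e$eta, beta = e$beta, w = e$w)
  }, numeric(4)))
  const <- apply(pars, 2, function(x) stats::sd(x) == 0)
  m <- suppressWarnings(stats::cor(pars, method = "spearman"))
  if (any(const)) {
    warning("constant parameter column(s): ",
            paste(colnames(pars)[const], collapse = ", "),
            "; correlations set to NA")
    m[const, ] <- NA; m[, const] <- NA
  }
  diag(m) <- 1
  m
}

#' Parameter-recovery summary
#'
#' Per-parameter bias, root-mean-square error and Spearman correlation
#' between matched true and fitted parameter tables.
#'
#' @param true,fitted Data frames with columns `alpha`, `eta`, `beta`, `w`
#'   and matched rows (one agent per row).
#' @return Data frame `parameter`, `bias`, `rmse`, `rho` (`rho` is `NA`
#'   when either column is constant).
#' @export
recovery_report <- function(true, fitted) {
  if (nrow(true) != nrow(fitted)) stop("true/fitted row mismatch")
  pars <- c("alpha", "eta", "beta", "w")
  do.call(rbind, lapply(pars, function(p) {
    d <- fitted[[p]] - true[[p]]
    rho <- if (stats::sd(true[[p]]) == 0 || stats::sd(fitted[[p]]) == 0)
      NA_real_
    else suppressWarnings(stats::cor(true[[p]], fitted[[p]],
                                     method = "spearman"))
    data.frame(parameter = p, bias = mean(d), rmse = sqrt(mean(d^2)),
               rho = rho)
  }))
}
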