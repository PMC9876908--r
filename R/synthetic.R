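# truncated normal via inverse-CDF (exact, vectorized)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  u <- stats::runif(n, stats::pnorm(lower, mean, sd),
                    stats::pnorm(upper, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Specification of a synthetic cohort
#'
#' Defines the generative conditions of a synthetic study cohort: group
#' sizes, per-group per-block means of the HYBRID parameters, between-
#' subject spread, SVO angle distributions and the reaction-time model.
#' Parameter-mean defaults are anchored to the whole-session group
#' estimates typical of proself/prosocial groups on this task (proself
#' alpha 0.34, eta 0.49, beta 5.21,
#' w 0.49; prosocial 0.33, 0.48, 4.58, 0.40) with the qualitative block
#' trends of the blockwise analysis: alpha decreasing, beta increasing,
#' and w decreasing from an elevated proself first-block value.
#'
#' @param n_proself,n_prosocial Group sizes.
#' @param proself_means,prosocial_means Lists of per-block mean vectors
#'   for `alpha`, `eta`, `beta`, `w` (length = number of blocks).
#' @param param_sd Named between-subject SDs for the four parameters.
#' @param svo_proself,svo_prosocial Mean/sd/lower/upper of the truncated
#'   normal SVO-angle distributions per group.
#' @param rt_model Reaction-time model constants: `rt1_asym`, `rt1_gain`,
#'   `rt1_tau` (ms, ms, trials), `rt2_base`, `rt2_surprise` (ms),
#'   `sd` (ms), `floor`, `cap` (ms).
#' @param n_trials,block_size Session layout.
#' @param seed Root seed; per-participant child seeds are derived from it
#'   and recorded in each dataset.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(
    n_proself = 40L, n_prosocial = 40L,
    proself_means = list(alpha = c(0.45, 0.38, 0.33, 0.29, 0.26),
                         eta = rep(0.49, 5),
                         beta = c(4.2, 4.9, 5.4, 5.7, 5.9),
                         w = c(0.75, 0.50, 0.45, 0.40, 0.35)),
    prosocial_means = list(alpha = c(0.44, 0.37, 0.32, 0.28, 0.24),
                           eta = rep(0.48, 5),
                           beta = c(3.6, 4.3, 4.8, 5.1, 5.1),
                           w = c(0.50, 0.43, 0.40, 0.37, 0.30)),
    param_sd = c(alpha = 0.12, eta = 0.12, beta = 1.0, w = 0.12),
    svo_proself = c(mean = 2, sd = 4, lower = -7.82, upper = 7.82),
    svo_prosocial = c(mean = 45, sd = 5, lower = 37.48, upper = 61.39),
    rt_model = list(rt1_asym = 480, rt1_gain = 170, rt1_tau = 30,
                    rt2_base = 520, rt2_surprise = 280, sd = 80,
                    floor = 150, cap = 2000),
    n_trials = 200L, block_size = 40L, seed = 1L) {
  structure(list(n_proself = as.integer(n_proself),
                 n_prosocial = as.integer(n_prosocial),
                 proself_means = proself_means,
                 prosocial_means = prosocial_means,
                 param_sd = param_sd, svo_proself = svo_proself,
                 svo_prosocial = svo_prosocial, rt_model = rt_model,
                 n_trials = as.integer(n_trials),
                 block_size = as.integer(block_size),
                 seed = as.integer(seed)), class = "cohort_spec")
}

#' Generate reaction times for simulated trials
#'
#' Invented but realistic RT model: the first-stage RT decays
#' exponentially with trial index toward an asymptote (practice effect);
#' the second-stage RT grows linearly with the learner's transition
#' surprise, `1 - T(s, a, s_observed)`, so rare transitions slow the
#' second response once the transition model is learned. Gaussian noise,
#' truncated to \[floor, cap\] ms.
#'
#' @param trial_index 1-based trial indices.
#' @param surprise Per-trial stage-1 transition surprise in \[0, 1\].
#' @param rt_model Constants list, see [cohort_spec()].
#' @return List with integer vectors `rt1_ms`, `rt2_ms`.
#' @export
generate_rts <- function(trial_index, surprise,
                         rt_model = cohort_spec()$rt_model) {
  stopifnot(all(surprise >= 0 & surprise <= 1))
  n <- length(trial_index)
  m <- rt_model
  rt1 <- m$rt1_asym + m$rt1_gain * exp(-(trial_index - 1) / m$rt1_tau) +
    stats::rnorm(n, 0, m$sd)
  rt2 <- m$rt2_base + m$rt2_surprise * surprise + stats::rnorm(n, 0, m$sd)
  clamp <- function(x) pmin(pmax(round(x), m$floor), m$cap)
  list(rt1_ms = as.integer(clamp(rt1)), rt2_ms = as.integer(clamp(rt2)))
}

#' Construct slider responses scoring a target SVO angle
#'
#' Inverse of [svo_angle()]: selects one option per primary item so the
#' scored angle is as close as possible to the target. The option space is
#' searched exactly — the six nine-option menus are split in half and all
#' 729 x 729 payoff sums enumerated — so the result is the global best
#' combination. Errors if even that falls outside `tol` (the target is
#' unattainable on the item table).
#'
#' @param target_angle Target angle in degrees.
#' @param items Item table, see [svo_items()].
#' @param tol Acceptable absolute deviation in degrees (default 1).
#' @return Data frame `item_id`, `self_payoff`, `other_payoff` (6 rows).
#' @export
generate_svo_responses <- function(target_angle, items = svo_items(),
                                   tol = 1) {
  menus <- split(items, items$item)
  if (length(menus) != 6L) stop("expected six primary items")
  half_sums <- function(idx) {
    grid <- expand.grid(k1 = 1:9, k2 = 1:9, k3 = 1:9)
    s <- menus[[idx[1]]]$self[grid$k1] + menus[[idx[2]]]$self[grid$k2] +
      menus[[idx[3]]]$self[grid$k3]
    o <- menus[[idx[1]]]$other[grid$k1] + menus[[idx[2]]]$other[grid$k2] +
      menus[[idx[3]]]$other[grid$k3]
    list(grid = grid, s = s, o = o)
  }
  h1 <- half_sums(1:3)
  h2 <- half_sums(4:6)
  s_tot <- outer(h1$s, h2$s, "+") / 6 - 50
  o_tot <- outer(h1$o, h2$o, "+") / 6 - 50
  ang <- atan2(o_tot, s_tot) * 180 / pi
  err <- abs(ang - target_angle)
  best <- arrayInd(which.min(err), dim(err))
  if (err[best] > tol)
    stop(sprintf("target angle %.2f not attainable within %.2f degrees",
                 target_angle, tol))
  pick <- c(unlist(h1$grid[best[1], ]), unlist(h2$grid[best[2], ]))
  data.frame(item_id = as.integer(names(menus)),
             self_payoff = mapply(function(it, k) it$self[k], menus, pick),
             other_payoff = mapply(function(it, k) it$other[k], menus, pick),
             row.names = NULL)
}

#' Generate a synthetic cohort
#'
#' For each participant: draws per-block true parameters from the group's
#' truncated-normal distributions, simulates a full session with the
#' HYBRID agent under the blockwise parameter schedule, attaches reaction
#' times driven by the agent's own transition surprise, and constructs
#' slider responses matching a group-consistent SVO angle. True parameters
#' are recorded for recovery studies.
#'
#' @param spec A [cohort_spec()].
#' @param task A `twostep_task`.
#' @return A `twostep_cohort`: list of `participant_dataset`s, each with
#'   `participant_id`, `group`, `seed`, `svo_angle`, `svo` (responses),
#'   `trials` (with RTs) and `true_params` (per-block data frame).
#' @export
generate_cohort <- function(spec = cohort_spec(), task = two_step_task()) {
  n_total <- spec$n_proself + spec$n_prosocial
  set.seed(spec$seed)
  child_seeds <- if (n_total > 0) sample.int(.Machine$integer.max, n_total)
                 else integer(0)
  groups <- rep(c("proself", "prosocial"),
                c(spec$n_proself, spec$n_prosocial))
  n_blocks <- spec$n_trials %/% spec$block_size
  items <- svo_items()
  bounds <- list(alpha = c(0.01, 0.99), eta = c(0.01, 0.99),
                 beta = c(0.1, 9.9), w = c(0.01, 0.99))

  cohort <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    set.seed(child_seeds[i])
    grp <- groups[i]
    means <- if (grp == "proself") spec$proself_means
             else spec$prosocial_means
    true <- data.frame(block = seq_len(n_blocks))
    for (p in c("alpha", "eta", "beta", "w"))
      true[[p]] <- rtruncnorm(n_blocks, means[[p]], spec$param_sd[[p]],
                              bounds[[p]][1], bounds[[p]][2])
    expand <- function(v) rep(v, each = spec$block_size)
    sim <- simulate_hybrid_agent(task, expand(true$alpha),
                                 expand(true$eta), expand(true$beta),
                                 expand(true$w), n_trials = spec$n_trials)
    rts <- generate_rts(sim$trials$trial, sim$surprise1, spec$rt_model)
    trials <- sim$trials
    trials$rt1_ms <- rts$rt1_ms
    trials$rt2_ms <- rts$rt2_ms
    trials <- cbind(participant_id = sprintf("P%03d", i), trials,
                    stringsAsFactors = FALSE)
    svo_par <- if (grp == "proself") spec$svo_proself else spec$svo_prosocial
    target <- rtruncnorm(1, svo_par[["mean"]], svo_par[["sd"]],
                         svo_par[["lower"]], svo_par[["upper"]])
    svo <- generate_svo_responses(target, items)
    cohort[[i]] <- structure(
      list(participant_id = sprintf("P%03d", i), group = grp,
           seed = child_seeds[i], svo_angle_target = target,
           svo = svo, trials = trials, true_params = true),
      class = "participant_dataset")
  }
  structure(cohort, class = "twostep_cohort", spec = spec)
}

#' @export
print.twostep_cohort <- function(x, ...) {
  groups <- vapply(x, function(p) p$group, character(1))
  cat("Synthetic two-step cohort:", length(x), "participants (",
      sum(groups == "proself"), "proself,",
      sum(groups == "prosocial"), "prosocial )\n")
  invisible(x)
}

#' Write / read a cohort as plain-text CSV files
#'
#' `write_cohort()` writes `trials.csv` (fixed trial-log header),
#' `svo.csv` and `truth.csv` (group label, child seed and per-block true
#' parameters) into `dir`; `read_cohort()` reconstructs the cohort
#' field-for-field.
#'
#' @param cohort A `twostep_cohort`.
#' @param dir Directory (created if missing).
#' @return `write_cohort()` the directory path invisibly; `read_cohort()`
#'   a `twostep_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trials <- do.call(rbind, lapply(cohort, function(p)
    p$trials[, c("participant_id", "trial", "a1", "s2", "transition",
                 "a2", "s3", "reward_yen", "rt1_ms", "rt2_ms")]))
  utils::write.csv(trials, file.path(dir, "trials.csv"), row.names = FALSE)
  svo <- do.call(rbind, lapply(cohort, function(p)
    cbind(participant_id = p$participant_id, p$svo)))
  utils::write.csv(svo, file.path(dir, "svo.csv"), row.names = FALSE)
  truth <- do.call(rbind, lapply(cohort, function(p)
    cbind(participant_id = p$participant_id, group = p$group,
          seed = p$seed, svo_angle_target = p$svo_angle_target,
          p$true_params)))
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  trials <- read_trial_log(file.path(dir, "trials.csv"))
  svo <- utils::read.csv(file.path(dir, "svo.csv"))
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  ids <- unique(truth$participant_id)
  cohort <- lapply(ids, function(id) {
    tp <- truth[truth$participant_id == id, ]
    structure(
      list(participant_id = id, group = tp$group[1], seed = tp$seed[1],
           svo_angle_target = tp$svo_angle_target[1],
           svo = svo[svo$participant_id == id,
                     c("item_id", "self_payoff", "other_payoff")],
           trials = trials[trials$participant_id == id, ],
           true_params = tp[, c("block", "alpha", "eta", "beta", "w")]),
      class = "participant_dataset")
  })
  cohort <- lapply(cohort, function(p) {
    rownames(p$svo) <- rownames(p$trials) <- rownames(p$true_params) <- NULL
    p
  })
  structure(cohort, class = "twostep_cohort")
}
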