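#' @export
print.rl_fit <- function(x, digits = 4, ...) {
  cat("Blockwise MAP fit (", toupper(x$model), " learner), ",
      nrow(x$estimates), " block(s) of ", x$block_size, " trials",
      if (x$carryover) ", carryover on" else "", "\n\n", sep = "")
  print(round(x$estimates[, c("block", "alpha", "eta", "beta", "w",
                              "nll", "bic")], digits))
  invisible(x)
}

#' Summarize a blockwise fit
#'
#' @param object An `rl_fit`.
#' @param ... Unused.
#' @return The object's estimate table plus totals, invisibly printed.
#' @export
summary.rl_fit <- function(object, ...) {
  est <- object$estimates
  out <- list(model = object$model, estimates = est,
              total_nll = sum(est$nll),
              total_bic = bic(sum(est$nll),
                              object$k * nrow(est),
                              2L * object$n_trials))
  class(out) <- "summary.rl_fit"
  out
}

#' @export
print.summary.rl_fit <- function(x, digits = 4, ...) {
  cat("Model:", toupper(x$model), "\n")
  print(round(x$estimates[, c("block", "alpha", "eta", "beta", "w",
                              "nll", "bic")], digits))
  cat(sprintf("\nSession NLL %.3f, session BIC %.3f\n",
              x$total_nll, x$total_bic))
  invisible(x)
}

#' Per-block parameter estimates
#'
#' @param object An `rl_fit`.
#' @param ... Unused.
#' @return Matrix with one row per block and columns alpha, eta, beta, w.
#' @export
coef.rl_fit <- function(object, ...) {
  m <- as.matrix(object$estimates[, c("alpha", "eta", "beta", "w")])
  rownames(m) <- paste0("block", object$estimates$block)
  m
}

#' @export
logLik.rl_fit <- function(object, ...) {
  structure(-sum(object$estimates$nll),
            df = object$k * nrow(object$estimates),
            nobs = 2L * object$n_trials, class = "logLik")
}

#' Teacher-forced choice probabilities under the fitted parameters
#'
#' Replays a trial log through the fitted per-block parameters (with the
#' fit's carryover scheme) and returns the model probability of each
#' observed choice.
#'
#' @param object An `rl_fit`.
#' @param newdata Optional trial-log data frame; defaults to the fitted
#'   data.
#' @param ... Unused.
#' @return Data frame `trial`, `block`, `p1`, `p2`.
#' @export
predict.rl_fit <- function(object, newdata = NULL, ...) {
  data <- if (is.null(newdata)) object$data else newdata
  if (inherits(data, "participant_dataset")) data <- data$trials
  bs <- object$block_size
  n_blocks <- nrow(object$estimates)
  n <- min(nrow(data), n_blocks * bs)
  state <- NULL
  out <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1) * bs + 1):min(b * bs, n)
    if (length(idx) == 0 || idx[1] > n) break
    pars <- unlist(object$estimates[b, c("alpha", "eta", "beta", "w")])
    lik <- trial_loglik(pars, data[idx, , drop = FALSE], object$task,
                        init = state, model = object$model,
                        per_trial = TRUE)
    out[[b]] <- data.frame(trial = idx, block = b,
                           p1 = exp(lik$lp1), p2 = exp(lik$lp2))
    if (object$carryover) state <- lik$end_state
  }
  do.call(rbind, out)
}

#' Simulate sessions from a fitted learner
#'
#' Generates synthetic sessions from the fitted per-block parameters (each
#' block's parameters applied to its trials, values carried across blocks).
#'
#' @param object An `rl_fit`.
#' @param nsim Number of sessions.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return List of `nsim` trial-log data frames.
#' @export
simulate.rl_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  est <- object$estimates
  bs <- object$block_size
  expand <- function(p) rep(p, each = bs)
  lapply(seq_len(nsim), function(i) {
    simulate_hybrid_agent(object$task, alpha = expand(est$alpha),
                          eta = expand(est$eta), beta = expand(est$beta),
                          w = expand(est$w))$trials
  })
}

#' Plot per-block parameter trajectories
#'
#' @param x An `rl_fit`.
#' @param ... Passed to `matplot`.
#' @export
plot.rl_fit <- function(x, ...) {
  est <- x$estimates
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::matplot(est$block, est[, c("alpha", "eta", "w")], type = "b",
                    pch = 1:3, lty = 1, ylim = c(0, 1), xlab = "block",
                    ylab = "estimate", ...)
  graphics::legend("topright", c("alpha", "eta", "w"), pch = 1:3,
                   col = 1:3, bty = "n")
  graphics::plot(est$block, est$beta, type = "b", xlab = "block",
                 ylab = "beta", ylim = c(0, 10))
  invisible(x)
}

#' @export
print.rl_fe_fit <- function(x, digits = 4, ...) {
  cat("Fixed-effects fit (", toupper(x$model), "), ",
      x$n_participants, " participants\n\n", sep = "")
  print(round(x$estimates[, c("block", "alpha", "eta", "beta", "w",
                              "nll", "bic")], digits))
  invisible(x)
}
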