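#' Moving-average reward with edge truncation
#'
#' Centered moving mean over a `window`-trial range in one-trial steps.
#' For the default even window of 20 the range spans the 10 trials before
#' through the 9 after the current trial (the convention of an even-window
#' centered moving mean); at the series edges the window is truncated and
#' the mean taken only over the available trials. The window placement is
#' configurable and recorded as attributes of the result.
#'
#' @param rewards Per-trial reward vector (yen).
#' @param window Window length in trials (default 20).
#' @param before,after Trials before/after the current one included in the
#'   window; default `floor(window/2)` before and the remainder after.
#' @return Data frame `trial`, `mean_reward`, `n_in_window`, with
#'   attributes `window_before`/`window_after`.
#' @export
moving_average_reward <- function(rewards, window = 20L, before = NULL,
                                  after = NULL) {
  n <- length(rewards)
  if (n == 0L) stop("empty reward series")
  if (is.null(before)) before <- window %/% 2L
  if (is.null(after)) after <- window - before - 1L
  out <- data.frame(trial = seq_len(n), mean_reward = NA_real_,
                    n_in_window = NA_integer_)
  for (i in seq_len(n)) {
    idx <- max(1L, i - before):min(n, i + after)
    out$mean_reward[i] <- mean(rewards[idx])
    out$n_in_window[i] <- length(idx)
  }
  attr(out, "window_before") <- before
  attr(out, "window_after") <- after
  out
}

#' Reaction-time block summaries split by transition type
#'
#' Mean first-stage RT and mean second-stage RT after common and after
#' rare transitions, per block of 40 trials. The first trial of the
#' session is excluded, missing RTs are dropped cell-wise, and an empty
#' cell (e.g. a block without rare transitions) yields `NA` rather than 0.
#'
#' @param trials Trial-log data frame with `trial`, `transition`,
#'   `rt1_ms`, `rt2_ms`.
#' @param block_size Trials per block (default 40).
#' @return Data frame `block`, `rt1_mean`, `rt2_common_mean`,
#'   `rt2_rare_mean`, `n_rt1`, `n_common`, `n_rare`.
#' @export
rt_block_summaries <- function(trials, block_size = 40L) {
  keep <- trials[trials$trial != 1L, , drop = FALSE]
  keep$block <- (keep$trial - 1L) %/% block_size + 1L
  cell_mean <- function(x) if (sum(!is.na(x)) == 0L) NA_real_
                           else mean(x, na.rm = TRUE)
  out <- do.call(rbind, lapply(split(keep, keep$block), function(b) {
    common <- b$transition == "common"
    data.frame(block = b$block[1],
               rt1_mean = cell_mean(b$rt1_ms),
               rt2_common_mean = cell_mean(b$rt2_ms[common]),
               rt2_rare_mean = cell_mean(b$rt2_ms[!common]),
               n_rt1 = sum(!is.na(b$rt1_ms)),
               n_common = sum(common & !is.na(b$rt2_ms)),
               n_rare = sum(!common & !is.na(b$rt2_ms)))
  }))
  rownames(out) <- NULL
  out
}

#' Per-trial rank-sum comparison of two groups' series
#'
#' Wilcoxon rank-sum test at every trial between the per-participant
#' series values of two groups (e.g. moving-average rewards of proself vs
#' prosocial participants). Trials where all values tie are flagged and
#' yield `NA`.
#'
#' @param series Matrix, participants in rows and trials in columns.
#' @param groups Vector with two levels, one entry per participant.
#' @return Data frame `trial`, `statistic`, `p.value`, `tied`.
#' @export
group_series_compare <- function(series, groups) {
  groups <- as.factor(groups)
  lv <- levels(groups)
  if (length(lv) != 2L) stop("exactly two groups are required")
  if (min(table(groups)) < 2L) stop("need at least two participants per group")
  out <- data.frame(trial = seq_len(ncol(series)), statistic = NA_real_,
                    p.value = NA_real_, tied = FALSE)
  for (j in seq_len(ncol(series))) {
    x <- series[groups == lv[1], j]
    y <- series[groups == lv[2], j]
    if (stats::sd(c(x, y)) == 0) { out$tied[j] <- TRUE; next }
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    out$statistic[j] <- unname(wt$statistic)
    out$p.value[j] <- wt$p.value
  }
  out
}

#' Tidy long-format table of per-trial metrics for a cohort
#'
#' One row per (participant, trial) with group label, transition type,
#' reward, RTs and the 20-trial moving-average reward — the layout a
#' mixed-model or ANOVA routine expects.
#'
#' @param cohort A `twostep_cohort` (see [generate_cohort()]) or a list of
#'   `participant_dataset`s.
#' @param window Moving-average window.
#' @return Data frame `participant_id`, `group`, `trial`, `block`,
#'   `transition`, `reward_yen`, `rt1_ms`, `rt2_ms`, `ma_reward`.
#' @export
cohort_trial_table <- function(cohort, window = 20L) {
  out <- do.call(rbind, lapply(cohort, function(p) {
    ma <- moving_average_reward(p$trials$reward_yen, window)$mean_reward
    data.frame(participant_id = p$participant_id, group = p$group,
               trial = p$trials$trial,
               block = (p$trials$trial - 1L) %/% 40L + 1L,
               transition = p$trials$transition,
               reward_yen = p$trials$reward_yen,
               rt1_ms = p$trials$rt1_ms, rt2_ms = p$trials$rt2_ms,
               ma_reward = ma, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
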