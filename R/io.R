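#' Read a trial-log CSV
#'
#' Reads a trial log in the package's dialect (header `participant_id,
#' trial, a1, s2, transition, a2, s3, reward_yen, rt1_ms, rt2_ms`) or, via
#' `col_map`, any CSV whose columns can be mapped onto it — a best-effort
#' adapter for externally deposited session files. Rows are validated
#' against the task layout and schema violations are reported with their
#' row numbers; missing RT cells are preserved as `NA`.
#'
#' @param path CSV file path.
#' @param col_map Optional named character vector mapping package column
#'   names to source column names, e.g.
#'   `c(a1 = "choice1", s2 = "state2")`.
#' @param task Task used for validation.
#' @return Validated trial-log data frame.
#' @export
read_trial_log <- function(path, col_map = NULL, task = two_step_task()) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map))
    for (target in names(col_map)) {
      if (!col_map[[target]] %in% names(d))
        stop("mapped column not found in file: ", col_map[[target]])
      names(d)[names(d) == col_map[[target]]] <- target
    }
  required <- c("participant_id", "trial", "a1", "s2", "transition", "a2",
                "s3", "reward_yen")
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("missing trial-log column(s): ", paste(missing, collapse = ", "))
  for (rt in c("rt1_ms", "rt2_ms")) if (!rt %in% names(d)) d[[rt]] <- NA
  bad <- which(!d$a1 %in% task$actions | !d$a2 %in% task$actions)
  if (length(bad))
    stop("unknown action label in row(s): ", paste(utils::head(bad, 5),
                                                   collapse = ", "))
  bad <- which(!d$transition %in% c("common", "rare"))
  if (length(bad))
    stop("malformed transition label in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!d$s2 %in% task$states$stage2)
  if (length(bad))
    stop("unknown stage-2 state in row(s): ", paste(utils::head(bad, 5),
                                                    collapse = ", "))
  bad <- which(!d$s3 %in% task$states$outcomes)
  if (length(bad))
    stop("unknown outcome state in row(s): ", paste(utils::head(bad, 5),
                                                    collapse = ", "))
  bad <- which(d$reward_yen != unname(task$reward_yen[d$s3]))
  if (length(bad))
    stop("reward inconsistent with outcome state in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  d
}

#' Write a trial log in the package dialect
#'
#' @param trials Trial-log data frame.
#' @param path Output CSV path.
#' @export
write_trial_log <- function(trials, path) {
  cols <- c("participant_id", "trial", "a1", "s2", "transition", "a2",
            "s3", "reward_yen", "rt1_ms", "rt2_ms")
  utils::write.csv(trials[, intersect(cols, names(trials))], path,
                   row.names = FALSE)
}

#' Serialize blockwise fits
#'
#' `fit_to_json()` writes one participant's estimate table to JSON;
#' `fits_to_csv()` binds several fits into the tidy CSV layout
#' `participant, block, model, alpha, eta, beta, w, nll, bic, converged`.
#'
#' @param fits Named list of `rl_fit` objects (names = participant ids).
#' @param path Output CSV path; `NULL` returns the data frame.
#' @return The tidy data frame, invisibly when written.
#' @export
fits_to_csv <- function(fits, path = NULL) {
  out <- do.call(rbind, lapply(names(fits), function(id) {
    e <- fits[[id]]$estimates
    data.frame(participant = id, block = e$block, model = fits[[id]]$model,
               alpha = e$alpha, eta = e$eta, beta = e$beta, w = e$w,
               nll = e$nll, bic = e$bic, converged = e$convergence)
  }))
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' @rdname fits_to_csv
#' @param fit A single `rl_fit`.
#' @export
fit_to_json <- function(fit, path) {
  jsonlite::write_json(
    list(model = fit$model, block_size = fit$block_size,
         carryover = fit$carryover, estimates = fit$estimates),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
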