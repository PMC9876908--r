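#' Payoff menus of the six primary SVO slider items
#'
#' The published slider measure's six primary items, each a menu of nine
#' self/other allocations. Shipped as a plain-text table so alternative
#' menus can be supplied to [svo_angle()].
#'
#' @param path Path to the item table CSV (columns `item`, `option`,
#'   `self`, `other`); defaults to the bundled table.
#' @return Data frame with 54 rows.
#' @export
svo_items <- function(path = system.file("extdata", "svo_items.csv",
                                         package = "twostep")) {
  utils::read.csv(path)
}

#' SVO angle from six primary-item responses
#'
#' The social value orientation angle is the arctangent of the mean
#' other-payoff offset over the mean self-payoff offset, both relative to
#' the 50-point origin:
#' `atan((mean(other) - 50) / (mean(self) - 50))` in degrees. 0 degrees is
#' pure self-interest; larger angles weight the other's payoff more.
#'
#' @param responses Data frame with one row per item: `item_id`,
#'   `self_payoff`, `other_payoff` (exactly the 6 primary items).
#' @param items Item table (see [svo_items()]) used to validate that each
#'   response is one of the item's menu options.
#' @return The angle in degrees; `NA` with a warning if both means sit at
#'   the 50-point origin (undefined direction).
#' @examples
#' items <- svo_items()
#' # perfectly altruistic responses: maximize the other's payoff
#' alt <- do.call(rbind, lapply(split(items, items$item), function(it)
#'   it[which.max(it$other), ]))
#' svo_angle(data.frame(item_id = alt$item, self_payoff = alt$self,
#'                      other_payoff = alt$other))  # 61.39 degrees
#' @export
svo_angle <- function(responses, items = svo_items()) {
  if (nrow(responses) != 6L)
    stop("exactly the 6 primary items are required, got ",
         nrow(responses), " rows")
  for (i in seq_len(6)) {
    it <- items[items$item == responses$item_id[i], ]
    ok <- any(it$self == responses$self_payoff[i] &
                it$other == responses$other_payoff[i])
    if (!ok)
      stop(sprintf("row %d: allocation (%g, %g) is not on item %d's menu",
                   i, responses$self_payoff[i], responses$other_payoff[i],
                   responses$item_id[i]))
  }
  ms <- mean(responses$self_payoff) - 50
  mo <- mean(responses$other_payoff) - 50
  if (ms == 0 && mo == 0) {
    warning("mean allocation sits at the 50-point origin; angle undefined")
    return(NA_real_)
  }
  atan2(mo, ms) * 180 / pi
}

#' Strict SVO group classification
#'
#' Angles at or above the inequity-aversion archetype (37.48 degrees) are
#' prosocial; at or below the complete-individualism archetype
#' (7.82 degrees) proself; anything between is intermediate and excluded
#' from strict group contrasts. Boundary angles are included in the named
#' group since archetypal responders must fall inside it.
#'
#' @param angle Numeric vector of angles in degrees.
#' @return Character vector: `"prosocial"`, `"proself"` or
#'   `"intermediate"`.
#' @export
classify_strict <- function(angle) {
  ifelse(angle >= 37.48, "prosocial",
         ifelse(angle <= 7.82, "proself", "intermediate"))
}

#' Conventional SVO group classification
#'
#' The conventional two-way split at 22.45 degrees: above is prosocial,
#' at or below proself.
#'
#' @param angle Numeric vector of angles in degrees.
#' @return Character vector: `"prosocial"` or `"proself"`.
#' @export
classify_conventional <- function(angle) {
  ifelse(angle > 22.45, "prosocial", "proself")
}

#' Full four-way SVO category
#'
#' Altruist above 57.15 degrees, prosocial in (22.45, 57.15], individualist
#' in (12.04, 22.45], competitor at or below 12.04 degrees.
#'
#' @param angle Numeric vector of angles in degrees.
#' @return Character vector of category labels.
#' @export
classify_full <- function(angle) {
  ifelse(angle > 57.15, "altruist",
         ifelse(angle > 22.45, "prosocial",
                ifelse(angle > 12.04, "individualist", "competitor")))
}

#' Score a cohort's SVO responses
#'
#' @param responses Data frame with columns `participant_id`, `item_id`,
#'   `self_payoff`, `other_payoff` (6 rows per participant).
#' @param items Item table for validation.
#' @return Data frame `participant_id`, `angle_deg`, `group_strict`,
#'   `group_conventional`, `category`.
#' @export
score_svo <- function(responses, items = svo_items()) {
  out <- do.call(rbind, lapply(split(responses, responses$participant_id),
                               function(d) {
    a <- svo_angle(d[order(d$item_id), ], items)
    data.frame(participant_id = d$participant_id[1], angle_deg = a,
               group_strict = classify_strict(a),
               group_conventional = classify_conventional(a),
               category = classify_full(a), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
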