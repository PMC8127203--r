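# Sequential (dynamic) classification: ROC-optimal cutoff, credible-interval
# allocation, and the freeze-once-classified scan across occasions.

#' Allocation configuration
#'
#' @param cutoff probability threshold in (0, 1).
#' @param scheme `"cri"` (default): allocate case only when the whole
#'   credible interval lies strictly above the cutoff, control only when it
#'   lies strictly below, otherwise indeterminate. `"point"`: allocate on
#'   the point estimate (case iff point > cutoff), never indeterminate.
#' @param criLevel credible level the intervals were computed at.
#' @param firstDecisionOccasion first occasion at which allocation is
#'   attempted (default 1, i.e. the second birthday).
#' @return An [AllocationConfig-class].
#' @export
allocationConfig <- function(cutoff = 0.5, scheme = c("cri", "point"),
                             criLevel = 0.99, firstDecisionOccasion = 1L) {
  new("AllocationConfig",
    cutoff = cutoff, scheme = match.arg(scheme), criLevel = criLevel,
    firstDecisionOccasion = as.integer(firstDecisionOccasion)
  )
}

#' ROC-optimal probability cutoff
#'
#' Returns the threshold minimizing the squared distance to the top-left
#' corner of the ROC curve, `d^2 = (1 - Sensitivity)^2 + (1 -
#' Specificity)^2`, over the candidate thresholds (midpoints between
#' adjacent sorted unique probabilities, plus 0 and 1). A probability above
#' the threshold predicts case. Ties in `d^2` are broken toward the
#' threshold nearest 0.5 (then the smaller).
#'
#' @param probabilities numeric vector of case-membership point estimates.
#' @param labels gold-standard labels (`"case"`/`"control"`), both present.
#' @return Numeric scalar cutoff.
#' @export
selectCutoff <- function(probabilities, labels) {
  stopifnot(length(probabilities) == length(labels))
  if (any(!is.finite(probabilities))) stop("probabilities must be finite")
  isCase <- labels == "case"
  if (!any(isCase) || all(isCase)) stop("both labels must be present")
  u <- sort(unique(probabilities))
  cand <- unique(c(0, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, 1))
  d2 <- vapply(cand, function(cc) {
    sens <- mean(probabilities[isCase] > cc)
    spec <- mean(probabilities[!isCase] <= cc)
    (1 - sens)^2 + (1 - spec)^2
  }, numeric(1))
  best <- which(d2 <= min(d2) + 1e-12)
  best <- best[order(abs(cand[best] - 0.5), cand[best])]
  cand[best[1]]
}

#' Allocate one probability entry to a group
#'
#' @param p_lo,p_hi credible-interval bounds.
#' @param p_point point estimate.
#' @param config An [AllocationConfig-class].
#' @return Character vector over `{"case", "control", "indeterminate"}`
#'   (vectorized over entries).
#' @examples
#' cfg <- allocationConfig(cutoff = 0.5)
#' allocateLabel(0.80, 0.95, 0.9, cfg) # case
#' allocateLabel(0.30, 0.70, 0.5, cfg) # indeterminate
#' allocateLabel(0.10, 0.45, 0.3, cfg) # control
#' @export
allocateLabel <- function(p_lo, p_hi, p_point, config) {
  validObject(config)
  if (any(p_lo > p_hi, na.rm = TRUE)) stop("malformed credible interval (lo > hi)")
  c <- config@cutoff
  if (config@scheme == "point") {
    ifelse(p_point > c, "case", "control")
  } else {
    ifelse(p_lo > c, "case", ifelse(p_hi < c, "control", "indeterminate"))
  }
}

#' Sequential classification with frozen decisions
#'
#' Scans each individual's occasions in order from
#' `firstDecisionOccasion`; the first occasion whose allocation is not
#' indeterminate freezes the label (later probabilities are never
#' revisited). The decision age is the upper age bound of the deciding
#' occasion (occasion 1 -> 2 years, occasion 15 -> 16 years). Individuals
#' never allocated remain indeterminate with no decision age.
#'
#' @param series A [ProbabilitySeries-class] (full 15 occasions or a
#'   prefix).
#' @param config An [AllocationConfig-class].
#' @return data.frame with `person_id`, `final_label`, `decision_occasion`,
#'   `decision_age`.
#' @export
classifySequential <- function(series, config) {
  stopifnot(is(series, "ProbabilitySeries"))
  validObject(config)
  e <- series@entries
  e$alloc <- allocateLabel(e$p_lo, e$p_hi, e$p_point, config)
  e$alloc[e$occasion < config@firstDecisionOccasion] <- "indeterminate"
  ageHi <- occasionGrid()$age_hi
  out <- lapply(split(e, e$person_id), function(ei) {
    ei <- ei[order(ei$occasion), ]
    hit <- which(ei$alloc != "indeterminate")
    if (length(hit)) {
      j <- ei$occasion[hit[1]]
      data.frame(
        person_id = ei$person_id[1], final_label = ei$alloc[hit[1]],
        decision_occasion = j, decision_age = ageHi[j]
      )
    } else {
      data.frame(
        person_id = ei$person_id[1], final_label = "indeterminate",
        decision_occasion = NA_integer_, decision_age = NA_real_
      )
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
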