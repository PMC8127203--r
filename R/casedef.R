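# Deterministic ICD-coded case definition and its windowed sensitivity
# analyses.

#' Construct a deterministic case-definition rule
#'
#' The validated claim-level definition: a person is a case if, within the
#' age window, they have one or more non-newborn hospitalizations carrying a
#' relevant diagnosis code (the hospital arm ignores the visit-pair logic),
#' or two or more physician visits with a relevant diagnosis such that some
#' pair of visit days is at least 56 days (eight weeks) and at most 730 days
#' (two years) apart, both bounds inclusive. Relevant codes are the
#' rheumatoid arthritis / ankylosing spondylitis categories (ICD-9-CM 714,
#' 720; ICD-10-CA M05, M06, M08, M45), matched by category prefix.
#'
#' @param window `"full"` (birth to 16th birthday), `"0-2"` or `"14-16"`
#'   (the restricted two-year sensitivity-analysis windows), or a numeric
#'   `c(lo, hi)` day range.
#' @return A [CaseDefinitionRule-class].
#' @examples
#' caseDefinitionRule("full")
#' @export
caseDefinitionRule <- function(window = "full") {
  if (is.character(window)) {
    w <- switch(window,
      "full" = c(0, MAX_FOLLOWUP_DAY),
      "0-2" = c(0, 2 * DAYS_PER_YEAR),
      "14-16" = c(14 * DAYS_PER_YEAR, MAX_FOLLOWUP_DAY),
      stop("unknown window label: ", window)
    )
    lab <- window
  } else {
    w <- as.numeric(window)
    lab <- sprintf("[%g, %g)", w[1], w[2])
  }
  new("CaseDefinitionRule",
    codes9 = .JA_CASEDEF_ICD9, codes10 = .JA_CASEDEF_ICD10,
    minVisits = 2L, minGapDays = 56L, maxGapDays = 730L,
    windowDays = w, label = lab
  )
}

#' The full-window rule plus the two restricted-window rules
#'
#' @return List of three [CaseDefinitionRule-class] objects: full window
#'   (birth to the 16th birthday), ages \[0, 2) and ages \[14, 16) -- the
#'   two-year windows used to mimic settings where administrative data are
#'   only available for short periods.
#' @export
windowedRules <- function() {
  list(
    full = caseDefinitionRule("full"),
    `0-2` = caseDefinitionRule("0-2"),
    `14-16` = caseDefinitionRule("14-16")
  )
}

#' Does a qualifying visit pair exist?
#'
#' True iff some pair of visit days `(d_a, d_b)` satisfies
#' `minGapDays <= d_b - d_a <= maxGapDays`. The pair need not be
#' consecutive visits. Input must be sorted ascending (contract that keeps
#' the scan near-linear).
#'
#' @param visit_days sorted integer vector of days.
#' @param rule A [CaseDefinitionRule-class].
#' @return Logical scalar.
#' @examples
#' r <- caseDefinitionRule()
#' qualifyingPairExists(c(100L, 156L), r) # gap exactly 56
#' qualifyingPairExists(c(100L, 155L), r)
#' @export
qualifyingPairExists <- function(visit_days, rule) {
  if (is.unsorted(visit_days)) stop("visit_days must be sorted ascending")
  n <- length(visit_days)
  if (n < 2L) return(FALSE)
  # for each later visit b, a qualifying earlier visit exists iff some day
  # falls in [d_b - maxGap, d_b - minGap]
  loIdx <- findInterval(visit_days - rule@maxGapDays - 0.5, visit_days) + 1L
  hiIdx <- findInterval(visit_days - rule@minGapDays + 0.5, visit_days)
  any(loIdx <= hiIdx & hiIdx >= 1L)
}

# relevant physician-visit days and coded-hospital indicator for one person
.casedefEvidence <- function(claims, rule) {
  keep <- claims$day >= rule@windowDays[1] & claims$day < rule@windowDays[2]
  claims <- claims[keep, , drop = FALSE]
  if (!nrow(claims)) {
    return(list(visitDays = integer(0), codedHospital = FALSE))
  }
  relevant <- vapply(seq_len(nrow(claims)), function(i) {
    any(.isCaseDefCode(claims$codes[[i]], claims$icd_version[i],
                       rule@codes9, rule@codes10))
  }, logical(1))
  hosp <- claims$record_type == "hospital" & !claims$newborn_flag
  list(
    visitDays = sort(claims$day[relevant & claims$record_type == "physician"]),
    codedHospital = any(relevant & hosp)
  )
}

#' Apply the deterministic case definition to one person's claims
#'
#' @param claims claims data.frame for a single person (empty allowed).
#' @param rule A [CaseDefinitionRule-class] (default: full window).
#' @return `"case"` or `"control"`.
#' @examples
#' classifyDeterministic(data.frame(), caseDefinitionRule())
#' @export
classifyDeterministic <- function(claims, rule = caseDefinitionRule()) {
  if (nrow(claims) == 0L) return("control")
  if (length(unique(claims$person_id)) > 1L) {
    stop("classifyDeterministic expects claims for a single person; see deterministicLabels()")
  }
  ev <- .casedefEvidence(claims, rule)
  if (ev$codedHospital || qualifyingPairExists(ev$visitDays, rule)) "case" else "control"
}

#' Apply the deterministic case definition to a whole claims table
#'
#' @param claims claims data.frame for many persons.
#' @param rule A [CaseDefinitionRule-class].
#' @param person_ids persons to label (defaults to those present in
#'   `claims`; pass the full cohort id vector so claim-free individuals are
#'   labelled `control`).
#' @return data.frame with `person_id` and `det_label`.
#' @export
deterministicLabels <- function(claims, rule = caseDefinitionRule(),
                                person_ids = unique(claims$person_id)) {
  split_idx <- split(seq_len(nrow(claims)), claims$person_id)
  lab <- vapply(person_ids, function(pid) {
    idx <- split_idx[[pid]]
    if (is.null(idx)) return("control")
    classifyDeterministic(claims[idx, , drop = FALSE], rule)
  }, character(1))
  data.frame(person_id = person_ids, det_label = unname(lab))
}
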