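# Measurement-occasion grid shared by every module.
#
# Follow-up runs from birth to the 16th birthday on 15 occasions: the first
# spans ages [0, 2) because disease-specific healthcare use is sparse in the
# first year of life, and occasions 2..15 each span a single year [j, j+1).
# A year of age is 365.25 days, so follow-up covers days [0, 5844).

DAYS_PER_YEAR <- 365.25
N_OCCASIONS <- 15L
MAX_FOLLOWUP_DAY <- 5844L # 16 * 365.25

MARKERS <- c("ja_contact", "gp_visits", "specialist_visits", "hospitalization")
MARKER_FAMILIES <- c(
  ja_contact = "bernoulli_logit",
  gp_visits = "poisson_log",
  specialist_visits = "poisson_log",
  hospitalization = "bernoulli_logit"
)

#' Measurement-occasion grid
#'
#' The 15 measurement occasions spanning birth to the 16th birthday. The
#' first occasion covers ages \[0, 2) (two years, merged because
#' disease-related utilization is sparse in infancy); occasions 2 to 15 each
#' cover a single year of age \[j, j+1).
#'
#' @return A `data.frame` with columns `occasion` (1..15), `age_lo`
#'   (inclusive lower age bound, years), `age_hi` (exclusive upper bound),
#'   and `age` (the representative age used as the model covariate: 1 for
#'   the merged first occasion, otherwise the year itself).
#' @examples
#' occasionGrid()
#' @export
occasionGrid <- function() {
  data.frame(
    occasion = seq_len(N_OCCASIONS),
    age_lo = c(0L, 2:15),
    age_hi = c(2L, 3:16),
    age = c(1L, 2:15)
  )
}

#' Map days since birth to measurement occasions
#'
#' Days are mapped through `floor(day / 365.25)`: years 0 and 1 belong to
#' the merged first occasion, year j (2..15) to occasion j.
#'
#' @param day Integer vector of days since birth; must lie in \[0, 5844).
#' @return Integer vector of occasion indices in 1..15.
#' @examples
#' dayToOccasion(c(0, 730, 731, 5843))
#' @export
dayToOccasion <- function(day) {
  if (any(!is.finite(day)) || any(day < 0) || any(day >= MAX_FOLLOWUP_DAY)) {
    stop("claim days must lie in [0, ", MAX_FOLLOWUP_DAY, ")")
  }
  yr <- floor(day / DAYS_PER_YEAR)
  as.integer(ifelse(yr <= 1, 1L, yr))
}

# integer day range [lo, hi] covered by one occasion
.occasionDayRange <- function(occasion) {
  grid <- occasionGrid()
  lo <- ceiling(grid$age_lo[occasion] * DAYS_PER_YEAR)
  hi <- ceiling(grid$age_hi[occasion] * DAYS_PER_YEAR) - 1
  cbind(lo = as.integer(lo), hi = as.integer(hi))
}
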