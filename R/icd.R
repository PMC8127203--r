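# ICD diagnosis code sets.
#
# Two distinct sets are in play and must not be conflated:
#  * the broad "JA-related contact" set that defines the annual binary
#    utilization marker (ICD-9-CM categories 696, 713, 714, 716, 720;
#    ICD-10-CA categories M05-M09 and M45), and
#  * the narrower set used by the validated deterministic case definition
#    (rheumatoid arthritis and ankylosing spondylitis: ICD-9-CM 714, 720;
#    ICD-10-CA M05, M06, M08, M45).
#
# Administrative data record codes at four or more characters, so matching
# is prefix-based on the three-character category root.

.JA_CONTACT_ICD9 <- c("696", "713", "714", "716", "720")
.JA_CONTACT_ICD10 <- c("M05", "M06", "M07", "M08", "M09", "M45") # M05-M09 inclusive + M45
.JA_CASEDEF_ICD9 <- c("714", "720")
.JA_CASEDEF_ICD10 <- c("M05", "M06", "M08", "M45")

.icdRoot <- function(code) toupper(substr(trimws(code), 1L, 3L))

.matchesCodeSet <- function(code, icd_version, set9, set10) {
  if (length(icd_version) == 1L) icd_version <- rep(icd_version, length(code))
  stopifnot(length(code) == length(icd_version))
  if (!all(icd_version %in% c(9L, 10L))) {
    stop("icd_version must be 9 or 10")
  }
  if (any(!nzchar(trimws(code)))) stop("diagnosis codes must be non-empty")
  root <- .icdRoot(code)
  ifelse(icd_version == 9L, root %in% set9, root %in% set10)
}

#' Is a diagnosis code JA-related?
#'
#' Tests whether an ICD code belongs to the juvenile-arthritis-related
#' contact set used for the annual `ja_contact` utilization marker:
#' ICD-9-CM categories 696, 713, 714, 716, 720; ICD-10-CA categories
#' M05 through M09 (inclusive range) and M45. Matching is by the
#' three-character category prefix, so e.g. `"7140"` and `"M081"` match.
#'
#' @param code Character vector of diagnosis codes (non-empty).
#' @param icd_version 9 or 10 (scalar or vector parallel to `code`).
#' @return Logical vector.
#' @examples
#' isJaRelated(c("7140", "715"), 9)
#' isJaRelated("M081", 10)
#' @export
isJaRelated <- function(code, icd_version) {
  .matchesCodeSet(code, as.integer(icd_version), .JA_CONTACT_ICD9, .JA_CONTACT_ICD10)
}

# narrow deterministic-definition set (rule supplies its own code vectors)
.isCaseDefCode <- function(code, icd_version, set9, set10) {
  .matchesCodeSet(code, as.integer(icd_version), set9, set10)
}
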