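# Plain-text interchange formats: claim-level and cohort-level CSV.

#' Write / read claim-level CSV
#'
#' The claim table is flattened to one row per record with diagnosis codes
#' spread over `code_1` .. `code_25` (empty trailing columns allowed), the
#' layout administrative extracts use.
#'
#' @param claims claims data.frame (as from [generateClaims()]).
#' @param path file path.
#' @return `writeClaimsCsv()` returns `path` invisibly; `readClaimsCsv()`
#'   returns a claims data.frame with the list-column `codes` rebuilt.
#' @export
writeClaimsCsv <- function(claims, path) {
  maxCodes <- max(1L, if (nrow(claims)) max(lengths(claims$codes)) else 1L)
  codeMat <- t(vapply(claims$codes, function(cc) {
    c(cc, rep("", maxCodes - length(cc)))
  }, character(maxCodes)))
  flat <- cbind(
    claims[, c("person_id", "day", "record_type", "provider_class",
               "setting", "icd_version")],
    as.data.frame(codeMat, optional = TRUE) |>
      stats::setNames(paste0("code_", seq_len(maxCodes))),
    newborn_flag = claims$newborn_flag
  )
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeClaimsCsv
#' @export
readClaimsCsv <- function(path) {
  flat <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(person_id = "character"))
  codeCols <- grep("^code_", colnames(flat), value = TRUE)
  codes <- lapply(seq_len(nrow(flat)), function(i) {
    cc <- as.character(unlist(flat[i, codeCols], use.names = FALSE))
    cc[!is.na(cc) & nzchar(cc)]
  })
  out <- flat[, c("person_id", "day", "record_type", "provider_class",
                  "setting", "icd_version")]
  out$codes <- I(codes)
  out$newborn_flag <- as.logical(flat$newborn_flag)
  out
}

#' Write / read cohort-level CSV
#'
#' One row per individual: `person_id`, `sex`, `region`, `income_quintile`,
#' `group`, then the 60 measure columns named `<marker>_occ<j>`.
#'
#' @param cohort A [UtilizationCohort-class].
#' @param path file path.
#' @return `writeCohortCsv()` returns `path` invisibly; `readCohortCsv()`
#'   returns a [UtilizationCohort-class] (without latent generator truth).
#' @export
writeCohortCsv <- function(cohort, path) {
  stopifnot(is(cohort, "UtilizationCohort"))
  meas <- do.call(cbind, lapply(MARKERS, function(m) {
    x <- t(measureMatrix(cohort, m))
    colnames(x) <- paste0(m, "_occ", seq_len(N_OCCASIONS))
    x
  }))
  flat <- cbind(
    data.frame(person_id = cohort$person_id, sex = cohort$sex,
               region = cohort$region,
               income_quintile = cohort$income_quintile,
               group = cohort$group),
    meas
  )
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortCsv
#' @export
readCohortCsv <- function(path) {
  flat <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(person_id = "character"))
  measures <- setNames(lapply(MARKERS, function(m) {
    cols <- paste0(m, "_occ", seq_len(N_OCCASIONS))
    t(as.matrix(flat[, cols]))
  }), MARKERS)
  utilizationCohort(
    measures = measures,
    colData = flat[, c("person_id", "sex", "region", "income_quintile", "group")]
  )
}
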