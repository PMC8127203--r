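# UtilizationCohort construction and accessors.

#' Construct a UtilizationCohort
#'
#' @param measures named list of the four marker matrices, each 15 occasions
#'   x n individuals (`ja_contact`, `gp_visits`, `specialist_visits`,
#'   `hospitalization`).
#' @param colData data.frame (or DataFrame) with one row per individual and
#'   columns `person_id`, `sex`, `region`, `income_quintile`, `group`.
#' @param latentIntercepts optional 4 x n matrix of generator-truth random
#'   intercepts (rows = markers), stored in `metadata()`.
#' @return A [UtilizationCohort-class].
#' @export
utilizationCohort <- function(measures, colData, latentIntercepts = NULL) {
  measures <- measures[MARKERS]
  cd <- DataFrame(colData)
  rownames(cd) <- cd$person_id
  measures <- lapply(measures, function(m) {
    m <- as.matrix(m)
    dimnames(m) <- list(NULL, cd$person_id)
    m
  })
  se <- SummarizedExperiment(
    assays = measures,
    rowData = DataFrame(occasionGrid()),
    colData = cd
  )
  obj <- methods::as(se, "UtilizationCohort")
  if (!is.null(latentIntercepts)) {
    metadata(obj)$latent_intercepts <- latentIntercepts
  }
  validObject(obj)
  obj
}

#' Extract one marker's occasion-by-individual matrix
#'
#' @param x A [UtilizationCohort-class].
#' @param marker One of `"ja_contact"`, `"gp_visits"`, `"specialist_visits"`,
#'   `"hospitalization"`.
#' @return 15 x n numeric matrix.
#' @export
measureMatrix <- function(x, marker) {
  stopifnot(is(x, "UtilizationCohort"), marker %in% MARKERS)
  assay(x, marker)
}

#' Gold-standard group labels
#'
#' @param x A [UtilizationCohort-class].
#' @return Character vector (`"case"`/`"control"`) named by person id.
#' @export
goldLabels <- function(x) {
  stopifnot(is(x, "UtilizationCohort"))
  setNames(as.character(x$group), x$person_id)
}

#' Model covariates of a cohort
#'
#' @param x A [UtilizationCohort-class].
#' @return data.frame with `person_id`, and 0/1 `male` and `urban` indicators.
#' @export
covariateTable <- function(x) {
  stopifnot(is(x, "UtilizationCohort"))
  data.frame(
    person_id = x$person_id,
    male = as.numeric(x$sex == "male"),
    urban = as.numeric(x$region == "urban")
  )
}

#' Generator-truth latent random intercepts (synthetic cohorts only)
#'
#' @param x A [UtilizationCohort-class].
#' @return 4 x n matrix, or NULL for observed cohorts.
#' @export
latentIntercepts <- function(x) {
  stopifnot(is(x, "UtilizationCohort"))
  metadata(x)$latent_intercepts
}

setMethod("show", "UtilizationCohort", function(object) {
  g <- table(factor(object$group, levels = c("case", "control")))
  cat(sprintf(
    "UtilizationCohort: %d individuals x %d occasions (%d cases, %d controls)\n",
    ncol(object), nrow(object), g[["case"]], g[["control"]]
  ))
  cat("  markers:", paste(assayNames(object), collapse = ", "), "\n")
  if (!is.null(latentIntercepts(object))) {
    cat("  synthetic cohort (latent generator intercepts attached)\n")
  }
  invisible(NULL)
})

setMethod("show", "PosteriorDraws", function(object) {
  cat(sprintf(
    "PosteriorDraws (%s group): %d draws x %d parameters, %d chain(s)\n",
    object@group, nrow(object@draws), ncol(object@draws),
    length(unique(object@chain))
  ))
  cat("  markers:", paste(object@spec@markers, collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "ProbabilitySeries", function(object) {
  cat(sprintf(
    "ProbabilitySeries (%s approach): %d individuals x %d occasions, %d%% CrI\n",
    object@approach, length(unique(object@entries$person_id)),
    max(object@entries$occasion), round(object@criLevel * 100)
  ))
  invisible(NULL)
})

setMethod("show", "CaseDefinitionRule", function(object) {
  cat(sprintf(
    "CaseDefinitionRule '%s': window days [%d, %d), >=1 coded hospitalization or >=%d visits %d-%d days apart\n",
    object@label, object@windowDays[1], object@windowDays[2],
    object@minVisits, object@minGapDays, object@maxGapDays
  ))
  invisible(NULL)
})

#' Posterior draws matrix
#'
#' @param x A [PosteriorDraws-class].
#' @return Numeric matrix, kept draws x parameters (columns
#'   `<marker>.<coef>`).
#' @export
drawsMatrix <- function(x) {
  stopifnot(is(x, "PosteriorDraws"))
  x@draws
}

#' Posterior-probability entries table
#'
#' @param x A [ProbabilitySeries-class].
#' @return data.frame with one row per individual x occasion.
#' @export
probabilityEntries <- function(x) {
  stopifnot(is(x, "ProbabilitySeries"))
  x@entries
}
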