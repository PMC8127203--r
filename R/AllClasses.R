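# S4 class definitions for the whole package.

## ---------------------------------------------------------------------------
## UtilizationCohort: the central data container
## ---------------------------------------------------------------------------

#' UtilizationCohort: annual healthcare-utilization measures for a cohort
#'
#' An S4 container extending [SummarizedExperiment::SummarizedExperiment].
#' Rows are the 15 measurement occasions (birth to the 16th birthday, first
#' occasion spanning ages 0-1), columns are individuals. Assays hold the four
#' utilization markers: `ja_contact` (binary: any JA-related diagnosis code
#' that occasion), `gp_visits` (count of ambulatory general-practitioner
#' visits), `specialist_visits` (count of ambulatory specialist visits) and
#' `hospitalization` (binary: any non-newborn hospitalization). `colData`
#' carries `person_id`, `sex`, `region`, `income_quintile` and the
#' gold-standard `group` label (`case` / `control`). For synthetic cohorts the
#' generator's latent per-marker random intercepts are stored in
#' `metadata(x)$latent_intercepts` (generator truth, not visible to fitting).
#'
#' @seealso [utilizationCohort()], [generateCohort()]
#' @export
setClass("UtilizationCohort", contains = "SummarizedExperiment")

setValidity("UtilizationCohort", function(object) {
  msg <- character()
  if (!all(MARKERS %in% assayNames(object))) {
    msg <- c(msg, paste("assays must include:", paste(MARKERS, collapse = ", ")))
  }
  if (nrow(object) != N_OCCASIONS) {
    msg <- c(msg, sprintf("must have exactly %d rows (occasions)", N_OCCASIONS))
  }
  need <- c("person_id", "sex", "region", "income_quintile", "group")
  if (!all(need %in% colnames(colData(object)))) {
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  } else {
    if (!all(object$group %in% c("case", "control"))) {
      msg <- c(msg, "group labels must be 'case' or 'control'")
    }
    if (!all(object$sex %in% c("male", "female"))) {
      msg <- c(msg, "sex must be 'male' or 'female'")
    }
    if (!all(object$region %in% c("urban", "rural"))) {
      msg <- c(msg, "region must be 'urban' or 'rural'")
    }
  }
  if (ncol(object) > 0L) {
    for (m in intersect(MARKERS, assayNames(object))) {
      a <- assay(object, m)
      if (any(!is.finite(a)) || any(a < 0) || any(a != round(a))) {
        msg <- c(msg, sprintf("assay '%s' must be non-negative integers", m))
      } else if (MARKER_FAMILIES[[m]] == "bernoulli_logit" && any(a > 1)) {
        msg <- c(msg, sprintf("binary marker '%s' must be 0/1", m))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## GeneratorConfig
## ---------------------------------------------------------------------------

#' GeneratorConfig: parameters of the synthetic-cohort generator
#'
#' Holds everything [generateCohort()] and [generateClaims()] need: cohort
#' size and composition, covariate prevalences, per-group per-marker
#' generating parameters (fixed effects for male/urban/age plus the mean and
#' SD of the per-marker random intercept), and the claim-placement parameters
#' that map annual measures back to dated, ICD-coded claim records. Defaults
#' are documented at [generatorConfig()].
#'
#' @slot nIndividuals cohort size
#' @slot caseFraction probability an individual is a (gold-standard) case
#' @slot pFemale,pUrban covariate prevalences
#' @slot effects list with elements `case` and `control`, each a 4 x 5 matrix
#'   (rows = markers, columns `male`, `urban`, `age`, `mu_b`, `sd_b`)
#' @slot pJaSpecialist probability a JA-coded ambulatory claim is placed on a
#'   specialist visit rather than a GP visit
#' @slot pJaSecondary probability each further ambulatory claim in a
#'   JA-contact occasion also carries a JA code (active disease years show
#'   repeated coded visits)
#' @slot pHospitalJa probability the JA-related code is carried on a hospital
#'   record when one exists in the occasion
#' @slot pNewborn probability of a newborn (birth) hospital record
#' @slot jaCodeWeights9,jaCodeWeights10 sampling weights over the JA-related
#'   ICD category roots used when a JA code is emitted
#' @slot seed RNG seed
#' @export
setClass("GeneratorConfig", representation(
  nIndividuals = "integer",
  caseFraction = "numeric",
  pFemale = "numeric",
  pUrban = "numeric",
  effects = "list",
  pJaSpecialist = "numeric",
  pJaSecondary = "numeric",
  pHospitalJa = "numeric",
  pNewborn = "numeric",
  jaCodeWeights9 = "numeric",
  jaCodeWeights10 = "numeric",
  seed = "integer"
))

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  probs <- c(
    object@caseFraction, object@pFemale, object@pUrban,
    object@pJaSpecialist, object@pJaSecondary, object@pHospitalJa,
    object@pNewborn
  )
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    msg <- c(msg, "all probability parameters must lie in [0, 1]")
  }
  if (object@nIndividuals < 0L) msg <- c(msg, "nIndividuals must be >= 0")
  for (g in c("case", "control")) {
    eff <- object@effects[[g]]
    if (is.null(eff) || !is.matrix(eff) ||
        !identical(rownames(eff), MARKERS) ||
        !identical(colnames(eff), c("male", "urban", "age", "mu_b", "sd_b"))) {
      msg <- c(msg, sprintf("effects$%s must be a 4 x 5 marker-by-parameter matrix", g))
    } else if (any(!is.finite(eff))) {
      msg <- c(msg, sprintf("effects$%s contains non-finite parameters", g))
    } else if (any(eff[, "sd_b"] < 0)) {
      msg <- c(msg, sprintf("effects$%s random-intercept SDs must be >= 0", g))
    }
  }
  if (any(object@jaCodeWeights9 < 0) || any(object@jaCodeWeights10 < 0)) {
    msg <- c(msg, "code weights must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## MGLMMSpec and McmcConfig
## ---------------------------------------------------------------------------

#' MGLMMSpec: model specification for the group-specific MGLMM
#'
#' Describes which utilization markers enter the multivariate generalized
#' linear mixed model, each marker's exponential family / link (Bernoulli
#' with logit link for the binary markers, Poisson with log link for the
#' counts), and which fixed covariates are included. Every marker carries an
#' individual-level random intercept; the random-effects distribution is a
#' single normal component (the mixture interface is reserved, and
#' `nMixtureComponents` must currently equal 1). Dispersion is fixed at 1
#' for both families.
#'
#' @slot markers character vector of marker names
#' @slot families named character vector, `"bernoulli_logit"` or `"poisson_log"`
#' @slot covariates subset of `c("male", "urban", "age")`
#' @slot nMixtureComponents integer, must be 1
#' @export
setClass("MGLMMSpec", representation(
  markers = "character",
  families = "character",
  covariates = "character",
  nMixtureComponents = "integer"
))

setValidity("MGLMMSpec", function(object) {
  msg <- character()
  if (length(object@markers) < 1L) msg <- c(msg, "at least one marker required")
  if (!all(object@markers %in% MARKERS)) {
    msg <- c(msg, paste("unknown markers; available:", paste(MARKERS, collapse = ", ")))
  }
  if (!identical(sort(names(object@families)), sort(object@markers)) ||
      !all(object@families %in% c("bernoulli_logit", "poisson_log"))) {
    msg <- c(msg, "families must be named by marker and be bernoulli_logit/poisson_log")
  }
  if (!all(object@covariates %in% c("male", "urban", "age"))) {
    msg <- c(msg, "covariates must be a subset of male, urban, age")
  }
  if (object@nMixtureComponents != 1L) {
    msg <- c(msg, "only one mixture component is supported (interface reserved)")
  }
  if (length(msg)) msg else TRUE
})

#' McmcConfig: sampler settings
#'
#' @slot nIterations total iterations per chain (default 10000)
#' @slot burnIn iterations discarded as burn-in (default 1000)
#' @slot thin thinning interval applied after burn-in (default 100)
#' @slot nChains number of chains (default 2, so the potential scale
#'   reduction factor is computable)
#' @slot seed RNG seed
#' @slot ghNodes Gauss-Hermite nodes used to integrate the random intercept
#'   out of the per-individual likelihood during fitting
#' @export
setClass("McmcConfig", representation(
  nIterations = "integer",
  burnIn = "integer",
  thin = "integer",
  nChains = "integer",
  seed = "integer",
  ghNodes = "integer"
))

setValidity("McmcConfig", function(object) {
  msg <- character()
  if (object@burnIn >= object@nIterations) msg <- c(msg, "burnIn must be < nIterations")
  if (object@thin < 1L) msg <- c(msg, "thin must be >= 1")
  if (object@nChains < 1L) msg <- c(msg, "nChains must be >= 1")
  if (object@ghNodes < 3L) msg <- c(msg, "ghNodes must be >= 3")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## PosteriorDraws
## ---------------------------------------------------------------------------

#' PosteriorDraws: MCMC draws of one group's MGLMM parameters
#'
#' Kept (post burn-in, thinned) posterior draws for every parameter of one
#' group's model. Parameters are named `<marker>.<coef>` with coefficients
#' `male`, `urban`, `age`, `mu_b` (random-intercept mean, the `E(Intercept)`
#' of the model summaries) and `sd_b` (random-intercept SD).
#'
#' @slot group `"case"` or `"control"`
#' @slot draws numeric matrix, kept draws x parameters
#' @slot chain integer chain id per draw
#' @slot iteration iteration index (within chain, post burn-in) per draw
#' @slot spec the [MGLMMSpec-class] that was fitted
#' @slot mcmc the [McmcConfig-class] used
#' @slot acceptance named numeric vector of per-marker acceptance rates
#' @export
setClass("PosteriorDraws", representation(
  group = "character",
  draws = "matrix",
  chain = "integer",
  iteration = "integer",
  spec = "MGLMMSpec",
  mcmc = "McmcConfig",
  acceptance = "numeric"
))

setValidity("PosteriorDraws", function(object) {
  msg <- character()
  if (!object@group %in% c("case", "control")) msg <- c(msg, "group must be case/control")
  if (nrow(object@draws) != length(object@chain) ||
      nrow(object@draws) != length(object@iteration)) {
    msg <- c(msg, "chain/iteration length must match draw count")
  }
  sdCols <- grep("\\.sd_b$", colnames(object@draws))
  if (length(sdCols) && any(object@draws[, sdCols] <= 0)) {
    msg <- c(msg, "random-intercept SD draws must be > 0")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## ProbabilitySeries
## ---------------------------------------------------------------------------

#' ProbabilitySeries: per-occasion case-membership probabilities
#'
#' For each individual and occasion j, the probability of belonging to the
#' case group given the marker history accrued through occasion j, computed
#' per posterior draw and summarized by the mean (point estimate) and an
#' equal-tailed credible interval.
#'
#' @slot entries data.frame with columns `person_id`, `occasion`, `p_point`,
#'   `p_lo`, `p_hi`, `n_draws`
#' @slot perDraw numeric array individuals x occasions x draws of per-draw
#'   case probabilities
#' @slot approach `"marginal"`, `"conditional"` or `"random_effects"`
#' @slot priors prior group probabilities `c(case=, control=)`
#' @slot criLevel credible level of `p_lo`/`p_hi`
#' @export
setClass("ProbabilitySeries", representation(
  entries = "data.frame",
  perDraw = "array",
  approach = "character",
  priors = "numeric",
  criLevel = "numeric"
))

setValidity("ProbabilitySeries", function(object) {
  msg <- character()
  e <- object@entries
  need <- c("person_id", "occasion", "p_point", "p_lo", "p_hi", "n_draws")
  if (!all(need %in% colnames(e))) msg <- c(msg, "entries missing required columns")
  ok <- stats::complete.cases(e[, c("p_point", "p_lo", "p_hi")])
  if (any(e$p_lo[ok] > e$p_point[ok] + 1e-12) || any(e$p_point[ok] > e$p_hi[ok] + 1e-12)) {
    msg <- c(msg, "must have p_lo <= p_point <= p_hi")
  }
  if (!object@approach %in% c("marginal", "conditional", "random_effects")) {
    msg <- c(msg, "unknown prediction approach")
  }
  if (abs(sum(object@priors) - 1) > 1e-8 || any(object@priors < 0)) {
    msg <- c(msg, "priors must be non-negative and sum to 1")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## AllocationConfig and CaseDefinitionRule
## ---------------------------------------------------------------------------

#' AllocationConfig: dynamic-classification settings
#'
#' @slot cutoff probability threshold in (0, 1)
#' @slot scheme `"cri"` (allocate only when the whole credible interval lies
#'   on one side of the cutoff) or `"point"` (allocate on the point estimate,
#'   never indeterminate)
#' @slot criLevel credible level the intervals were computed at
#' @slot firstDecisionOccasion first occasion at which allocation is attempted
#' @export
setClass("AllocationConfig", representation(
  cutoff = "numeric",
  scheme = "character",
  criLevel = "numeric",
  firstDecisionOccasion = "integer"
))

setValidity("AllocationConfig", function(object) {
  msg <- character()
  if (object@cutoff <= 0 || object@cutoff >= 1) msg <- c(msg, "cutoff must be in (0, 1)")
  if (!object@scheme %in% c("cri", "point")) msg <- c(msg, "scheme must be cri/point")
  if (object@firstDecisionOccasion < 1L || object@firstDecisionOccasion > N_OCCASIONS) {
    msg <- c(msg, "firstDecisionOccasion out of range")
  }
  if (length(msg)) msg else TRUE
})

#' CaseDefinitionRule: the deterministic ICD case definition
#'
#' An individual is a case if, within the rule's age window, they have one or
#' more non-newborn hospitalizations carrying a relevant diagnosis code, or
#' two or more physician visits with a relevant diagnosis at least eight
#' weeks (56 days) apart but no more than two years (730 days) apart.
#' Relevant codes are rheumatoid arthritis / ankylosing spondylitis:
#' ICD-9-CM 714, 720; ICD-10-CA M05, M06, M08, M45 (category-prefix match).
#'
#' @slot codes9,codes10 relevant ICD category roots
#' @slot minVisits minimum qualifying physician visits (2)
#' @slot minGapDays,maxGapDays inclusive bounds on the gap between some pair
#'   of qualifying visits
#' @slot windowDays `c(lo, hi)` age window in days, claims with
#'   `lo <= day < hi` are considered
#' @slot label human-readable window label
#' @export
setClass("CaseDefinitionRule", representation(
  codes9 = "character",
  codes10 = "character",
  minVisits = "integer",
  minGapDays = "integer",
  maxGapDays = "integer",
  windowDays = "numeric",
  label = "character"
))

setValidity("CaseDefinitionRule", function(object) {
  msg <- character()
  if (object@minGapDays > object@maxGapDays) msg <- c(msg, "minGapDays must be <= maxGapDays")
  w <- object@windowDays
  if (length(w) != 2L || w[1] < 0 || w[2] > MAX_FOLLOWUP_DAY || w[1] >= w[2]) {
    msg <- c(msg, sprintf("window must satisfy 0 <= lo < hi <= %d", MAX_FOLLOWUP_DAY))
  }
  if (length(msg)) msg else TRUE
})
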