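# Synthetic cohort and claims generator.
#
# The generator emulates the structure of a linked clinical-registry /
# administrative-claims cohort for juvenile arthritis: a two-group cohort
# (~48% gold-standard cases), four annual utilization markers on the 15
# occasions of occasionGrid(), Bernoulli-logit / Poisson-log outcomes with
# per-marker normal random intercepts, and dated ICD-coded claim records
# that are exactly consistent with the annual measures (so the deterministic
# claim-level case definition can be exercised on the same synthetic world).

.defaultEffects <- function() {
  # generating parameters per group: fixed effects (male, urban, age),
  # random-intercept mean mu_b and SD sd_b, per marker
  case <- rbind(
    ja_contact        = c(-0.59, -0.24,  0.21, -1.77, 1.60),
    gp_visits         = c( 0.03, -0.50, -0.11,  1.62, 0.94),
    specialist_visits = c(-0.19,  0.55, -0.04,  1.26, 0.80),
    hospitalization   = c( 0.24, -0.57, -0.11, -1.46, 0.87)
  )
  control <- rbind(
    ja_contact        = c(-0.07, -0.53,  0.17, -4.74, 1.03),
    gp_visits         = c(-0.02, -0.46, -0.10,  1.45, 1.00),
    specialist_visits = c(-0.13,  0.63, -0.03,  0.91, 0.92),
    hospitalization   = c( 0.02, -0.58, -0.04, -1.47, 0.84)
  )
  colnames(case) <- colnames(control) <- c("male", "urban", "age", "mu_b", "sd_b")
  list(case = case, control = control)
}

# non-JA filler diagnosis categories (none prefix-matches either JA set)
.NONJA_ICD9 <- c("250", "382", "465", "486", "715", "780", "845")
.NONJA_ICD10 <- c("A09", "J06", "K21", "R10", "S93")

#' Configure the synthetic-cohort generator
#'
#' Default generating parameters reflect a pediatric rheumatology cohort in
#' a universal-coverage claims system: cases are 48.4% of the cohort, about
#' 65% of children are female and 57% urban, JA-related contact probability
#' rises with age among cases (and stays rare among controls, whose
#' random-intercept mean is far lower), while GP-visit, specialist-visit and
#' hospitalization intensities decline with age from their infancy peak.
#'
#' @param nIndividuals cohort size (default 797).
#' @param caseFraction probability of the gold-standard case label (0.484).
#' @param pFemale,pUrban covariate prevalences (0.65, 0.572).
#' @param effects list with 4 x 5 matrices `case` and `control` (rows =
#'   markers; columns `male`, `urban`, `age`, `mu_b`, `sd_b`); defaults
#'   above.
#' @param pJaSpecialist probability a JA-coded ambulatory claim is placed on
#'   a specialist rather than a GP visit (0.8; rheumatology contacts are
#'   specialist contacts).
#' @param pJaSecondary probability each further ambulatory claim in a
#'   JA-contact occasion also carries a JA code (0.5; active disease years
#'   produce repeated coded visits, which is what the deterministic
#'   definition's visit-pair arm relies on).
#' @param pHospitalJa probability the JA code rides on a hospital record
#'   when one exists in the occasion (0.2).
#' @param pNewborn probability of a newborn (birth) hospital record in the
#'   first occasion (0.9).
#' @param jaCodeWeights9,jaCodeWeights10 named weights over JA-related ICD
#'   category roots used when emitting a JA code; defaults put most mass on
#'   the juvenile/rheumatoid arthritis categories (714 / M08), so most--but
#'   not all--JA-coded contacts also satisfy the narrower deterministic
#'   definition's code set.
#' @param seed RNG seed.
#' @return A [GeneratorConfig-class].
#' @export
generatorConfig <- function(nIndividuals = 797L,
                            caseFraction = 0.484,
                            pFemale = 0.65,
                            pUrban = 0.572,
                            effects = .defaultEffects(),
                            pJaSpecialist = 0.8,
                            pJaSecondary = 0.5,
                            pHospitalJa = 0.2,
                            pNewborn = 0.9,
                            jaCodeWeights9 = c("714" = 0.50, "720" = 0.10, "716" = 0.20,
                                               "713" = 0.05, "696" = 0.15),
                            jaCodeWeights10 = c("M08" = 0.50, "M09" = 0.20, "M45" = 0.10,
                                                "M05" = 0.05, "M06" = 0.05, "M07" = 0.10),
                            seed = 1L) {
  new("GeneratorConfig",
    nIndividuals = as.integer(nIndividuals),
    caseFraction = caseFraction,
    pFemale = pFemale,
    pUrban = pUrban,
    effects = effects,
    pJaSpecialist = pJaSpecialist,
    pJaSecondary = pJaSecondary,
    pHospitalJa = pHospitalJa,
    pNewborn = pNewborn,
    jaCodeWeights9 = jaCodeWeights9,
    jaCodeWeights10 = jaCodeWeights10,
    seed = as.integer(seed)
  )
}

#' Generate a synthetic cohort of annual utilization measures
#'
#' Draws group labels, covariates and per-marker latent random intercepts,
#' then draws each marker value at each occasion from its Bernoulli-logit or
#' Poisson-log model with linear predictor
#' `male*a_male + urban*a_urban + age_j*a_age + b_i`, where `b_i ~ N(mu_b,
#' sd_b^2)` for the individual's group. The age covariate is the occasion's
#' representative year (1 for the merged first occasion, else the year
#' itself).
#'
#' @param config A [GeneratorConfig-class].
#' @return A [UtilizationCohort-class] with the generator-truth latent
#'   intercepts attached in `metadata()`.
#' @export
generateCohort <- function(config) {
  validObject(config)
  set.seed(config@seed)
  n <- config@nIndividuals
  ids <- sprintf("P%05d", seq_len(n))
  grp <- ifelse(runif(n) < config@caseFraction, "case", "control")
  sex <- ifelse(runif(n) < config@pFemale, "female", "male")
  region <- ifelse(runif(n) < config@pUrban, "urban", "rural")
  quintile <- if (n) sample(1:5, n, replace = TRUE) else integer(0)
  male <- as.numeric(sex == "male")
  urban <- as.numeric(region == "urban")
  age <- occasionGrid()$age

  b <- matrix(NA_real_, nrow = length(MARKERS), ncol = n,
              dimnames = list(MARKERS, ids))
  measures <- lapply(MARKERS, function(m) {
    matrix(0, nrow = N_OCCASIONS, ncol = n)
  })
  names(measures) <- MARKERS

  for (g in c("case", "control")) {
    idx <- which(grp == g)
    if (!length(idx)) next
    eff <- config@effects[[g]]
    for (m in MARKERS) {
      e <- eff[m, ]
      bi <- rnorm(length(idx), e[["mu_b"]], e[["sd_b"]])
      b[m, idx] <- bi
      # eta: occasions x individuals in this group
      eta <- outer(age * e[["age"]], rep(1, length(idx))) +
        rep(male[idx] * e[["male"]] + urban[idx] * e[["urban"]] + bi,
            each = N_OCCASIONS)
      if (MARKER_FAMILIES[[m]] == "bernoulli_logit") {
        measures[[m]][, idx] <- rbinom(length(eta), 1L, plogis(eta))
      } else {
        measures[[m]][, idx] <- rpois(length(eta), exp(pmin(eta, 12)))
      }
    }
  }

  utilizationCohort(
    measures = measures,
    colData = data.frame(
      person_id = ids, sex = sex, region = region,
      income_quintile = quintile, group = grp
    ),
    latentIntercepts = b
  )
}

.sampleCode <- function(roots, weights = NULL) {
  root <- if (is.null(weights)) {
    roots[sample.int(length(roots), 1L)]
  } else {
    sample(names(weights), 1L, prob = weights)
  }
  paste0(root, sample(0:9, 1L))
}

.claimRow <- function(person_id, day, record_type, provider_class, setting,
                      icd_version, codes, newborn_flag = FALSE) {
  data.frame(
    person_id = person_id, day = as.integer(day), record_type = record_type,
    provider_class = provider_class, setting = setting,
    icd_version = as.integer(icd_version),
    codes = I(list(codes)), newborn_flag = newborn_flag,
    stringsAsFactors = FALSE
  )
}

# claims for one individual (internal; generateClaims vectorizes over a cohort)
.claimsForIndividual <- function(person_id, measures, config) {
  if (any(measures < 0)) stop("measure matrix has negative counts")
  spans <- .occasionDayRange(seq_len(N_OCCASIONS))
  rows <- list()
  nr <- 0L
  add <- function(row) {
    nr <<- nr + 1L
    rows[[nr]] <<- row
  }

  # newborn (birth) hospital record: never counts toward the hospitalization
  # measure; its codes are always non-JA so it cannot create a JA contact
  if (runif(1) < config@pNewborn) {
    v <- sample(c(9L, 10L), 1L)
    pool <- if (v == 9L) .NONJA_ICD9 else .NONJA_ICD10
    add(.claimRow(person_id, sample(0:3, 1L), "hospital", "none", "inpatient",
                  v, vapply(seq_len(sample(1:2, 1L)), function(i) .sampleCode(pool),
                            character(1)), newborn_flag = TRUE))
  }

  for (j in seq_len(N_OCCASIONS)) {
    g <- measures[j, "gp_visits"]
    s <- measures[j, "specialist_visits"]
    jc <- measures[j, "ja_contact"]
    h <- measures[j, "hospitalization"]
    dlo <- spans[j, "lo"]; dhi <- spans[j, "hi"]
    rday <- function(k) dlo + sample.int(dhi - dlo + 1L, k, replace = TRUE) - 1L

    gpDays <- if (g > 0) rday(g) else integer(0)
    spDays <- if (s > 0) rday(s) else integer(0)
    gpCodes <- vapply(gpDays, function(d) .sampleCode(.NONJA_ICD9), character(1))
    spCodes <- vapply(spDays, function(d) .sampleCode(.NONJA_ICD9), character(1))

    hospRow <- NULL
    if (h > 0) {
      v <- sample(c(9L, 10L), 1L)
      pool <- if (v == 9L) .NONJA_ICD9 else .NONJA_ICD10
      nCodes <- sample(1:3, 1L)
      hospRow <- .claimRow(person_id, rday(1L), "hospital", "none", "inpatient",
                           v, vapply(seq_len(nCodes), function(i) .sampleCode(pool),
                                     character(1)))
    }

    extraRow <- NULL
    if (jc > 0) {
      ja9 <- function() .sampleCode(weights = config@jaCodeWeights9)
      placedOnHospital <- !is.null(hospRow) &&
        (runif(1) < config@pHospitalJa || (g == 0 && s == 0))
      if (placedOnHospital) {
        v <- hospRow$icd_version
        code <- if (v == 9L) ja9() else .sampleCode(weights = config@jaCodeWeights10)
        hospRow$codes[[1]][1] <- code
      } else if (s > 0 && (g == 0 || runif(1) < config@pJaSpecialist)) {
        spCodes[sample.int(s, 1L)] <- ja9()
      } else if (g > 0) {
        gpCodes[sample.int(g, 1L)] <- ja9()
      } else {
        # no ambulatory claim and no hospital record this occasion: the JA
        # contact is an in-hospital/ER physician claim, which feeds the
        # contact marker but neither the ambulatory visit counts nor the
        # hospitalization marker
        extraRow <- .claimRow(person_id, rday(1L), "physician", "specialist",
                              "inpatient", 9L, ja9())
      }
      # active disease years produce repeated coded visits: each remaining
      # ambulatory claim also carries a JA code with probability pJaSecondary
      if (s > 0 || g > 0) {
        for (k in seq_along(spCodes)) {
          if (!isJaRelated(spCodes[k], 9L) && runif(1) < config@pJaSecondary) {
            spCodes[k] <- ja9()
          }
        }
        for (k in seq_along(gpCodes)) {
          if (!isJaRelated(gpCodes[k], 9L) && runif(1) < config@pJaSecondary) {
            gpCodes[k] <- ja9()
          }
        }
      }
    }

    for (k in seq_along(gpDays)) {
      add(.claimRow(person_id, gpDays[k], "physician", "GP", "ambulatory",
                    9L, gpCodes[k]))
    }
    for (k in seq_along(spDays)) {
      add(.claimRow(person_id, spDays[k], "physician", "specialist",
                    "ambulatory", 9L, spCodes[k]))
    }
    if (!is.null(hospRow)) add(hospRow)
    if (!is.null(extraRow)) add(extraRow)
  }
  if (nr == 0L) return(.emptyClaims())
  do.call(rbind, rows[seq_len(nr)])
}

.emptyClaims <- function() {
  data.frame(
    person_id = character(0), day = integer(0), record_type = character(0),
    provider_class = character(0), setting = character(0),
    icd_version = integer(0), codes = I(list()), newborn_flag = logical(0)
  )
}

#' Generate dated claim records consistent with a cohort's annual measures
#'
#' Inverts the measure definitions: for every individual and occasion the
#' emitted claims reproduce the annual measures exactly -- the number of
#' ambulatory GP (specialist) physician claims equals `gp_visits`
#' (`specialist_visits`); some claim or hospital diagnosis carries a
#' JA-related code iff `ja_contact = 1`; a non-newborn hospital record exists
#' iff `hospitalization = 1`; all claim days fall inside the occasion's age
#' span. Physician claims are always ICD-9 coded (claims data predate the
#' ICD-10 transition for ambulatory billing); hospital records carry either
#' version.
#'
#' @param cohort A [UtilizationCohort-class] (any number of individuals).
#' @param config The [GeneratorConfig-class] driving claim placement.
#' @param seed optional seed (defaults to `config@seed + 1`).
#' @return A claims data.frame: `person_id`, `day`, `record_type`
#'   (`physician`/`hospital`), `provider_class` (`GP`/`specialist`/`none`),
#'   `setting` (`ambulatory`/`inpatient`), `icd_version`, `codes`
#'   (list-column of diagnosis code vectors; length 1 for physician claims,
#'   up to 25 for hospital records), `newborn_flag`.
#' @export
generateClaims <- function(cohort, config, seed = NULL) {
  stopifnot(is(cohort, "UtilizationCohort"))
  validObject(config)
  set.seed(if (is.null(seed)) config@seed + 1L else as.integer(seed))
  out <- lapply(seq_len(ncol(cohort)), function(i) {
    m <- sapply(MARKERS, function(mk) assay(cohort, mk)[, i])
    .claimsForIndividual(cohort$person_id[i], m, config)
  })
  if (!length(out)) return(.emptyClaims())
  do.call(rbind, out)
}

#' Derive annual utilization measures from claim records
#'
#' Applies the measure definitions to one person's claims: per occasion,
#' `ja_contact` is 1 iff any physician-claim code or any hospital-record
#' code is JA-related (broad contact set); `gp_visits` and
#' `specialist_visits` count ambulatory physician claims by provider class;
#' `hospitalization` is 1 iff any hospital record with `newborn_flag =
#' FALSE` falls in the occasion (newborn hospitalizations are excluded).
#'
#' @param claims claims data.frame (as from [generateClaims()]) for a single
#'   person; an empty table yields an all-zero matrix.
#' @return 15 x 4 numeric matrix (occasions x markers).
#' @export
deriveAnnualMeasures <- function(claims) {
  m <- matrix(0, nrow = N_OCCASIONS, ncol = length(MARKERS),
              dimnames = list(NULL, MARKERS))
  if (nrow(claims) == 0L) return(m)
  if (length(unique(claims$person_id)) > 1L) {
    stop("deriveAnnualMeasures expects claims for a single person")
  }
  occ <- dayToOccasion(claims$day)
  isHosp <- claims$record_type == "hospital"
  isAmb <- claims$record_type == "physician" & claims$setting == "ambulatory"
  nCodes <- lengths(claims$codes)
  if (any(!isHosp & nCodes != 1L)) stop("physician claims must have exactly 1 code")
  if (any(nCodes > 25L)) stop("hospital records carry at most 25 codes")
  jaRec <- vapply(seq_len(nrow(claims)), function(i) {
    any(isJaRelated(claims$codes[[i]], claims$icd_version[i]))
  }, logical(1))
  for (j in seq_len(N_OCCASIONS)) {
    sel <- occ == j
    m[j, "ja_contact"] <- as.numeric(any(jaRec[sel]))
    m[j, "gp_visits"] <- sum(sel & isAmb & claims$provider_class == "GP")
    m[j, "specialist_visits"] <- sum(sel & isAmb & claims$provider_class == "specialist")
    m[j, "hospitalization"] <- as.numeric(any(sel & isHosp & !claims$newborn_flag))
  }
  m
}
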