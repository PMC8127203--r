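test_that("occasion grid covers birth to the 16th birthday with a merged first period", {
  g <- occasionGrid()
  expect_equal(nrow(g), 15)
  expect_equal(g$age_lo[1], 0)
  expect_equal(g$age_hi[1], 2)
  expect_equal(g$age_lo[-1], 2:15)
  expect_equal(g$age_hi[-1], 3:16)
  # spans disjoint, union [0, 16)
  expect_equal(g$age_lo[-1], g$age_hi[-15])
  expect_equal(g$age, c(1, 2:15))
})

test_that("day-to-occasion mapping uses floor(day/365.25) with years 0-1 merged", {
  expect_equal(dayToOccasion(c(0, 365, 730)), c(1, 1, 1))
  expect_equal(dayToOccasion(731), 2) # first day of age 2
  expect_equal(dayToOccasion(5843), 15)
  expect_error(dayToOccasion(5844), "days must lie")
  expect_error(dayToOccasion(-1), "days must lie")
})

test_that("degenerate generator configs behave as forced", {
  empty <- generateCohort(generatorConfig(nIndividuals = 0, seed = 1))
  expect_equal(ncol(empty), 0)
  allCase <- generateCohort(generatorConfig(nIndividuals = 25, caseFraction = 1, seed = 1))
  expect_true(all(goldLabels(allCase) == "case"))
})

test_that("invalid generator parameters are rejected", {
  expect_error(generatorConfig(caseFraction = 1.5), "probability")
  eff <- generatorConfig()@effects
  eff$case["ja_contact", "age"] <- Inf
  expect_error(generatorConfig(effects = eff), "non-finite")
})

test_that("identical configs give bit-identical cohorts and claims", {
  cfg <- generatorConfig(nIndividuals = 30, seed = 99)
  c1 <- generateCohort(cfg); c2 <- generateCohort(cfg)
  for (m in MARKER_SET) {
    expect_identical(measureMatrix(c1, m), measureMatrix(c2, m))
  }
  expect_identical(goldLabels(c1), goldLabels(c2))
  expect_identical(covariateTable(c1), covariateTable(c2))
  expect_identical(latentIntercepts(c1), latentIntercepts(c2))
  k1 <- generateClaims(c1, cfg); k2 <- generateClaims(c2, cfg)
  expect_identical(k1, k2)
})

test_that("generated measures satisfy their type invariants", {
  coh <- generateCohort(generatorConfig(nIndividuals = 120, seed = 4))
  for (m in c("ja_contact", "hospitalization")) {
    expect_true(all(measureMatrix(coh, m) %in% 0:1))
  }
  for (m in c("gp_visits", "specialist_visits")) {
    x <- measureMatrix(coh, m)
    expect_true(all(x >= 0 & x == round(x)))
  }
  expect_equal(nrow(measureMatrix(coh, "ja_contact")), 15)
})

test_that("JA-related code matching is prefix-based on the category", {
  expect_true(isJaRelated("7140", 9))
  expect_true(isJaRelated("714", 9))
  expect_true(isJaRelated("M081", 10))
  expect_true(isJaRelated("M070", 10)) # inside the M05-M09 range
  expect_true(isJaRelated("M459", 10))
  expect_false(isJaRelated("715", 9))
  expect_false(isJaRelated("M04", 10))
  expect_false(isJaRelated("714", 10)) # version matters
  expect_error(isJaRelated("714", 8), "icd_version")
  expect_error(isJaRelated("", 9), "non-empty")
})

test_that("annual measures are derived from claims per the measure definitions", {
  expect_equal(deriveAnnualMeasures(oneClaim()[0, ]),
               matrix(0, 15, 4, dimnames = list(NULL, MARKER_SET)))

  # newborn hospitalization never counts toward the hospitalization marker
  nb <- oneClaim(record_type = "hospital", provider_class = "none",
                 setting = "inpatient", day = 0, codes = "V300",
                 newborn_flag = TRUE)
  expect_equal(deriveAnnualMeasures(nb)[, "hospitalization"], rep(0, 15))

  # 5 ambulatory GP claims on distinct days at ages [2, 3) -> occasion 2
  days <- 731 + c(0, 50, 100, 200, 300)
  gp <- do.call(rbind, lapply(days, function(d) oneClaim(day = d)))
  m <- deriveAnnualMeasures(gp)
  expect_equal(m[2, "gp_visits"], 5, ignore_attr = TRUE)
  expect_equal(sum(m[, "gp_visits"]), 5)
  expect_equal(sum(m[, c("ja_contact", "specialist_visits", "hospitalization")]), 0)

  # a JA code on a hospital record sets the contact marker, and inpatient
  # physician claims never enter the ambulatory visit counts
  hosp <- oneClaim(record_type = "hospital", provider_class = "none",
                   setting = "inpatient", day = 1000, codes = "M080",
                   icd_version = 10)
  mh <- deriveAnnualMeasures(hosp)
  expect_equal(mh[dayToOccasion(1000), "ja_contact"], 1, ignore_attr = TRUE)
  expect_equal(mh[dayToOccasion(1000), "hospitalization"], 1, ignore_attr = TRUE)
  inpat <- oneClaim(setting = "inpatient", provider_class = "specialist", day = 1000)
  expect_equal(sum(deriveAnnualMeasures(inpat)[, "specialist_visits"]), 0)

  expect_error(deriveAnnualMeasures(oneClaim(day = 6000)), "days must lie")
})

test_that("claims round-trip to the exact measure matrix and satisfy record invariants", {
  cfg <- generatorConfig(nIndividuals = 40, seed = 8)
  coh <- generateCohort(cfg)
  claims <- generateClaims(coh, cfg)

  expect_true(all(claims$day >= 0 & claims$day < 5844))
  isPhys <- claims$record_type == "physician"
  expect_true(all(lengths(claims$codes)[isPhys] == 1))
  expect_true(all(lengths(claims$codes)[!isPhys] <= 25))
  expect_true(all(claims$provider_class[!isPhys] == "none"))
  expect_true(all(claims$provider_class[isPhys] %in% c("GP", "specialist")))
  expect_true(all(!claims$newborn_flag[isPhys]))
  expect_true(all(claims$icd_version %in% c(9, 10)))

  for (pid in coh$person_id) {
    m <- deriveAnnualMeasures(claims[claims$person_id == pid, ])
    want <- sapply(MARKER_SET, function(mk) measureMatrix(coh, mk)[, pid])
    expect_equal(m, want, ignore_attr = TRUE)
  }
})

test_that("negative measure counts are rejected by the claims generator", {
  coh <- generateCohort(generatorConfig(nIndividuals = 2, seed = 1))
  bad <- sapply(MARKER_SET, function(m) measureMatrix(coh, m)[, 1])
  bad[3, "gp_visits"] <- -1
  expect_error(CaseLoDA:::.claimsForIndividual("X", bad, generatorConfig()),
               "negative")
})

test_that("generating model orders the groups and has a positive age trend in cases", {
  coh <- generateCohort(generatorConfig(nIndividuals = 2000, seed = 5))
  ja <- measureMatrix(coh, "ja_contact")
  isCase <- goldLabels(coh) == "case"
  # cases far exceed controls in JA contact at the last occasion
  expect_gt(mean(ja[15, isCase]), mean(ja[15, !isCase]))
  # empirical log-odds of ja_contact regressed on age within cases: positive
  # at well over 3 sigma
  age <- occasionGrid()$age
  y <- as.vector(ja[, isCase])
  x <- rep(age, times = sum(isCase))
  fit <- glm(y ~ x, family = binomial())
  z <- coef(summary(fit))["x", "z value"]
  expect_gt(z, 3)
})
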