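test_that("Bayes rule arithmetic is exact and stable in log space", {
  # equal densities, naive priors -> 1/2
  g <- groupProbabilities(log(c(0.3, 0.3)), log(c(0.3, 0.3)), c(0.5, 0.5))
  expect_equal(g$perDraw, c(0.5, 0.5))
  # f_case = 0.2, f_control = 0.1 -> 2/3
  g2 <- groupProbabilities(log(0.2), log(0.1), c(0.5, 0.5))
  expect_equal(g2$point, 2 / 3, tolerance = 1e-12)
  # degenerate priors dominate regardless of densities
  expect_equal(groupProbabilities(log(0.001), log(0.9), c(1, 0))$point, 1)
  expect_equal(groupProbabilities(log(0.9), log(0.001), c(0, 1))$point, 0)
  # extreme log densities that underflow linear space
  g3 <- groupProbabilities(-5000, -5001, c(0.5, 0.5))
  expect_equal(g3$point, plogis(1), tolerance = 1e-12)
  expect_error(groupProbabilities(c(-1, -2), -1), "draw counts")
  expect_error(groupProbabilities(-1, -1, c(0.7, 0.7)), "sum to 1")
})

test_that("case and control probabilities sum to one per draw", {
  set.seed(5)
  lfc <- rnorm(500, -40, 15)
  lf0 <- rnorm(500, -42, 15)
  pr <- c(0.37, 0.63)
  pc <- CaseLoDA:::.perDrawProb(lfc, lf0, pr)
  p0 <- CaseLoDA:::.perDrawProb(lf0, lfc, rev(pr))
  expect_true(all(pc >= 0 & pc <= 1))
  expect_equal(pc + p0, rep(1, 500), tolerance = 1e-15)
})

test_that("P_case is strictly increasing in the case prior", {
  lfc <- log(0.2); lf0 <- log(0.3)
  ps <- vapply(seq(0.05, 0.95, by = 0.05), function(pi1) {
    groupProbabilities(lfc, lf0, c(pi1, 1 - pi1))$point
  }, numeric(1))
  expect_true(all(diff(ps) > 0))
})

test_that("both groups see the same density for identical parameters and history", {
  hist <- matrix(c(0, 1, 0, 1, 1), ncol = 1,
                 dimnames = list(NULL, "ja_contact"))
  d <- matrix(c(-0.5, 0.3, 0.2, -1.7, 1.2), 1, 5,
              dimnames = list(NULL, paramNames("ja_contact")))
  for (ap in c("marginal", "conditional", "random_effects")) {
    a <- predictiveDensity(hist, 1, 0, d, ap)
    b <- predictiveDensity(hist, 1, 0, d, ap)
    expect_identical(a, b)
  }
})

test_that("a degenerate random-effects distribution collapses marginal onto conditional", {
  hist <- matrix(c(1, 0, 1), ncol = 1, dimnames = list(NULL, "ja_contact"))
  d0 <- matrix(c(0.4, -0.3, 0.1, 0, 0), 1, 5,
               dimnames = list(NULL, paramNames("ja_contact")))
  marg <- predictiveDensity(hist, 1, 1, d0, "marginal")
  cond <- predictiveDensity(hist, 1, 1, d0, "conditional")
  expect_equal(marg, cond)
  # and the common value is the likelihood at b = 0 exactly
  age <- occasionGrid()$age[1:3]
  eta <- 0.4 + (-0.3) + 0.1 * age
  want <- cumsum(dbinom(c(1, 0, 1), 1, plogis(eta), log = TRUE))
  expect_equal(as.numeric(marg), want)
})

test_that("quadrature matches dense-grid integration on small instances", {
  set.seed(12)
  for (i in 1:4) {
    fam <- if (i %% 2) "bernoulli_logit" else "poisson_log"
    mk <- if (fam == "bernoulli_logit") "ja_contact" else "gp_visits"
    theta <- c(rnorm(2, 0, 0.4), rnorm(1, 0, 0.1),
               if (fam == "bernoulli_logit") -1.5 else 1.4, runif(1, 0.6, 1.5))
    yv <- if (fam == "bernoulli_logit") rbinom(3, 1, 0.5) else rpois(3, 5)
    hist <- matrix(yv, 3, 1, dimnames = list(NULL, mk))
    d <- matrix(theta, 1, 5, dimnames = list(NULL, paramNames(mk)))
    got <- predictiveDensity(hist, 1, 0, d, "marginal")[1, ]
    want <- trapezoidMarginal(yv, 1, 0, theta, fam, 3)
    expect_lt(max(abs(exp(got - want) - 1)), 1e-6)
  }
})

test_that("posterior mode and posterior mean intercept estimators agree closely", {
  set.seed(33)
  for (mk in c("ja_contact", "gp_visits")) {
    fam <- if (mk == "ja_contact") "bernoulli_logit" else "poisson_log"
    yv <- if (fam == "bernoulli_logit") rbinom(6, 1, 0.5) else rpois(6, 4)
    hist <- matrix(yv, 6, 1, dimnames = list(NULL, mk))
    theta <- c(-0.4, 0.2, 0.05, if (fam == "bernoulli_logit") -1 else 1.2, 0.9)
    d <- matrix(theta, 1, 5, dimnames = list(NULL, paramNames(mk)))
    lmean <- predictiveDensity(hist, 1, 0, d, "conditional", bEstimator = "mean")
    lmode <- predictiveDensity(hist, 1, 0, d, "conditional", bEstimator = "mode")
    expect_true(all(is.finite(lmean)) && all(is.finite(lmode)))
    # near-Gaussian 1-D posteriors: mean and mode give similar densities
    expect_lt(max(abs(lmean - lmode)), 0.5)
  }
})

test_that("unknown approaches and malformed histories are rejected", {
  hist <- matrix(1, 1, 1, dimnames = list(NULL, "ja_contact"))
  d <- matrix(c(0, 0, 0, 0, 1), 1, 5, dimnames = list(NULL, paramNames("ja_contact")))
  expect_error(predictiveDensity(hist, 1, 0, d, "plugin"))
  expect_error(predictiveDensity(hist[0, , drop = FALSE], 1, 0, d), "non-empty")
  expect_error(predictiveDensity(hist, 1, 0, d[0, , drop = FALSE]), "non-empty")
})

test_that("probabilities accrue toward the right group as history accumulates", {
  coh <- generateCohort(generatorConfig(nIndividuals = 150, seed = 19))
  dc <- truthDraws("case", nDraws = 60, seed = 2)
  d0 <- truthDraws("control", nDraws = 60, seed = 3)
  isCase <- goldLabels(coh) == "case"
  for (ap in c("marginal", "random_effects")) {
    ps <- computeProbabilitySeries(coh, dc, d0, ap)
    e <- probabilityEntries(ps)
    mCase <- tapply(e$p_point[e$person_id %in% names(which(isCase))],
                    e$occasion[e$person_id %in% names(which(isCase))], mean)
    mCtrl <- tapply(e$p_point[e$person_id %in% names(which(!isCase))],
                    e$occasion[e$person_id %in% names(which(!isCase))], mean)
    checkpoints <- c(1, 5, 10, 15)
    expect_true(all(diff(mCase[checkpoints]) > 0))
    expect_true(all(diff(mCtrl[checkpoints]) < 0))
    expect_true(all(e$p_lo <= e$p_point + 1e-12 & e$p_point <= e$p_hi + 1e-12))
  }
})

test_that("marginal probabilities spread more across individuals than random-effects ones", {
  # the marginal approach reacts to each individual's own history from the
  # first occasion, while the random-effects approach compares estimated
  # intercepts that are still prior-dominated early on: predicted
  # probabilities therefore vary more between individuals under the
  # marginal approach, and their spread grows as history accrues
  coh <- generateCohort(generatorConfig(nIndividuals = 120, seed = 29))
  dc <- truthDraws("case", nDraws = 80, jitterSd = 0.1, seed = 4)
  d0 <- truthDraws("control", nDraws = 80, jitterSd = 0.1, seed = 5)
  sds <- lapply(c(marginal = "marginal", random_effects = "random_effects"),
                function(ap) {
    e <- probabilityEntries(computeProbabilitySeries(coh, dc, d0, ap))
    tapply(e$p_point, e$occasion, sd)
  })
  occ <- c(1, 4, 8)
  expect_true(all(sds$marginal[occ] >= sds$random_effects[occ]))
  # spread increases over the time periods for both approaches
  expect_gt(sds$marginal[15], sds$marginal[1])
  expect_gt(sds$random_effects[15], sds$random_effects[1])
})
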