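test_that("k-fold splits are balanced, reproducible and bounded", {
  f <- kfoldSplit(10, k = 5, seed = 1)
  expect_equal(unname(table(f)), rep(2L, 5), ignore_attr = TRUE)
  expect_identical(kfoldSplit(100, 5, seed = 3), kfoldSplit(100, 5, seed = 3))
  # the study cohort size splits 160/160/159/159/159 in some order
  sizes <- sort(as.integer(table(kfoldSplit(797, 5, seed = 2))), decreasing = TRUE)
  expect_equal(sizes, c(160L, 160L, 159L, 159L, 159L))
  expect_error(kfoldSplit(4, k = 5), "exceed")
  expect_error(kfoldSplit(10, k = 1), ">= 2")
})

test_that("confusion matrices conserve the truth-group sizes", {
  set.seed(8)
  truth <- sample(c("case", "control"), 60, replace = TRUE)
  assigned <- sample(c("case", "control", "indeterminate"), 60, replace = TRUE)
  conf <- confusionWithIndeterminate(truth, assigned)
  expect_equal(rowSums(conf), c(case = sum(truth == "case"),
                                control = sum(truth == "control")))
  # additivity: pooled confusion equals the sum of part confusions
  half <- seq_len(30)
  expect_equal(confusionWithIndeterminate(truth[half], assigned[half]) +
                 confusionWithIndeterminate(truth[-half], assigned[-half]),
               conf)
})

test_that("accuracy measures follow the indeterminate-aware definitions", {
  conf <- matrix(as.integer(c(70, 20, 10, 5, 80, 15)), 2, 3, byrow = TRUE,
                 dimnames = list(truth = c("case", "control"),
                                 assigned = c("case", "control", "indeterminate")))
  all <- accuracyMeasures(conf, "all_data")
  cls <- accuracyMeasures(conf, "classified_only")
  expect_equal(all$sensitivity, 0.70)
  expect_equal(cls$sensitivity, 70 / 90)
  expect_equal(all$specificity, 80 / 100)
  expect_equal(cls$specificity, 80 / 85)
  # indeterminates never enter PPV/NPV denominators
  expect_equal(all$ppv, 70 / 75)
  expect_equal(cls$ppv, 70 / 75)
  expect_equal(all$npv, 80 / 100)
  expect_equal(all$proportion_indeterminate, 25 / 200)
  expect_gte(cls$sensitivity, all$sensitivity)

  perfect <- matrix(as.integer(c(50, 0, 0, 0, 50, 0)), 2, 3, byrow = TRUE,
                    dimnames = dimnames(conf))
  pm <- accuracyMeasures(perfect, "all_data")
  expect_equal(unlist(pm[c("sensitivity", "specificity", "ppv", "npv", "pcc")]),
               rep(1, 5), ignore_attr = TRUE)

  # zero denominator reported as NA, not silently 0
  none <- matrix(as.integer(c(0, 0, 30, 0, 40, 0)), 2, 3, byrow = TRUE,
                 dimnames = dimnames(conf))
  expect_true(is.na(accuracyMeasures(none, "all_data")$ppv))
  expect_error(accuracyMeasures(matrix(0L, 2, 3,
                                       dimnames = dimnames(conf)), "all_data"),
               "at least one")
})

test_that("Wilson intervals match the prop.test score interval", {
  set.seed(14)
  for (i in 1:40) {
    n <- sample(5:500, 1)
    x <- sample(0:n, 1)
    got <- wilsonCI(x, n)
    want <- suppressWarnings(prop.test(x, n, correct = FALSE))$conf.int
    expect_equal(unname(got), as.numeric(want), tolerance = 1e-12)
  }
  expect_true(all(is.na(wilsonCI(0, 0))))
})

test_that("rank-based AUC handles separation, ties and null data", {
  expect_equal(aucRank(c(0.9, 0.8, 0.2, 0.1), c("case", "case", "control", "control")), 1)
  expect_equal(aucRank(rep(0.5, 10), rep(c("case", "control"), 5)), 0.5)
  set.seed(3)
  p <- runif(2000); lab <- sample(c("case", "control"), 2000, replace = TRUE)
  expect_lt(abs(aucRank(p, lab) - 0.5), 0.03)
  expect_error(aucRank(c(0.1, 0.2), c("case", "case")), "both classes")
})

test_that("rank-based AUC equals the trapezoidal ROC area from pROC", {
  skip_if_not_installed("pROC")
  set.seed(9)
  p <- round(runif(300), 2) # rounding forces ties
  lab <- ifelse(runif(300) < plogis(3 * (p - 0.5)), "case", "control")
  got <- aucRank(p, lab)
  want <- as.numeric(pROC::auc(pROC::roc(
    response = factor(lab, levels = c("control", "case")),
    predictor = p, quiet = TRUE
  )))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("mean classification time averages decision ages over the classified", {
  out <- data.frame(
    person_id = c("a", "b", "c"),
    final_label = c("case", "control", "indeterminate"),
    decision_occasion = c(1L, 15L, NA),
    decision_age = c(2, 16, NA)
  )
  expect_equal(as.numeric(meanClassificationTime(out)), 9)
  expect_equal(attr(meanClassificationTime(out), "n_excluded_indeterminate"), 1)
  allOcc1 <- data.frame(person_id = "a", final_label = "case",
                        decision_occasion = 1L, decision_age = 2)
  expect_equal(as.numeric(meanClassificationTime(allOcc1)), 2)
  never <- data.frame(person_id = "a", final_label = "indeterminate",
                      decision_occasion = NA_integer_, decision_age = NA_real_)
  expect_warning(res <- meanClassificationTime(never), "undefined")
  expect_true(is.na(res))
})

test_that("evolution of accuracy respects the freeze invariant", {
  set.seed(21)
  n <- 80
  out <- data.frame(
    person_id = sprintf("P%02d", 1:n),
    final_label = sample(c("case", "control", "indeterminate"), n, replace = TRUE),
    decision_occasion = sample(1:15, n, replace = TRUE)
  )
  out$decision_occasion[out$final_label == "indeterminate"] <- NA
  out$decision_age <- occasionGrid()$age_hi[out$decision_occasion]
  truth <- setNames(sample(c("case", "control"), n, replace = TRUE), out$person_id)
  ev <- evolutionTable(out, truth)
  unc <- ev$proportion_indeterminate[ev$variant == "all_data"]
  expect_true(all(diff(unc) <= 1e-12))
  expect_equal(unc[15], mean(out$final_label == "indeterminate"))
})

test_that("cross-validation wires fitting, cutoffs and scoring together", {
  coh <- generateCohort(generatorConfig(nIndividuals = 120, seed = 51))
  cv <- runCrossValidation(coh, "ja_utilization", approach = "marginal",
                           scheme = "cri", mcmc = fastMcmc(seed = 61),
                           k = 3, seed = 4, nodes = 21)
  truth <- goldLabels(coh)
  # every individual scored exactly once, confusions conserve group sizes
  expect_setequal(cv$outcomes$person_id, names(truth))
  expect_equal(sum(cv$pooled_confusion), 120)
  expect_equal(rowSums(cv$pooled_confusion),
               c(case = sum(truth == "case"), control = sum(truth == "control")))
  # pipeline consistency: pooled PPV recomputed from raw outcomes
  assigned <- setNames(cv$outcomes$final_label, cv$outcomes$person_id)
  tp <- sum(assigned == "case" & truth[names(assigned)] == "case")
  fp <- sum(assigned == "case" & truth[names(assigned)] == "control")
  expect_equal(cv$pooled$ppv[cv$pooled$variant == "all_data"], tp / (tp + fp))
  # averaged metrics are the unweighted fold means
  fm <- cv$fold_metrics[cv$fold_metrics$variant == "all_data", ]
  expect_equal(cv$averaged$sensitivity[cv$averaged$variant == "all_data"],
               mean(fm$sensitivity))
  expect_length(cv$cutoffs, 3)
  expect_true(all(cv$cutoffs >= 0 & cv$cutoffs <= 1))
  expect_true(cv$auc > 0.5) # separated generating groups
})

test_that("the deterministic definition is scored through the same accuracy path", {
  cfg <- generatorConfig(nIndividuals = 60, seed = 71)
  coh <- generateCohort(cfg)
  claims <- generateClaims(coh, cfg)
  res <- evaluateDeterministic(claims, goldLabels(coh))
  expect_equal(sum(res$confusion[, "indeterminate"]), 0)
  expect_equal(res$accuracy$proportion_indeterminate, 0)
  expect_equal(sum(res$confusion), 60)
  # deterministic labels match classifyDeterministic person by person
  for (pid in coh$person_id[1:10]) {
    expect_equal(res$labels$det_label[res$labels$person_id == pid],
                 classifyDeterministic(claims[claims$person_id == pid, ]))
  }
})
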