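# Cross-validated evaluation: confusion matrices with an indeterminate
# category, accuracy measures with Wilson score intervals, rank-based AUC,
# per-occasion evolution of accuracy, and the five-fold orchestration that
# fits group models on training folds and classifies the held-out fold.

#' Random k-fold split
#'
#' Simple (non-stratified) random partition with fold sizes differing by at
#' most one; reproducible by seed.
#'
#' @param n cohort size (or a [UtilizationCohort-class]).
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @return Integer vector of fold assignments in 1..k.
#' @export
kfoldSplit <- function(n, k = 5L, seed = 1L) {
  if (is(n, "UtilizationCohort")) n <- ncol(n)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k must not exceed the cohort size")
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' Confusion matrix with an indeterminate category
#'
#' @param truth gold-standard labels (`"case"`/`"control"`).
#' @param assigned assigned labels
#'   (`"case"`/`"control"`/`"indeterminate"`).
#' @return 2 x 3 integer matrix, rows truth, columns assigned.
#' @export
confusionWithIndeterminate <- function(truth, assigned) {
  stopifnot(length(truth) == length(assigned))
  tab <- table(
    factor(truth, levels = c("case", "control")),
    factor(assigned, levels = c("case", "control", "indeterminate"))
  )
  m <- matrix(as.integer(tab), 2, 3,
              dimnames = list(truth = c("case", "control"),
                              assigned = c("case", "control", "indeterminate")))
  m
}

#' Wilson score confidence interval for a proportion
#'
#' @param x successes.
#' @param n trials.
#' @param level confidence level (default 0.95).
#' @return `c(lower, upper)`; `c(NA, NA)` when `n == 0`.
#' @export
wilsonCI <- function(x, n, level = 0.95) {
  if (n == 0) return(c(lower = NA_real_, upper = NA_real_))
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = centre - half, upper = centre + half)
}

.rate <- function(num, den) if (den == 0) NA_real_ else num / den

#' Accuracy measures from a confusion matrix with indeterminates
#'
#' Two variants: `all_data` keeps indeterminate individuals in the
#' sensitivity/specificity denominators (an unclassified case counts
#' against sensitivity); `classified_only` removes them. PPV and NPV never
#' include indeterminates in their denominators (only assigned labels
#' enter). PCC is the proportion correctly classified with the
#' variant-consistent denominator. 95% CIs are Wilson score intervals.
#' Zero denominators yield `NA` rates, never silent zeros.
#'
#' @param confusion 2 x 3 matrix from [confusionWithIndeterminate()].
#' @param variant `"all_data"` or `"classified_only"`.
#' @return One-row data.frame: `sensitivity`, `specificity`, `ppv`, `npv`
#'   (each with `_lo`/`_hi` Wilson bounds), `pcc`,
#'   `proportion_indeterminate`, `variant`.
#' @export
accuracyMeasures <- function(confusion, variant = c("all_data", "classified_only")) {
  variant <- match.arg(variant)
  if (sum(confusion["case", ]) == 0 || sum(confusion["control", ]) == 0) {
    stop("need at least one truth-case and one truth-control")
  }
  TP <- confusion["case", "case"]; FN <- confusion["case", "control"]
  Ic <- confusion["case", "indeterminate"]
  TN <- confusion["control", "control"]; FP <- confusion["control", "case"]
  In <- confusion["control", "indeterminate"]
  sensDen <- if (variant == "all_data") TP + FN + Ic else TP + FN
  specDen <- if (variant == "all_data") TN + FP + In else TN + FP
  total <- if (variant == "all_data") sum(confusion) else sum(confusion[, 1:2])
  sens <- .rate(TP, sensDen); spec <- .rate(TN, specDen)
  ppv <- .rate(TP, TP + FP); npv <- .rate(TN, TN + FN)
  sci <- wilsonCI(TP, sensDen); pci <- wilsonCI(TN, specDen)
  ppvci <- wilsonCI(TP, TP + FP); npvci <- wilsonCI(TN, TN + FN)
  data.frame(
    sensitivity = sens, sensitivity_lo = sci[1], sensitivity_hi = sci[2],
    specificity = spec, specificity_lo = pci[1], specificity_hi = pci[2],
    ppv = ppv, ppv_lo = ppvci[1], ppv_hi = ppvci[2],
    npv = npv, npv_lo = npvci[1], npv_hi = npvci[2],
    pcc = .rate(TP + TN, total),
    proportion_indeterminate = (Ic + In) / sum(confusion),
    variant = variant, row.names = NULL
  )
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Area under the ROC curve computed from ranks, ties averaged.
#'
#' @param probabilities case-membership probabilities (or any score).
#' @param labels gold-standard labels, both classes present.
#' @return Numeric scalar in \[0, 1\].
#' @export
aucRank <- function(probabilities, labels) {
  isCase <- labels == "case"
  nC <- sum(isCase); nN <- sum(!isCase)
  if (nC == 0 || nN == 0) stop("both classes must be present")
  r <- rank(probabilities)
  (sum(r[isCase]) - nC * (nC + 1) / 2) / (nC * nN)
}

#' Mean classification time
#'
#' Mean decision age (years) over classified individuals; indeterminate
#' individuals are excluded (and their count attached as an attribute).
#'
#' @param outcomes data.frame from [classifySequential()].
#' @return Numeric scalar (NA with a warning if nobody was classified).
#' @export
meanClassificationTime <- function(outcomes) {
  cls <- outcomes[outcomes$final_label != "indeterminate", ]
  if (!nrow(cls)) {
    warning("no classified individuals; mean classification time undefined")
    out <- NA_real_
  } else {
    out <- mean(cls$decision_age)
  }
  attr(out, "n_excluded_indeterminate") <- sum(outcomes$final_label == "indeterminate")
  out
}

# per-occasion classification state implied by frozen sequential decisions
.stateAtOccasion <- function(outcomes, j) {
  ifelse(!is.na(outcomes$decision_occasion) & outcomes$decision_occasion <= j,
         outcomes$final_label, "indeterminate")
}

#' Evolution of accuracy across occasions
#'
#' For each occasion j, tabulates the classification state implied by the
#' frozen sequential decisions made up to j and computes the proportion
#' unclassified plus sensitivity, specificity and PPV under both the
#' all-data and classified-only variants.
#'
#' @param outcomes data.frame from [classifySequential()].
#' @param truth gold labels named by person id (or parallel to `outcomes`).
#' @return data.frame, one row per occasion x variant.
#' @export
evolutionTable <- function(outcomes, truth) {
  if (!is.null(names(truth))) truth <- truth[outcomes$person_id]
  do.call(rbind, lapply(seq_len(N_OCCASIONS), function(j) {
    st <- .stateAtOccasion(outcomes, j)
    conf <- confusionWithIndeterminate(truth, st)
    do.call(rbind, lapply(c("all_data", "classified_only"), function(v) {
      acc <- try(accuracyMeasures(conf, v), silent = TRUE)
      if (inherits(acc, "try-error")) return(NULL)
      cbind(occasion = j,
            acc[, c("variant", "sensitivity", "specificity", "ppv", "npv",
                    "pcc", "proportion_indeterminate")])
    }))
  }))
}

#' Evaluate the deterministic case definition against gold labels
#'
#' Runs the claim-level rule and scores it through the same confusion /
#' accuracy path as the dynamic classifier (the indeterminate column is
#' structurally zero).
#'
#' @param claims claims data.frame for the cohort.
#' @param truth gold labels named by person id.
#' @param rule A [CaseDefinitionRule-class].
#' @return list with `labels`, `confusion`, `accuracy`.
#' @export
evaluateDeterministic <- function(claims, truth, rule = caseDefinitionRule()) {
  det <- deterministicLabels(claims, rule, person_ids = names(truth))
  conf <- confusionWithIndeterminate(truth, det$det_label)
  list(labels = det, confusion = conf,
       accuracy = accuracyMeasures(conf, "all_data"))
}

#' Five-fold cross-validated dynamic classification
#'
#' For each fold: fits the case-group and control-group MGLMMs on the
#' training folds, computes held-out probability series at every occasion,
#' selects the d^2-optimal cutoff on the training individuals'
#' final-occasion point estimates (per fold), classifies the held-out
#' individuals sequentially, and tabulates the confusion matrix (with
#' indeterminates) after the last occasion. Reports fold-level and
#' (unweighted) averaged accuracy for both variants, pooled-confusion
#' accuracy, the per-occasion evolution of accuracy, AUC from
#' final-occasion point estimates, and mean classification time.
#'
#' @param cohort A [UtilizationCohort-class] with gold labels.
#' @param model `"ja_utilization"` or `"full"` (or an [MGLMMSpec-class]).
#' @param approach prediction approach (see [predictiveDensity()]).
#' @param scheme allocation scheme, `"cri"` or `"point"`.
#' @param mcmc An [McmcConfig-class]; each fold/group fit derives its seed
#'   from it.
#' @param k folds (default 5).
#' @param seed seed for the fold split.
#' @param cutoff `"auto"` (per-fold d^2-optimal) or a fixed numeric value.
#' @param priors,criLevel,nodes forwarded to [computeProbabilitySeries()].
#' @return list with `fold_metrics`, `averaged`, `pooled`,
#'   `pooled_confusion`, `evolution`, `outcomes`, `cutoffs`, `auc`,
#'   `mean_classification_time`, `folds`.
#' @export
runCrossValidation <- function(cohort, model = "ja_utilization",
                               approach = "random_effects", scheme = "cri",
                               mcmc = mcmcConfig(), k = 5L, seed = 1L,
                               cutoff = "auto",
                               priors = c(case = 0.5, control = 0.5),
                               criLevel = 0.99, nodes = 31L) {
  spec <- if (is(model, "MGLMMSpec")) model else mglmmSpec(model)
  truth <- goldLabels(cohort)
  folds <- kfoldSplit(ncol(cohort), k = k, seed = seed)
  outcomes <- NULL
  foldMetrics <- NULL
  cutoffs <- numeric(k)
  aucs <- numeric(k)
  pooledConf <- matrix(0L, 2, 3, dimnames = list(c("case", "control"),
                                                 c("case", "control", "indeterminate")))
  finalP <- NULL
  for (f in seq_len(k)) {
    train <- cohort[, folds != f]
    test <- cohort[, folds == f]
    if (length(unique(train$group)) < 2L) {
      stop("training set for fold ", f, " contains a single class")
    }
    mc <- mcmc
    mc@seed <- mcmc@seed + 1000L * f
    dCase <- fitMglmm(train, "case", spec, mc)
    mc@seed <- mc@seed + 500L
    dCtrl <- fitMglmm(train, "control", spec, mc)

    cut_f <- if (identical(cutoff, "auto")) {
      trainPs <- computeProbabilitySeries(train, dCase, dCtrl, approach,
                                          priors, criLevel, nodes)
      e <- probabilityEntries(trainPs)
      e15 <- e[e$occasion == N_OCCASIONS, ]
      selectCutoff(e15$p_point, truth[e15$person_id])
    } else {
      as.numeric(cutoff)
    }
    cutoffs[f] <- cut_f

    ps <- computeProbabilitySeries(test, dCase, dCtrl, approach,
                                   priors, criLevel, nodes)
    cfg <- allocationConfig(cutoff = cut_f, scheme = scheme, criLevel = criLevel)
    out_f <- classifySequential(ps, cfg)
    out_f$fold <- f
    e <- probabilityEntries(ps)
    e15 <- e[e$occasion == N_OCCASIONS, ]
    finalP <- rbind(finalP, data.frame(person_id = e15$person_id,
                                       p_point = e15$p_point, fold = f))
    aucs[f] <- aucRank(e15$p_point, truth[e15$person_id])
    conf <- confusionWithIndeterminate(truth[out_f$person_id], out_f$final_label)
    pooledConf <- pooledConf + conf
    fm <- do.call(rbind, lapply(c("all_data", "classified_only"),
                                function(v) accuracyMeasures(conf, v)))
    fm$fold <- f
    fm$auc <- aucs[f]
    foldMetrics <- rbind(foldMetrics, fm)
    outcomes <- rbind(outcomes, out_f)
  }
  num <- vapply(foldMetrics, is.numeric, logical(1)) & names(foldMetrics) != "fold"
  averaged <- do.call(rbind, lapply(unique(foldMetrics$variant), function(v) {
    sub <- foldMetrics[foldMetrics$variant == v, ]
    av <- as.data.frame(t(colMeans(sub[, num, drop = FALSE], na.rm = TRUE)))
    av$variant <- v
    av
  }))
  pooled <- do.call(rbind, lapply(c("all_data", "classified_only"),
                                  function(v) accuracyMeasures(pooledConf, v)))
  list(
    fold_metrics = foldMetrics,
    averaged = averaged,
    pooled = pooled,
    pooled_confusion = pooledConf,
    evolution = evolutionTable(outcomes, truth),
    outcomes = outcomes,
    cutoffs = cutoffs,
    auc = mean(aucs),
    final_probabilities = finalP,
    mean_classification_time = meanClassificationTime(outcomes),
    folds = folds
  )
}
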