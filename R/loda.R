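# Longitudinal discriminant analysis: predictive densities of an accrued
# marker history under each group's fitted MGLMM, and Bayes-rule group
# membership probabilities with per-draw credible intervals.
#
# All density work is done in log space: a history of up to 15 Bernoulli /
# Poisson terms underflows in linear space. The random intercept is
# integrated out (marginal approach) by Gauss-Hermite quadrature with 31
# nodes by default.

# observation-level log-likelihood, with normalizing constants
.llObs <- function(y, eta, family) {
  if (family == "bernoulli_logit") {
    y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))
  } else {
    y * eta - exp(pmin(eta, 500)) - lgamma(y + 1)
  }
}

# Core: per-draw log predictive densities of accrued histories.
# Ylist: list (by marker) of n x J matrices; drawsMat: M x (5 per marker)
# with columns <marker>.<coef>. Returns logf: n x J x M array (log density
# of the history through occasion j, summed over markers) and bhat: list by
# marker of n x J x M arrays of estimated intercepts.
.logDensCoreRaw <- function(Ylist, male, urban, drawsMat, markers, families,
                            approach = c("marginal", "conditional", "random_effects"),
                            nodes = 31L, bEstimator = c("mean", "mode")) {
  approach <- match.arg(approach)
  bEstimator <- match.arg(bEstimator)
  n <- length(male)
  J <- ncol(Ylist[[1]])
  M <- nrow(drawsMat)
  age <- occasionGrid()$age[seq_len(J)]
  gh <- pracma::gaussHermite(nodes)
  lw <- log(gh$w) - 0.5 * log(pi)
  U <- upper.tri(matrix(0, J, J), diag = TRUE) * 1 # row-cumsum operator

  logf <- array(0, dim = c(n, J, M))
  bhat <- if (approach != "marginal") {
    setNames(lapply(markers, function(m) array(NA_real_, c(n, J, M))), markers)
  } else {
    NULL
  }

  for (m in markers) {
    y <- Ylist[[m]]
    fam <- families[[m]]
    cols <- paste0(m, ".", c("male", "urban", "age", "mu_b", "sd_b"))
    par <- drawsMat[, cols, drop = FALSE]
    for (d in seq_len(M)) {
      a1 <- par[d, 1]; a2 <- par[d, 2]; a3 <- par[d, 3]
      mu <- par[d, 4]; sig <- par[d, 5]
      etaBase <- outer(male * a1 + urban * a2, age * a3, "+")
      if (sig < 1e-10) {
        # degenerate random-effects distribution: everything sits at b = mu
        cum <- .llObs(y, etaBase + mu, fam) %*% U
        lm <- cum
        bh <- matrix(mu, n, J)
      } else if (fam == "poisson_log") {
        # adaptive quadrature: a subject's accumulated counts make the
        # conditional posterior of b much narrower than N(mu, sig), so the
        # nodes are recentred at its mode and rescaled by its curvature
        agq <- .poisAgq(y, male * a1 + urban * a2, a3, age, mu, sig, gh, U)
        lm <- agq$lm
        bh <- agq$bhat
        if (approach != "marginal" && bEstimator == "mode") {
          bh <- .bMode(y, etaBase, fam, mu, sig, J)
        }
      } else {
        bq <- mu + sqrt(2) * sig * gh$x
        cums <- lapply(seq_len(nodes), function(q) {
          .llObs(y, etaBase + bq[q], fam) %*% U + lw[q]
        })
        mx <- Reduce(pmax, cums)
        sumExp <- Reduce(`+`, lapply(cums, function(cq) exp(cq - mx)))
        lm <- mx + log(sumExp)
        if (approach != "marginal") {
          wb <- Reduce(`+`, lapply(seq_len(nodes), function(q) {
            bq[q] * exp(cums[[q]] - mx)
          }))
          bh <- wb / sumExp
          if (bEstimator == "mode") {
            bh <- .bMode(y, etaBase, fam, mu, sig, J)
          }
        }
      }
      if (approach == "marginal") {
        logf[, , d] <- logf[, , d] + lm
      } else {
        bhat[[m]][, , d] <- bh
        if (approach == "conditional") {
          lc <- vapply(seq_len(J), function(j) {
            rowSums(.llObs(y[, seq_len(j), drop = FALSE],
                           etaBase[, seq_len(j), drop = FALSE] + bh[, j],
                           fam))
          }, numeric(n))
          logf[, , d] <- logf[, , d] + lc
        } else { # random_effects
          logf[, , d] <- logf[, , d] +
            dnorm(bh, mu, max(sig, 1e-10), log = TRUE)
        }
      }
    }
  }
  list(logf = logf, bhat = bhat)
}

# Adaptive Gauss-Hermite marginal log density and posterior-mean intercept
# for a Poisson marker, vectorized over individuals x prefix lengths.
# For the history through occasion j, the integrand profile depends only on
# the cumulative count CB, the cumulative exposure-like term CE = e^{base} *
# sum_{j'<=j} e^{a3 age_j'}, and the cumulative lgamma constants.
.poisAgq <- function(y, base, a3, age, mu, sig, gh, U) {
  n <- nrow(y); J <- ncol(y)
  CB <- y %*% U
  CA <- (y * matrix(age, n, J, byrow = TRUE)) %*% U
  CE <- exp(base) %o% cumsum(exp(a3 * age))
  Lg <- lgamma(y + 1) %*% U
  isig2 <- 1 / sig^2
  b <- matrix(mu, n, J)
  for (it in seq_len(100)) {
    eb <- exp(pmin(b, 690)) * CE
    d1 <- CB - eb - (b - mu) * isig2
    d2 <- -eb - isig2
    step <- pmin(pmax(d1 / d2, -3), 3)
    b <- b - step
    if (max(abs(step)) < 1e-10) break
  }
  h <- 1 / sqrt(-d2)
  gs <- lapply(seq_along(gh$x), function(q) {
    bq <- b + sqrt(2) * h * gh$x[q]
    bq * CB - exp(pmin(bq, 690)) * CE - 0.5 * (bq - mu)^2 * isig2 +
      log(gh$w[q]) + gh$x[q]^2
  })
  mx <- Reduce(pmax, gs)
  sumExp <- Reduce(`+`, lapply(gs, function(g) exp(g - mx)))
  lI <- 0.5 * log(2) + log(h) + mx + log(sumExp) - log(sig) - 0.5 * log(2 * pi)
  wb <- Reduce(`+`, lapply(seq_along(gh$x), function(q) {
    (b + sqrt(2) * h * gh$x[q]) * exp(gs[[q]] - mx)
  }))
  list(
    lm = matrix(base, n, J) * CB + a3 * CA - Lg + lI,
    bhat = wb / sumExp
  )
}

# posterior mode of the intercept given history through each occasion
.bMode <- function(y, etaBase, fam, mu, sig, J) {
  n <- nrow(y)
  out <- matrix(NA_real_, n, J)
  for (i in seq_len(n)) {
    for (j in seq_len(J)) {
      f <- function(b) {
        sum(.llObs(y[i, seq_len(j)], etaBase[i, seq_len(j)] + b, fam)) +
          dnorm(b, mu, sig, log = TRUE)
      }
      out[i, j] <- optimize(f, c(mu - 8 * sig, mu + 8 * sig), maximum = TRUE)$maximum
    }
  }
  out
}

.logDensCore <- function(cohort, drawsMat, spec, approach, nodes = 31L,
                         bEstimator = "mean") {
  cov <- covariateTable(cohort)
  Ylist <- setNames(lapply(spec@markers, function(m) t(measureMatrix(cohort, m))),
                    spec@markers)
  .logDensCoreRaw(Ylist, cov$male, cov$urban, drawsMat, spec@markers,
                  spec@families, approach, nodes, bEstimator)
}

#' Predictive density of one individual's accrued marker history
#'
#' For every posterior draw and occasion j, the log predictive density of
#' the history through occasion j under one group's model, using one of the
#' three prediction approaches: `marginal` (random intercept integrated out
#' by Gauss-Hermite quadrature), `conditional` (likelihood evaluated at the
#' estimated intercept b-hat, the per-draw posterior mean of b given the
#' history), or `random_effects` (density of b-hat under the group's
#' random-intercept distribution).
#'
#' @param history numeric matrix, occasions (1..j) x markers, with columns
#'   named by marker.
#' @param male,urban 0/1 covariates of the individual.
#' @param draws A [PosteriorDraws-class] (or a draws matrix with the same
#'   column naming).
#' @param approach prediction approach.
#' @param nodes Gauss-Hermite nodes (default 31).
#' @param bEstimator posterior `"mean"` (default) or `"mode"` of the
#'   intercept for the conditional / random-effects approaches.
#' @return Numeric matrix, draws x occasions, of log predictive densities.
#' @export
predictiveDensity <- function(history, male, urban, draws,
                              approach = c("marginal", "conditional", "random_effects"),
                              nodes = 31L, bEstimator = c("mean", "mode")) {
  approach <- match.arg(approach)
  if (NROW(history) < 1L) stop("history must be non-empty")
  history <- as.matrix(history)
  markers <- colnames(history)
  stopifnot(!is.null(markers), all(markers %in% MARKERS))
  drawsMat <- if (is(draws, "PosteriorDraws")) draws@draws else as.matrix(draws)
  if (nrow(drawsMat) < 1L) stop("draws must be non-empty")
  Ylist <- setNames(lapply(markers, function(m) matrix(history[, m], nrow = 1)),
                    markers)
  res <- .logDensCoreRaw(Ylist, male, urban, drawsMat, markers,
                         MARKER_FAMILIES[markers], approach, nodes,
                         match.arg(bEstimator))
  lf <- res$logf
  t(matrix(lf[1, , ], nrow = dim(lf)[2], ncol = dim(lf)[3]))
}

#' Group-membership probabilities from per-draw log densities
#'
#' Applies Bayes' rule per draw, in log space:
#' `P_case = pi_case f_case / (pi_case f_case + pi_control f_control)`.
#' The point estimate is the mean over draws and the credible interval the
#' equal-tailed quantiles at `criLevel`. Draws for which both densities are
#' zero (log density `-Inf`) are skipped and counted.
#'
#' @param logf_case,logf_control numeric vectors of per-draw log predictive
#'   densities (equal length).
#' @param priors prior group probabilities `c(case, control)`, positive,
#'   summing to 1 (boundary 0/1 priors are honoured as limits).
#' @param criLevel credible level (default 0.99).
#' @return List with `perDraw`, `point`, `lower`, `upper`, `nUsed`,
#'   `nSkipped`.
#' @examples
#' groupProbabilities(log(0.2), log(0.1), c(0.5, 0.5))$point # 2/3
#' @export
groupProbabilities <- function(logf_case, logf_control, priors = c(0.5, 0.5),
                               criLevel = 0.99) {
  if (length(logf_case) != length(logf_control)) {
    stop("draw counts differ between groups")
  }
  if (any(priors < 0) || abs(sum(priors) - 1) > 1e-8) {
    stop("priors must be non-negative and sum to 1")
  }
  p <- .perDrawProb(logf_case, logf_control, priors)
  bad <- is.na(p)
  nSkip <- sum(bad)
  if (nSkip > 0) {
    message(nSkip, " draw(s) skipped (zero density under both groups)")
  }
  p <- p[!bad]
  if (!length(p)) stop("no draw with positive density under either group")
  alpha <- (1 - criLevel) / 2
  q <- quantile(p, c(alpha, 1 - alpha), names = FALSE)
  list(perDraw = p, point = mean(p), lower = q[1], upper = q[2],
       nUsed = length(p), nSkipped = nSkip)
}

# stable per-draw case probability; NA where both groups have zero density
.perDrawProb <- function(lfCase, lfControl, priors) {
  if (priors[1] == 0) {
    return(ifelse(is.infinite(lfControl) & is.infinite(lfCase), NA_real_, 0))
  }
  if (priors[2] == 0) {
    return(ifelse(is.infinite(lfControl) & is.infinite(lfCase), NA_real_, 1))
  }
  a <- log(priors[1]) + lfCase
  b <- log(priors[2]) + lfControl
  out <- plogis(a - b)
  out[is.infinite(a) & is.infinite(b) & a < 0 & b < 0] <- NA_real_
  out
}

#' Per-occasion case-membership probability series for a cohort
#'
#' Computes, for every individual and occasion j, the per-draw probability
#' of case-group membership given the marker history accrued through j,
#' pairing the case-group and control-group posterior draws by index (both
#' fits are truncated to the smaller draw count). Fully Bayesian: each
#' draw's own parameters produce its own probability, and the credible
#' interval summarizes that per-draw distribution.
#'
#' @param cohort A [UtilizationCohort-class] (typically held-out
#'   individuals).
#' @param drawsCase,drawsControl [PosteriorDraws-class] fits of the case and
#'   control group models (same spec).
#' @param approach prediction approach (see [predictiveDensity()]).
#' @param priors prior group probabilities `c(case, control)`; the naive
#'   default is 0.5/0.5.
#' @param criLevel credible level for the allocation intervals (default
#'   0.99).
#' @param nodes Gauss-Hermite nodes.
#' @param bEstimator `"mean"` or `"mode"` (see [predictiveDensity()]).
#' @return A [ProbabilitySeries-class].
#' @export
computeProbabilitySeries <- function(cohort, drawsCase, drawsControl,
                                     approach = c("marginal", "conditional", "random_effects"),
                                     priors = c(case = 0.5, control = 0.5),
                                     criLevel = 0.99, nodes = 31L,
                                     bEstimator = c("mean", "mode")) {
  approach <- match.arg(approach)
  bEstimator <- match.arg(bEstimator)
  stopifnot(is(drawsCase, "PosteriorDraws"), is(drawsControl, "PosteriorDraws"))
  spec <- drawsCase@spec
  M <- min(nrow(drawsCase@draws), nrow(drawsControl@draws))
  dc <- drawsCase@draws[seq_len(M), , drop = FALSE]
  d0 <- drawsControl@draws[seq_len(M), , drop = FALSE]
  lfC <- .logDensCore(cohort, dc, spec, approach, nodes, bEstimator)$logf
  lf0 <- .logDensCore(cohort, d0, spec, approach, nodes, bEstimator)$logf
  n <- ncol(cohort); J <- dim(lfC)[2]
  p <- array(.perDrawProb(as.numeric(lfC), as.numeric(lf0), priors),
             dim = dim(lfC))
  alpha <- (1 - criLevel) / 2
  entries <- do.call(rbind, lapply(seq_len(J), function(j) {
    pj <- p[, j, , drop = FALSE]
    pt <- apply(pj, 1, mean, na.rm = TRUE)
    lo <- apply(pj, 1, quantile, probs = alpha, na.rm = TRUE, names = FALSE)
    hi <- apply(pj, 1, quantile, probs = 1 - alpha, na.rm = TRUE, names = FALSE)
    data.frame(
      person_id = cohort$person_id, occasion = j, p_point = pt,
      p_lo = lo, p_hi = hi, n_draws = apply(pj, 1, function(z) sum(!is.na(z)))
    )
  }))
  new("ProbabilitySeries",
    entries = entries[order(entries$person_id, entries$occasion), ],
    perDraw = p, approach = approach,
    priors = c(case = priors[[1]], control = priors[[2]]),
    criLevel = criLevel
  )
}
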