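# Group-specific multivariate generalized linear mixed models fitted by
# MCMC, convergence diagnostics, and penalized expected deviance.
#
# Each marker r of group g follows an exponential-family model with linear
# predictor x' alpha + b, where b ~ N(mu_b, sd_b^2) is an individual-level
# random intercept. Random intercepts are independent across markers
# (diagonal random-effects covariance), so the joint model factorizes over
# markers given the covariates and the markers are sampled independently.
# Priors are weakly informative on the link scale: fixed effects and mu_b ~
# N(0, 10^2), sd_b ~ half-normal(5).

#' Specify a group-specific MGLMM
#'
#' @param model `"full"` (all four utilization markers) or
#'   `"ja_utilization"` (the single any-JA-related-contact marker); or pass
#'   `markers` directly.
#' @param markers character vector of marker names (overrides `model`).
#' @param covariates fixed-effect covariates (default all of male, urban,
#'   age).
#' @return An [MGLMMSpec-class].
#' @export
mglmmSpec <- function(model = c("full", "ja_utilization"),
                      markers = NULL,
                      covariates = c("male", "urban", "age")) {
  if (is.null(markers)) {
    model <- match.arg(model)
    markers <- if (model == "full") MARKERS else "ja_contact"
  }
  new("MGLMMSpec",
    markers = markers,
    families = MARKER_FAMILIES[markers],
    covariates = covariates,
    nMixtureComponents = 1L
  )
}

#' Configure the MCMC sampler
#'
#' Defaults follow the study protocol: 10000 iterations per chain with the
#' first 1000 discarded as burn-in, 1:100 thinning (autocorrelation), and
#' two chains so the Gelman-Rubin diagnostic is computable.
#'
#' @param nIterations,burnIn,thin,nChains,seed,ghNodes see
#'   [McmcConfig-class].
#' @return An [McmcConfig-class].
#' @export
mcmcConfig <- function(nIterations = 10000L, burnIn = 1000L, thin = 100L,
                       nChains = 2L, seed = 1L, ghNodes = 15L) {
  new("McmcConfig",
    nIterations = as.integer(nIterations), burnIn = as.integer(burnIn),
    thin = as.integer(thin), nChains = as.integer(nChains),
    seed = as.integer(seed), ghNodes = as.integer(ghNodes)
  )
}

#' Linear predictor of one observation
#'
#' `x' alpha + b`; the mean response is the inverse link applied to this
#' (logistic for Bernoulli markers, exponential for Poisson markers).
#'
#' @param fixed coefficient vector alpha.
#' @param covariates covariate vector x (same length).
#' @param intercept_b random-intercept value b.
#' @return Numeric scalar.
#' @examples
#' linearPredictor(c(0.5, -1), c(1, 2), 0.25)
#' @export
linearPredictor <- function(fixed, covariates, intercept_b = 0) {
  if (length(fixed) != length(covariates)) {
    stop("coefficient and covariate lengths differ")
  }
  sum(fixed * covariates) + intercept_b
}

# Laplace approximation of the per-marker marginal posterior: mode found by
# BFGS, covariance from the numerical Hessian at the mode. Used to
# initialize the chains and calibrate the proposal covariance.
.laplaceInit <- function(B, Tstat, kIdx, age, fam, gh, init0, active) {
  nlp <- function(par) {
    th <- numeric(5)
    th[active] <- par
    ll <- .mglmm_marg_loglik(B, Tstat, kIdx, age, fam, gh$x, gh$w, th)
    sig <- exp(th[5])
    lp <- -0.5 * sum(th[1:4]^2) / 100 - 0.5 * sig^2 / 25 + th[5]
    v <- -(ll + lp)
    if (!is.finite(v)) 1e10 else v
  }
  opt <- optim(init0[active], nlp, method = "BFGS", hessian = TRUE,
               control = list(maxit = 300))
  mode <- numeric(5)
  mode[active] <- opt$par
  cv <- matrix(0, 5, 5)
  H <- opt$hessian
  ch <- try(chol(H), silent = TRUE)
  cvAct <- if (inherits(ch, "try-error")) {
    diag(0.05^2, sum(active))
  } else {
    chol2inv(ch)
  }
  cv[active, active] <- cvAct
  diag(cv)[!active] <- 1e-12
  list(mode = mode, cov = cv)
}

# moment-based starting values for one marker
.initTheta <- function(y, family) {
  ybar <- mean(y)
  mu0 <- if (family == "bernoulli_logit") {
    qlogis(min(max(ybar, 0.02), 0.98))
  } else {
    log(max(ybar, 0.05))
  }
  c(0, 0, 0, mu0, log(0.5))
}

#' Fit one group's MGLMM by MCMC
#'
#' Runs an adaptive random-walk Metropolis sampler on each marker's
#' 5-parameter posterior (fixed effects for male/urban/age, random-intercept
#' mean and SD), with the random intercept integrated out of the likelihood
#' by Gauss-Hermite quadrature. Markers factorize (diagonal random-effects
#' covariance) and are sampled independently; chains are over-dispersed by
#' jittering the starting values. Reproducible given `mcmc@seed`.
#'
#' @param cohort A [UtilizationCohort-class].
#' @param group `"case"` or `"control"`: which gold-standard group to fit.
#' @param spec An [MGLMMSpec-class].
#' @param mcmc An [McmcConfig-class].
#' @return A [PosteriorDraws-class].
#' @export
fitMglmm <- function(cohort, group = c("case", "control"),
                     spec = mglmmSpec("full"), mcmc = mcmcConfig()) {
  group <- match.arg(group)
  validObject(spec); validObject(mcmc)
  sub <- cohort[, cohort$group == group]
  n <- ncol(sub)
  if (n < 2L) stop("need at least 2 individuals in the ", group, " group")
  cov <- covariateTable(sub)
  age <- occasionGrid()$age
  gh <- pracma::gaussHermite(mcmc@ghNodes)
  nKeep <- (mcmc@nIterations - mcmc@burnIn) %/% mcmc@thin
  active <- c("male", "urban", "age") %in% spec@covariates

  set.seed(mcmc@seed)
  allDraws <- NULL
  chainId <- integer(0)
  iterId <- integer(0)
  accept <- numeric(0)
  for (m in spec@markers) {
    y <- t(measureMatrix(sub, m)) # n x J
    if (all(y == y[1])) stop("marker ", m, " has no nonconstant observation")
    fam <- if (spec@families[[m]] == "bernoulli_logit") 0L else 1L
    B <- rowSums(y)
    Tstat <- as.numeric(y %*% age)
    kIdx <- as.integer(2 * cov$male + cov$urban)
    lap <- .laplaceInit(B, Tstat, kIdx, age, fam, gh,
                        .initTheta(y, spec@families[[m]]), c(active, TRUE, TRUE))
    mDraws <- vector("list", mcmc@nChains)
    mAcc <- numeric(mcmc@nChains)
    chainV <- integer(0); iterV <- integer(0)
    for (ch in seq_len(mcmc@nChains)) {
      # over-disperse later chains around the posterior mode
      jit <- if (ch == 1) 0 else rnorm(5) * 2 * sqrt(pmax(diag(lap$cov), 1e-12))
      init <- lap$mode + jit * c(active, TRUE, TRUE)
      res <- .mh_mglmm_marker(
        B, Tstat, kIdx, age, fam, gh$x, gh$w, init, lap$mode, lap$cov,
        c(active, TRUE, TRUE),
        mcmc@nIterations, mcmc@burnIn, mcmc@thin,
        10, 10, 5, 0.9, 15, 1.1
      )
      mDraws[[ch]] <- res$draws
      mAcc[ch] <- res$acceptance
      chainV <- c(chainV, rep(ch, nrow(res$draws)))
      iterV <- c(iterV, res$iteration)
    }
    d <- do.call(rbind, mDraws)
    colnames(d) <- paste0(m, ".", c("male", "urban", "age", "mu_b", "sd_b"))
    if (is.null(allDraws)) {
      allDraws <- d
      chainId <- chainV
      iterId <- iterV
    } else {
      allDraws <- cbind(allDraws, d)
    }
    accept[m] <- mean(mAcc)
  }

  new("PosteriorDraws",
    group = group, draws = allDraws, chain = chainId,
    iteration = as.integer(iterId), spec = spec, mcmc = mcmc,
    acceptance = accept
  )
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computes the corrected (Brooks-Gelman) PSRF point estimate and its upper
#' 97.5% confidence limit for one parameter from two or more chains of equal
#' length. The operational convergence criterion used throughout the package
#' is upper limit < 1.02.
#'
#' @param chains numeric matrix, iterations x chains (>= 2 chains, >= 10
#'   iterations).
#' @return Named numeric vector `c(point, upper)`.
#' @export
psrf <- function(chains) {
  chains <- as.matrix(chains)
  m <- ncol(chains)
  n <- nrow(chains)
  if (m < 2L) stop("psrf needs at least 2 chains")
  if (n < 10L) stop("psrf needs chains of length >= 10")
  xbar <- colMeans(chains)
  s2 <- apply(chains, 2, var)
  W <- mean(s2)
  B <- n * var(xbar)
  if (B < .Machine$double.eps) {
    # identical chains: no between-chain variation at all
    return(c(point = 1, upper = 1))
  }
  muhat <- mean(xbar)
  varW <- var(s2) / m
  varB <- 2 * B^2 / (m - 1)
  covWB <- (n / m) * (cov(s2, xbar^2) - 2 * muhat * cov(s2, xbar))
  V <- (n - 1) * W / n + (1 + 1 / m) * B / n
  varV <- ((n - 1)^2 * varW + (1 + 1 / m)^2 * varB +
             2 * (n - 1) * (1 + 1 / m) * covWB) / n^2
  if (W < .Machine$double.eps) {
    # identical chains: no between- or within-variation to compare
    return(c(point = 1, upper = 1))
  }
  dfV <- max(2 * V^2 / max(varV, .Machine$double.eps), 1e-8)
  dfAdj <- (dfV + 3) / (dfV + 1)
  Bdf <- m - 1
  Wdf <- 2 * W^2 / max(varW, .Machine$double.eps)
  R2fixed <- (n - 1) / n
  R2random <- (1 + 1 / m) * B / (n * W)
  point <- sqrt(dfAdj * (R2fixed + R2random))
  upper <- sqrt(dfAdj * (R2fixed + qf(0.975, Bdf, Wdf) * R2random))
  c(point = point, upper = upper)
}

#' PSRF table for every parameter of a fit
#'
#' @param draws A [PosteriorDraws-class] fitted with >= 2 chains.
#' @return data.frame with `parameter`, `psrf`, `upper`.
#' @export
psrfTable <- function(draws) {
  stopifnot(is(draws, "PosteriorDraws"))
  chains <- sort(unique(draws@chain))
  if (length(chains) < 2L) stop("psrfTable needs >= 2 chains")
  res <- t(vapply(colnames(draws@draws), function(p) {
    x <- vapply(chains, function(ch) draws@draws[draws@chain == ch, p],
                numeric(sum(draws@chain == chains[1])))
    psrf(x)
  }, numeric(2)))
  data.frame(parameter = rownames(res), psrf = res[, "point"],
             upper = res[, "upper"], row.names = NULL)
}

#' Penalized expected deviance
#'
#' Model-fit criterion for comparing MGLMM specifications on the same data:
#' the expected (posterior mean) deviance of the marginal likelihood -- the
#' random intercept integrated out by quadrature -- plus an optimism
#' penalty. With two or more chains the penalty uses the asymptotic
#' approximation `p_opt = 2 p_D` (twice the effective number of parameters);
#' with a single chain it falls back to a DIC-style penalty `p_D` with a
#' warning. Lower values indicate better fit.
#'
#' @param draws A [PosteriorDraws-class].
#' @param cohort The [UtilizationCohort-class] the model was fitted to (its
#'   matching group subset is used).
#' @param nodes Gauss-Hermite nodes for the deviance integrals.
#' @return Numeric scalar (deviance scale).
#' @export
penalizedExpectedDeviance <- function(draws, cohort, nodes = 31L) {
  stopifnot(is(draws, "PosteriorDraws"))
  sub <- cohort[, cohort$group == draws@group]
  logf <- .logDensCore(sub, draws@draws, draws@spec, approach = "marginal",
                       nodes = nodes)$logf[, N_OCCASIONS, , drop = FALSE]
  devDraw <- -2 * colSums(logf[, 1, ])
  thetaBar <- matrix(colMeans(draws@draws), nrow = 1,
                     dimnames = list(NULL, colnames(draws@draws)))
  logfBar <- .logDensCore(sub, thetaBar, draws@spec, approach = "marginal",
                          nodes = nodes)$logf[, N_OCCASIONS, 1]
  Dbar <- mean(devDraw)
  pD <- Dbar - (-2 * sum(logfBar))
  if (length(unique(draws@chain)) >= 2L) {
    Dbar + 2 * pD
  } else {
    warning("single chain: using DIC-style penalty p_D instead of p_opt")
    Dbar + pD
  }
}
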