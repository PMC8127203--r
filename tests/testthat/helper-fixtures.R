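# Shared fixtures: all synthetic, built in code at test time.

MARKER_SET <- c("ja_contact", "gp_visits", "specialist_visits", "hospitalization")

paramNames <- function(markers) {
  as.vector(t(outer(markers, c("male", "urban", "age", "mu_b", "sd_b"),
                    paste, sep = ".")))
}

# PosteriorDraws built directly from known parameter values (plus optional
# jitter), bypassing MCMC: lets LoDA / classification tests run against
# exact generating truth.
truthDraws <- function(group, effects = generatorConfig()@effects[[group]],
                       markers = "ja_contact", nDraws = 50, jitterSd = 0.02,
                       seed = 1) {
  set.seed(seed)
  cols <- paramNames(markers)
  base <- as.numeric(t(effects[markers, , drop = FALSE]))
  d <- matrix(rep(base, each = nDraws), nrow = nDraws) +
    matrix(rnorm(nDraws * length(base), 0, jitterSd), nrow = nDraws)
  sdCols <- grep("\\.sd_b$", cols)
  d[, sdCols] <- abs(d[, sdCols]) + 1e-6
  colnames(d) <- cols
  new("PosteriorDraws",
    group = group, draws = d,
    chain = rep(1L, nDraws), iteration = seq_len(nDraws),
    spec = mglmmSpec(markers = markers), mcmc = mcmcConfig(seed = seed),
    acceptance = c(ja_contact = 1)
  )
}

# hand-built ProbabilitySeries from an entries table
seriesFromEntries <- function(entries, approach = "random_effects",
                              criLevel = 0.99) {
  new("ProbabilitySeries",
    entries = entries,
    perDraw = array(NA_real_, c(1, 1, 1)),
    approach = approach,
    priors = c(case = 0.5, control = 0.5), criLevel = criLevel
  )
}

oneClaim <- function(person_id = "X", day = 100L, record_type = "physician",
                     provider_class = "GP", setting = "ambulatory",
                     icd_version = 9L, codes = "4650",
                     newborn_flag = FALSE) {
  data.frame(
    person_id = person_id, day = as.integer(day), record_type = record_type,
    provider_class = provider_class, setting = setting,
    icd_version = as.integer(icd_version), codes = I(list(codes)),
    newborn_flag = newborn_flag, stringsAsFactors = FALSE
  )
}

claimTable <- function(...) do.call(rbind, list(...))

# O(n^2) brute-force re-implementation of the deterministic definition,
# independent of the package's scan
bruteForceDeterministic <- function(claims, rule) {
  w <- claims$day >= rule@windowDays[1] & claims$day < rule@windowDays[2]
  claims <- claims[w, , drop = FALSE]
  if (!nrow(claims)) return("control")
  rel <- vapply(seq_len(nrow(claims)), function(i) {
    root <- toupper(substr(trimws(claims$codes[[i]]), 1, 3))
    if (claims$icd_version[i] == 9) any(root %in% rule@codes9)
    else any(root %in% rule@codes10)
  }, logical(1))
  if (any(rel & claims$record_type == "hospital" & !claims$newborn_flag)) {
    return("case")
  }
  days <- claims$day[rel & claims$record_type == "physician"]
  if (length(days) >= 2) {
    for (a in seq_along(days)) {
      for (b in seq_along(days)) {
        gap <- abs(days[b] - days[a])
        if (a != b && gap >= rule@minGapDays && gap <= rule@maxGapDays) {
          return("case")
        }
      }
    }
  }
  "control"
}

# dense-grid trapezoid oracle for the marginal predictive density
# (independent of the Gauss-Hermite code path)
trapezoidMarginal <- function(yv, male, urban, theta, family, jmax,
                              gridN = 1e5) {
  age <- occasionGrid()$age
  b <- seq(-10, 10, length.out = gridN)
  eta0 <- male * theta[1] + urban * theta[2] + age * theta[3]
  vapply(seq_len(jmax), function(j) {
    eta <- outer(eta0[seq_len(j)], b, "+") # j x grid
    ll <- if (family == "bernoulli_logit") {
      colSums(yv[seq_len(j)] * eta - log1p(exp(eta)))
    } else {
      colSums(yv[seq_len(j)] * eta - exp(eta) - lgamma(yv[seq_len(j)] + 1))
    }
    f <- exp(ll) * dnorm(b, theta[4], theta[5])
    log(sum((f[-1] + f[-length(f)]) / 2) * (b[2] - b[1]))
  }, numeric(1))
}

fastMcmc <- function(seed = 1, nIterations = 1500, burnIn = 400, thin = 10,
                     nChains = 2) {
  mcmcConfig(nIterations, burnIn, thin, nChains, seed = seed)
}
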