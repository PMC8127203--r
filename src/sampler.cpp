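#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <map>
using namespace Rcpp;

// MCMC for one marker of the group-specific MGLMM, on the 5-parameter
// marginal posterior theta = (a_male, a_urban, a_age, mu_b, log sd_b) with
// the individual random intercept integrated out by *adaptive*
// Gauss-Hermite quadrature (nodes recentred at each integrand's conditional
// mode and rescaled by its curvature), which keeps the integral accurate
// even when a subject's accumulated counts make the conditional posterior
// of b much narrower than the random-effects distribution.
//
// The design is the fixed one the models use (male/urban constant within
// individual, age varying by occasion), so the per-individual marginal
// log-likelihood depends on the data only through the sufficient statistics
// B_i = sum_j y_ij and k_i (male x urban combo); T_i = sum_j y_ij age_j
// enters linearly outside the integral. Individuals sharing (k, B) share
// the integral, so each likelihood evaluation costs O(#profiles x nodes),
// not O(n x J x nodes).
//
// The kernel mixes an independence proposal (multivariate t centred at the
// Laplace mode with inflated Laplace covariance; near-iid draws because the
// posterior is close to Gaussian at these sample sizes) with random-walk
// moves for robustness. Poisson lgamma(y+1) constants are omitted (they
// cancel in Metropolis ratios; deviance summaries add them back in R).

static const double LOG_2PI = 1.8378770664093453;

struct Model {
  int family; // 0 bernoulli, 1 poisson
  int J, Q;
  std::vector<double> age, ghx, lghw;
  // unique (k, B) profiles with multiplicities
  std::vector<int> profK;
  std::vector<double> profB, profCnt;
  double sumT;        // sum_i T_i
  double sumBk[4];    // sum of B_i within each combo k
};

static inline double softplus(double x) {
  return (x > 0 ? x : 0.0) + std::log1p(std::exp(-std::fabs(x)));
}
static inline double sigmoid(double x) {
  return 1.0 / (1.0 + std::exp(-x));
}

// adaptive-GH log of integral_R exp(b*B - pen(b)) phi(b; mu, sig) db,
// where pen is family-specific; eta_k points to the J baseline linear
// predictors of the profile's combo (bernoulli only), E is e^{base_k} * D
// (poisson only)
static double profileLogInt(const Model &M, double B, const double *etak,
                            double E, double mu, double sig) {
  const double isig2 = 1.0 / (sig * sig);
  double b = mu;
  double d1 = 0, d2 = -1;
  // Newton for the mode of g(b) = b*B - pen(b) - (b-mu)^2/(2 sig^2)
  for (int it = 0; it < 100; ++it) {
    if (M.family == 0) {
      double s1 = 0, s2 = 0;
      for (int j = 0; j < M.J; ++j) {
        double p = sigmoid(etak[j] + b);
        s1 += p;
        s2 += p * (1 - p);
      }
      d1 = B - s1 - (b - mu) * isig2;
      d2 = -s2 - isig2;
    } else {
      double eb = std::exp(std::min(b, 690.0)) * E;
      d1 = B - eb - (b - mu) * isig2;
      d2 = -eb - isig2;
    }
    double step = d1 / d2;
    if (step > 3) step = 3; else if (step < -3) step = -3;
    b -= step;
    if (std::fabs(step) < 1e-10) break;
  }
  const double h = 1.0 / std::sqrt(-d2);
  // g at the transformed nodes
  double mx = -INFINITY;
  std::vector<double> gv(M.Q);
  for (int q = 0; q < M.Q; ++q) {
    double bq = b + M_SQRT2 * h * M.ghx[q];
    double pen;
    if (M.family == 0) {
      pen = 0;
      for (int j = 0; j < M.J; ++j) pen += softplus(etak[j] + bq);
    } else {
      pen = std::exp(std::min(bq, 690.0)) * E;
    }
    double g = bq * B - pen - 0.5 * (bq - mu) * (bq - mu) * isig2 -
               std::log(sig) - 0.5 * LOG_2PI;
    double v = M.lghw[q] + M.ghx[q] * M.ghx[q] + g;
    gv[q] = v;
    if (v > mx) mx = v;
  }
  if (!std::isfinite(mx)) return -INFINITY;
  double s = 0;
  for (int q = 0; q < M.Q; ++q) s += std::exp(gv[q] - mx);
  return 0.5 * std::log(2.0) + std::log(h) + mx + std::log(s);
}

static double margLogLik(const Model &M, double a1, double a2, double a3,
                         double mu, double sig) {
  if (M.profK.empty()) return 0.0;
  double base[4] = {0.0, a2, a1, a1 + a2}; // k = 2*male + urban
  double total = a3 * M.sumT;
  for (int k = 0; k < 4; ++k) total += base[k] * M.sumBk[k];
  double etak[4][64];
  double Ek[4] = {0, 0, 0, 0};
  if (M.family == 0) {
    for (int k = 0; k < 4; ++k)
      for (int j = 0; j < M.J; ++j) etak[k][j] = base[k] + a3 * M.age[j];
  } else {
    double D = 0;
    for (int j = 0; j < M.J; ++j) D += std::exp(a3 * M.age[j]);
    for (int k = 0; k < 4; ++k) Ek[k] = std::exp(base[k]) * D;
  }
  for (size_t p = 0; p < M.profK.size(); ++p) {
    int k = M.profK[p];
    double lI = profileLogInt(M, M.profB[p], etak[k], Ek[k], mu, sig);
    if (!std::isfinite(lI)) return -INFINITY;
    total += M.profCnt[p] * lI;
  }
  return total;
}

static double logPrior(const double *th, double priorSdFixed, double priorSdMu,
                       double halfNormScale) {
  double lp = 0.0;
  for (int d = 0; d < 3; ++d)
    lp += -0.5 * th[d] * th[d] / (priorSdFixed * priorSdFixed);
  lp += -0.5 * th[3] * th[3] / (priorSdMu * priorSdMu);
  double sig = std::exp(th[4]);
  lp += -0.5 * sig * sig / (halfNormScale * halfNormScale) + th[4];
  return lp;
}

// Cholesky of a da x da SPD matrix (row-major, da <= 5)
static bool cholSmall(const double *A, double *L, int da) {
  for (int i = 0; i < da * da; ++i) L[i] = 0.0;
  for (int i = 0; i < da; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i * da + j];
      for (int p = 0; p < j; ++p) s -= L[i * da + p] * L[j * da + p];
      if (i == j) {
        if (s <= 0) return false;
        L[i * da + i] = std::sqrt(s);
      } else {
        L[i * da + j] = s / L[j * da + j];
      }
    }
  }
  return true;
}

static Model buildModel(NumericVector B, NumericVector T, IntegerVector kIdx,
                        NumericVector age, int family, NumericVector ghx,
                        NumericVector ghw) {
  Model M;
  M.family = family;
  M.J = age.size();
  M.Q = ghx.size();
  M.age.assign(age.begin(), age.end());
  M.ghx.assign(ghx.begin(), ghx.end());
  M.lghw.resize(M.Q);
  for (int q = 0; q < M.Q; ++q) M.lghw[q] = std::log(ghw[q]);
  M.sumT = 0;
  for (int k = 0; k < 4; ++k) M.sumBk[k] = 0;
  std::map<std::pair<int, long long>, double> prof;
  const int n = B.size();
  for (int i = 0; i < n; ++i) {
    M.sumT += T[i];
    M.sumBk[kIdx[i]] += B[i];
    prof[{kIdx[i], (long long)std::llround(B[i] * 4)}] += 1.0;
  }
  for (auto &kv : prof) {
    M.profK.push_back(kv.first.first);
    M.profB.push_back(kv.first.second / 4.0);
    M.profCnt.push_back(kv.second);
  }
  return M;
}

// [[Rcpp::export(name = ".mglmm_marg_loglik")]]
double mglmm_marg_loglik(NumericVector B, NumericVector T, IntegerVector kIdx,
                         NumericVector age, int family, NumericVector ghx,
                         NumericVector ghw, NumericVector theta) {
  Model M = buildModel(B, T, kIdx, age, family, ghx, ghw);
  return margLogLik(M, theta[0], theta[1], theta[2], theta[3],
                    std::exp(theta[4]));
}

// [[Rcpp::export(name = ".mh_mglmm_marker")]]
List mh_mglmm_marker(NumericVector B, NumericVector T, IntegerVector kIdx,
                     NumericVector age, int family, NumericVector ghx,
                     NumericVector ghw, NumericVector init,
                     NumericVector lapMode, NumericMatrix lapCov,
                     LogicalVector active, int nIter, int burnIn, int thin,
                     double priorSdFixed, double priorSdMu,
                     double halfNormScale, double pInd, double tDf,
                     double indScale) {
  Model M = buildModel(B, T, kIdx, age, family, ghx, ghw);

  // reduced (active-dimension) parameter space
  int idx[5], da = 0;
  for (int d = 0; d < 5; ++d)
    if (active[d]) idx[da++] = d;

  double th[5] = {0, 0, 0, 0, 0};
  for (int d = 0; d < 5; ++d) th[d] = active[d] ? init[d] : 0.0;

  double covA[25], Lrw[25], Lind[25];
  for (int a = 0; a < da; ++a)
    for (int b = 0; b < da; ++b) covA[a * da + b] = lapCov(idx[a], idx[b]);
  for (int d = 0; d < da; ++d) covA[d * da + d] += 1e-12;
  if (!cholSmall(covA, Lrw, da)) {
    for (int i = 0; i < da * da; ++i) covA[i] = 0.0;
    for (int d = 0; d < da; ++d) covA[d * da + d] = 0.01;
    cholSmall(covA, Lrw, da);
  }
  double logdetInd = 0.0;
  for (int i = 0; i < da * da; ++i) Lind[i] = indScale * Lrw[i];
  for (int d = 0; d < da; ++d) logdetInd += std::log(Lind[d * da + d]);

  // log independence-proposal density (multivariate t, constants dropped)
  auto logq = [&](const double *x) {
    double v[5], w[5];
    for (int a = 0; a < da; ++a) v[a] = x[idx[a]] - lapMode[idx[a]];
    for (int a = 0; a < da; ++a) {
      double s = v[a];
      for (int p = 0; p < a; ++p) s -= Lind[a * da + p] * w[p];
      w[a] = s / Lind[a * da + a];
    }
    double ss = 0;
    for (int a = 0; a < da; ++a) ss += w[a] * w[a];
    return -logdetInd - 0.5 * (tDf + da) * std::log1p(ss / tDf);
  };

  double curLL = margLogLik(M, th[0], th[1], th[2], th[3], std::exp(th[4]));
  double curLP = curLL + logPrior(th, priorSdFixed, priorSdMu, halfNormScale);
  if (!std::isfinite(curLP)) stop("non-finite log-posterior at initial values");
  double curLQ = logq(th);

  const int nKeep = (nIter - burnIn) / thin;
  NumericMatrix out(nKeep, 5);
  IntegerVector keptIter(nKeep);
  double lscale = std::log(2.38 / std::sqrt((double)da));
  const double target = 0.30;
  long nAcc = 0;

  RNGScope scope;
  int kept = 0;
  for (int it = 1; it <= nIter; ++it) {
    double prop[5];
    std::memcpy(prop, th, sizeof(th));
    bool indMove = unif_rand() < pInd;
    double z[5];
    for (int a = 0; a < da; ++a) z[a] = norm_rand();
    if (indMove) {
      double u = Rf_rchisq(tDf) / tDf;
      double sc = 1.0 / std::sqrt(u);
      for (int a = 0; a < da; ++a) {
        double step = 0;
        for (int p = 0; p <= a; ++p) step += Lind[a * da + p] * z[p];
        prop[idx[a]] = lapMode[idx[a]] + sc * step;
      }
    } else {
      double sc = std::exp(lscale);
      for (int a = 0; a < da; ++a) {
        double step = 0;
        for (int p = 0; p <= a; ++p) step += Lrw[a * da + p] * z[p];
        prop[idx[a]] = th[idx[a]] + sc * step;
      }
    }
    double pLL = margLogLik(M, prop[0], prop[1], prop[2], prop[3],
                            std::exp(prop[4]));
    double pLP = pLL + logPrior(prop, priorSdFixed, priorSdMu, halfNormScale);
    double logRatio;
    double pLQ = 0.0;
    if (indMove) {
      pLQ = logq(prop);
      logRatio = (pLP - pLQ) - (curLP - curLQ);
    } else {
      logRatio = pLP - curLP;
    }
    bool acc = std::isfinite(pLP) &&
               (logRatio >= 0 || unif_rand() < std::exp(logRatio));
    if (acc) {
      std::memcpy(th, prop, sizeof(th));
      curLP = pLP;
      curLQ = indMove ? pLQ : logq(th);
      ++nAcc;
    }
    if (!indMove && it <= burnIn) {
      double gam = 1.0 / std::pow(it + 1.0, 0.6);
      lscale += gam * ((acc ? 1.0 : 0.0) - target);
    }
    if (it > burnIn && (it - burnIn) % thin == 0) {
      out(kept, 0) = th[0];
      out(kept, 1) = th[1];
      out(kept, 2) = th[2];
      out(kept, 3) = th[3];
      out(kept, 4) = std::exp(th[4]);
      keptIter[kept] = it - burnIn;
      ++kept;
    }
  }

  return List::create(
    _["draws"] = out,
    _["iteration"] = keptIter,
    _["acceptance"] = (double)nAcc / nIter
  );
}
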