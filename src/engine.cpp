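#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Annual update loop for the fire--beetle stand model.
//
// State per year n: juvenile age vector j (K classes), susceptible S,
// infested I with two lag years (red/grey snags), burned F, and the fuel
// deficit D_n = sum_i F_i exp(-kappa (n - i)) maintained recursively
// (D_{n+1} = D_n * exp(-kappa) + F_{n+1}), so fire severity P_n = T - D_n
// needs no history scan.  All populations are continuous tree-equivalents.
//
// Noise: per year, xi (infestation) is drawn first, then gamma (fire); the
// same gamma realization enters the S loss and the F gain, so fire noise is
// a pure S -> F transfer.  Draws come from R's RNG so set.seed() governs
// reproducibility.
//
// policy_mode: 0 none, 1 FTP (thinnings recycled to seedlings), 2 CBP
// (thinnings diverted to the burned compartment).  On application years
// (n %% period == 0, n counted from the start of the run) the juvenile
// vector is advanced first; then the m most-populated classes of the
// advanced vector (ties to the oldest class) are each thinned by the
// fraction tau and the removed mass is added to the seedling class (FTP)
// or to F (CBP).  The seedling class itself has no thinning equation, so
// selecting it treats nothing (it only receives).

static int select_m_largest(const std::vector<double>& j, int m,
                            std::vector<int>& out) {
  // indices (0-based) of the m largest entries, ties broken to larger index
  int K = (int) j.size();
  out.clear();
  std::vector<int> idx(K);
  for (int k = 0; k < K; ++k) idx[k] = k;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (j[a] != j[b]) return j[a] > j[b];
    return a > b;
  });
  for (int k = 0; k < m; ++k) out.push_back(idx[k]);
  return m;
}

// [[Rcpp::export]]
List sim_engine(int n_years, NumericVector j0, double S0, double I0,
                double I_lag1, double I_lag2, double F0,
                double r1, double beta1, double d,
                double alpha1, double alpha2, double kappa,
                double T, double sigma_F, double sigma_I,
                int policy_mode, double tau, int m, int period,
                bool strict_noise_balance, bool keep_ages) {
  const int K = j0.size();
  std::vector<double> j(j0.begin(), j0.end()), jn(K);
  double S = S0, I = I0, il1 = I_lag1, il2 = I_lag2, F = F0;
  double fuel = F0; // history starts with the year-0 burn count
  const double ek = std::exp(-kappa);

  NumericVector oJ(n_years), oS(n_years), oI(n_years), oF(n_years),
      oP(n_years);
  NumericMatrix ages = keep_ages ? NumericMatrix(n_years, K)
                                 : NumericMatrix(0, 0);
  std::vector<int> treat;
  long n_clamped = 0;

  RNGScope scope;
  for (int n = 0; n < n_years; ++n) {
    double P = T - fuel;
    if (P < 0) P = 0;

    double xi = norm_rand();
    double gamma = norm_rand();

    bool applying = policy_mode != 0 && tau > 0 && m > 0 &&
                    (n % period == 0);

    double J = 0, burn_sum = 0;
    for (int k = 0; k < K; ++k) J += j[k];
    for (int k = 0; k < K - 1; ++k) burn_sum += j[k];

    const double g = (1 - d) - (alpha1 / T) * P; // survival x fire advance

    // recruitment into the youngest class: dead juveniles, grey snags,
    // last year's burns; then age-class advance with fire loss
    jn[0] = d * J + il2 + F;
    for (int k = 1; k < K; ++k) jn[k] = g * j[k - 1];

    double rem = 0; // mass removed from the treated classes
    if (applying) {
      select_m_largest(jn, m, treat);
      for (int t = 0; t < (int) treat.size(); ++t) {
        int kp = treat[t];
        if (kp == 0) continue; // seedling class only receives
        rem += tau * jn[kp];
        jn[kp] *= (1 - tau);
      }
      if (policy_mode == 1) jn[0] += rem + sigma_F * gamma;
    }

    double mature_in = S + (1 - d) * j[K - 1];
    double Snew = mature_in - (I + (alpha2 / T) * P * I) -
                  (alpha2 / T) * P * mature_in - sigma_F * gamma;
    if (strict_noise_balance) Snew -= sigma_I * xi;

    double Inew = r1 * I * std::exp(-beta1 * (T - Snew)) -
                  (alpha2 / T) * P * I + sigma_I * xi;

    double Fnew = P * ((alpha1 / T) * burn_sum +
                       (alpha2 / T) * mature_in + (alpha2 / T) * I) +
                  sigma_F * gamma;
    if (applying && policy_mode == 2) Fnew += rem;

    // clamp negative excursions from noise at zero
    for (int k = 0; k < K; ++k)
      if (jn[k] < 0) { jn[k] = 0; ++n_clamped; }
    if (Snew < 0) { Snew = 0; ++n_clamped; }
    if (Inew < 0) { Inew = 0; ++n_clamped; }
    if (Fnew < 0) { Fnew = 0; ++n_clamped; }

    if (!std::isfinite(Snew)) stop("non-finite susceptible population at year %d", n + 1);
    if (!std::isfinite(Inew)) stop("non-finite infested population at year %d", n + 1);
    if (!std::isfinite(Fnew)) stop("non-finite burned population at year %d", n + 1);
    for (int k = 0; k < K; ++k)
      if (!std::isfinite(jn[k])) stop("non-finite juvenile class at year %d", n + 1);

    il2 = il1;
    il1 = I;
    I = Inew;
    S = Snew;
    F = Fnew;
    std::copy(jn.begin(), jn.end(), j.begin());
    fuel = fuel * ek + F;

    double Jnew = 0;
    for (int k = 0; k < K; ++k) Jnew += j[k];
    double Pnew = T - fuel;
    if (Pnew < 0) Pnew = 0;

    oJ[n] = Jnew;
    oS[n] = S;
    oI[n] = I;
    oF[n] = F;
    oP[n] = Pnew;
    if (keep_ages)
      for (int k = 0; k < K; ++k) ages(n, k) = j[k];
  }

  return List::create(_["J"] = oJ, _["S"] = oS, _["I"] = oI, _["F"] = oF,
                      _["P"] = oP, _["ages"] = ages,
                      _["I_lag1"] = il1, _["I_lag2"] = il2,
                      _["fuel"] = fuel, _["n_clamped"] = (double) n_clamped);
}
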