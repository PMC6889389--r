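#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One extended-Kalman-filter pass over a patient series for the TCM /
// TCM-CRP state-space models.  The sub-step geometry and BSA-normalised
// dose inputs are precomputed in R (they do not depend on the parameters),
// so a likelihood evaluation is a single call into this routine.
//
// theta layout (natural scale):
//   0 eTgn, 1 h, 2 kPlMax, 3 kL, 4 sigmaL0, 5 gamma, 6 kMe, 7 rho,
//   8 sigmaLeuk, 9 thetaOu, 10 sigmaOu, 11 betaCrp, 12 sigmaCrp
//
// crp = false: 2-state (M, L); crp = true: 3-state (M, L, V).
// lobs / vobs hold the observations at the K time points; NA marks a
// missing (or deliberately masked) component, and such components are
// skipped in the update while the predictive moments are still emitted.
//
// Covariance updates use the Joseph form plus symmetrisation; tiny negative
// diagonal entries from round-off are floored at zero and counted in
// `repairs`.

// [[Rcpp::export]]
List ekf_filter_cpp(NumericVector theta, bool crp,
                    NumericVector subdt, NumericVector subdose,
                    IntegerVector nsub,
                    NumericVector lobs, NumericVector vobs,
                    double l1, double l1var) {
  const double etgn = theta[0], h = theta[1], kpl = theta[2], kl = theta[3],
               sig0 = theta[4], g = theta[5], kme = theta[6], rho = theta[7],
               sleuk = theta[8];
  const double thou = theta[9], sou = theta[10], bcrp = theta[11],
               scrp = theta[12];
  const int K = lobs.size();
  const int d = crp ? 3 : 2;
  const double prg = std::pow(rho, g);

  double m[3] = {0.0, l1, 0.0};
  double P[3][3] = {{0.0}};
  P[1][1] = l1var;
  if (crp) P[2][2] = sou * sou / (2.0 * thou);

  double ll = 0.0;
  int repairs = 0;
  bool ok = true;
  NumericMatrix predMean(K, 2), predVar(K, 2), filtMean(K, 3);
  double A[3][3], FP[3][3], Fm[3][3];

  int pos = 0;
  for (int k = 0; k < K; ++k) {
    if (k > 0) {
      const int n = nsub[k - 1];
      for (int s = 0; s < n; ++s) {
        const double dt = subdt[pos], dd = subdose[pos];
        ++pos;
        const double a = (dd > 0.0) ? etgn * dd / (dd + h) : 0.0;
        const double phiM = std::exp(-kme * dt);
        const double eL = std::exp(g * m[1]);
        double hill, dhill;
        if (!std::isfinite(eL) || eL > 1e290) {
          hill = 0.0;
          dhill = 0.0;
        } else {
          const double den = prg + eL;
          hill = kpl * prg / den;
          dhill = -kpl * prg * g * eL / (den * den);
        }
        double sigL = sig0;
        double phiV = 1.0, qV = 0.0;
        if (crp) {
          sigL = sig0 * std::exp(bcrp * m[2]);
          phiV = std::exp(-thou * dt);
          qV = sou * sou / (2.0 * thou) * (1.0 - phiV * phiV);
        }
        // mean step (uses the pre-step mean of M in the L drift)
        const double mM = (m[0] - a) * phiM + a;
        const double mL = m[1] + dt * (hill - m[0] - kl);
        // F = [[phiM,0,0],[-dt,JLL,0],[0,0,phiV]]
        const double JLL = 1.0 + dt * dhill;
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) Fm[i][j] = 0.0;
        Fm[0][0] = phiM;
        Fm[1][0] = -dt;
        Fm[1][1] = JLL;
        Fm[2][2] = phiV;
        for (int i = 0; i < d; ++i)
          for (int j = 0; j < d; ++j) {
            double acc = 0.0;
            for (int r = 0; r < d; ++r) acc += Fm[i][r] * P[r][j];
            FP[i][j] = acc;
          }
        for (int i = 0; i < d; ++i)
          for (int j = 0; j < d; ++j) {
            double acc = 0.0;
            for (int r = 0; r < d; ++r) acc += FP[i][r] * Fm[j][r];
            P[i][j] = acc;
          }
        P[1][1] += sigL * sigL * dt;
        if (crp) P[2][2] += qV;
        for (int i = 0; i < d; ++i)
          for (int j = i + 1; j < d; ++j) {
            const double sym = 0.5 * (P[i][j] + P[j][i]);
            P[i][j] = sym;
            P[j][i] = sym;
          }
        m[0] = mM;
        m[1] = mL;
        if (crp) m[2] *= phiV;
        if (!std::isfinite(m[1]) || !std::isfinite(P[1][1])) {
          ok = false;
          break;
        }
      }
      if (!ok) break;
    }
    // predictive (pre-update) moments at this observation time
    predMean(k, 0) = m[1];
    predVar(k, 0) = P[1][1];
    predMean(k, 1) = crp ? m[2] : NA_REAL;
    predVar(k, 1) = crp ? P[2][2] : NA_REAL;
    // sequential scalar updates (diagonal measurement covariance)
    for (int c = 0; c < 2; ++c) {
      const int j = (c == 0) ? 1 : 2;
      if (c == 1 && !crp) continue;
      const double y = (c == 0) ? lobs[k] : vobs[k];
      if (NumericVector::is_na(y)) continue;
      const double r = (c == 0) ? sleuk : scrp;
      double Sd = P[j][j] + r * r;
      if (!(Sd > 0.0) || !std::isfinite(Sd)) {
        ok = false;
        break;
      }
      const double innov = y - m[j];
      ll += -0.5 * (std::log(2.0 * M_PI * Sd) + innov * innov / Sd);
      double Kv[3];
      for (int i = 0; i < d; ++i) Kv[i] = P[i][j] / Sd;
      for (int i = 0; i < d; ++i) m[i] += Kv[i] * innov;
      // Joseph form: P' = (I - K e_j') P (I - e_j K') + r^2 K K'
      for (int i = 0; i < d; ++i)
        for (int l2 = 0; l2 < d; ++l2)
          A[i][l2] = P[i][l2] - Kv[i] * P[j][l2];
      for (int i = 0; i < d; ++i)
        for (int l2 = 0; l2 < d; ++l2)
          P[i][l2] = A[i][l2] - A[i][j] * Kv[l2] + r * r * Kv[i] * Kv[l2];
      for (int i = 0; i < d; ++i)
        for (int l2 = i + 1; l2 < d; ++l2) {
          const double sym = 0.5 * (P[i][l2] + P[l2][i]);
          P[i][l2] = sym;
          P[l2][i] = sym;
        }
      for (int i = 0; i < d; ++i)
        if (P[i][i] < 0.0) {
          P[i][i] = 0.0;
          ++repairs;
        }
    }
    if (!ok) break;
    filtMean(k, 0) = m[0];
    filtMean(k, 1) = m[1];
    filtMean(k, 2) = crp ? m[2] : NA_REAL;
    if (!std::isfinite(ll)) {
      ok = false;
      break;
    }
  }
  if (!ok) ll = R_NegInf;
  NumericMatrix Pout(d, d);
  for (int i = 0; i < d; ++i)
    for (int j = 0; j < d; ++j) Pout(i, j) = P[i][j];
  return List::create(_["loglik"] = ll, _["predMean"] = predMean,
                      _["predVar"] = predVar, _["filtMean"] = filtMean,
                      _["finalCov"] = Pout, _["repairs"] = repairs,
                      _["ok"] = ok);
}
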