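// Expected time-with-k-lineages under a piecewise-constant size history.
//
// In coalescent-rescaled time tau (dtau = dt / 2N(t)) the ancestral
// lineage count of a sample of n is a pure death chain with rates
// b_k = k(k-1)/2.  The expected SFS needs E[S_k], the expected number of
// generations during which exactly k ancestral lineages exist.  We
// integrate the chain's forward equation with a Crank-Nicolson scheme
// (triangular, unconditionally stable; step bounded by 0.5/b_active for
// accuracy) and accumulate E[S_k] = int 2N(t(tau)) P_k(tau) dtau.  After
// the last epoch boundary the chain lives in a constant-size world where
// the integral has the closed form 2N * P[A >= k] / b_k.
//
// This avoids the catastrophic cancellation of the classical
// alternating-sum formula for P_k(tau), which fails in double precision
// for n larger than about 50.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// t_bounds: epoch start times in generations, increasing, t_bounds[0] = 0.
// N_epoch: diploid size in each epoch; the last epoch extends to infinity.
// Returns E[S_k] for k = 2..n (element k-2), in generations.
// [[Rcpp::export]]
NumericVector cpp_esfs_sk(int n, NumericVector t_bounds,
                          NumericVector N_epoch) {
  if (n < 2) stop("n must be >= 2");
  int J = N_epoch.size();
  if (t_bounds.size() != J) stop("t_bounds and N_epoch must match");
  std::vector<double> b(n + 2, 0.0);
  for (int k = 2; k <= n; ++k) b[k] = k * (k - 1.0) / 2.0;

  std::vector<double> P(n + 2, 0.0), Pn(n + 2, 0.0), S(n + 1, 0.0);
  P[n] = 1.0;
  int kmax = n;

  for (int j = 0; j < J - 1; ++j) {
    double N = N_epoch[j];
    if (N <= 0) stop("non-positive population size in epoch");
    double span = (t_bounds[j + 1] - t_bounds[j]) / (2.0 * N);
    if (span < 0) stop("t_bounds must be increasing");
    double left = span;
    while (left > 1e-300 && kmax >= 2) {
      double h = 0.5 / b[kmax];
      if (h > left) h = left;
      left -= h;
      // Crank-Nicolson step, solved from kmax down
      for (int k = kmax; k >= 1; --k) {
        double up = (k < kmax) ? b[k + 1] * P[k + 1] : 0.0;
        double upn = (k < kmax) ? b[k + 1] * Pn[k + 1] : 0.0;
        double rhs = P[k] + 0.5 * h * (up - b[k] * P[k]);
        Pn[k] = (rhs + 0.5 * h * upn) / (1.0 + 0.5 * h * b[k]);
        if (Pn[k] < 0) Pn[k] = 0;
      }
      for (int k = 1; k <= kmax; ++k) {
        if (k >= 2) S[k] += 2.0 * N * h * 0.5 * (P[k] + Pn[k]);
        P[k] = Pn[k];
      }
      while (kmax > 1 && P[kmax] < 1e-15) { P[kmax] = 0.0; --kmax; }
    }
    if (kmax < 2) break;
  }
  // closed-form tail in the final (infinite) epoch
  if (kmax >= 2) {
    double N = N_epoch[J - 1];
    double q = 0.0;  // P[A >= k], accumulated from the top
    for (int k = kmax; k >= 2; --k) {
      q += P[k];
      S[k] += 2.0 * N * q / b[k];
    }
  }
  NumericVector out(n - 1);
  for (int k = 2; k <= n; ++k) out[k - 2] = S[k];
  return out;
}
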