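#include <Rcpp.h>
using namespace Rcpp;

// Heat-bath Gibbs sweeps over candidate-link indicators.
//
// The cascade likelihood factorises over informed nodes; flipping candidate
// k = (u, v) only touches node v's terms in cascades where t_u < t_v.  For
// each candidate the eligible (cascade) entries are stored CSR-style with
// the link's hazard lambda_uv(d_uv); the per-(node, cascade) hazard sums A
// are maintained incrementally.  The add-direction gain is
//   delta = sum_c log(1 + lambda/A_c) + sum_c log S_uv(d_c)
// (the survival part is constant per candidate and passed pre-summed), and
// the full conditional is P(present | rest) = 1 / (1 + exp(-delta)).
// A candidate whose removal would leave some node parentless gets
// delta = +Inf, i.e. it is forced present — the repair rule for -Inf states.
//
// [[Rcpp::export]]
List cpp_gibbs(int K, IntegerVector ptr, IntegerVector casc,
               NumericVector lam, IntegerVector vnode,
               NumericVector logS_sum, int n, int C,
               IntegerVector order, int burn_in, int lag, int M,
               bool keep_samples) {
  std::vector<double> A((size_t)n * C, 0.0);
  std::vector<int> present(K, 1);
  std::vector<double> counts(K, 0.0);
  IntegerMatrix samples(keep_samples ? K : 0, keep_samples ? M : 0);

  // initial graph: all candidates present
  for (int k = 0; k < K; ++k)
    for (int i = ptr[k]; i < ptr[k + 1]; ++i)
      A[(size_t)vnode[k] * C + casc[i]] += lam[i];

  const double tiny = 1e-300;
  int total_sweeps = burn_in + lag * M;
  int retained = 0;

  for (int s = 1; s <= total_sweeps && retained < M; ++s) {
    for (int kk = 0; kk < K; ++kk) {
      int k = order[kk];
      size_t vbase = (size_t)vnode[k] * C;
      double delta = logS_sum[k];
      bool pres = present[k] != 0;
      for (int i = ptr[k]; i < ptr[k + 1]; ++i) {
        double l = lam[i];
        if (l <= 0.0) continue;
        double a = A[vbase + casc[i]];
        if (pres) {
          double a0 = a - l;
          if (a0 < tiny) { delta = R_PosInf; break; }
          delta += std::log(a / a0);
        } else {
          if (a < tiny) { delta = R_PosInf; break; }
          delta += std::log1p(l / a);
        }
      }
      bool newpres;
      double urand = unif_rand();  // always consume one draw: reproducibility
      if (delta == R_PosInf) {
        newpres = true;
      } else {
        double p = 1.0 / (1.0 + std::exp(-delta));
        newpres = urand < p;
      }
      if (newpres != pres) {
        for (int i = ptr[k]; i < ptr[k + 1]; ++i) {
          double &a = A[vbase + casc[i]];
          a += newpres ? lam[i] : -lam[i];
          if (a < 0.0) a = 0.0;
        }
        present[k] = newpres ? 1 : 0;
      }
    }
    // periodic exact refresh of A against floating-point drift
    if (s % 64 == 0) {
      std::fill(A.begin(), A.end(), 0.0);
      for (int k = 0; k < K; ++k)
        if (present[k])
          for (int i = ptr[k]; i < ptr[k + 1]; ++i)
            A[(size_t)vnode[k] * C + casc[i]] += lam[i];
    }
    if (s > burn_in && (s - burn_in) % lag == 0) {
      for (int k = 0; k < K; ++k) {
        counts[k] += present[k];
        if (keep_samples) samples(k, retained) = present[k];
      }
      ++retained;
    }
  }

  NumericVector freq(K);
  for (int k = 0; k < K; ++k) freq[k] = counts[k] / retained;
  return List::create(_["freq"] = freq, _["samples"] = samples);
}
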