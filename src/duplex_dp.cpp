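#include <Rcpp.h>
using namespace Rcpp;

// Inside-outside partition function over all non-crossing, intermolecular-only
// pairings of two strands. Strand b must be supplied 3'->5' (reversed) by the
// caller so that admissible pairings are strictly increasing in both indices.
//
// A structure is a chain of pairs (i1,k1) < (i2,k2) < ... (strict in both
// coordinates). Its Boltzmann weight is the product of per-pair weights w[i,k]
// and, for each internal region between consecutive pairs leaving da and dk
// nucleotides unpaired on the two strands, a factor
//   gl^(da+dk) * (gb if exactly one of da,dk is zero)
// i.e. a per-nucleotide loop factor plus a bulge surcharge when the region is
// one-sided. Terminal unpaired runs are free.
//
// L[i,k]: summed weight of chains ending at (i,k); R[i,k]: chains starting at
// (i,k); Z = 1 + sum L (the empty structure has weight 1). The probability
// that pair (i,k) occurs is L*R/(w*Z).
// [[Rcpp::export]]
List duplex_dp_cpp(NumericMatrix w, double gl, double gb) {
  int n = w.nrow(), m = w.ncol();
  NumericMatrix L(n, m), R(n, m), P(n, m);
  int dmax = (n > m ? n : m);
  std::vector<double> glp(dmax + 1);
  glp[0] = 1.0;
  for (int d = 1; d <= dmax; ++d) glp[d] = glp[d - 1] * gl;
  auto region = [&](int da, int dk) {
    double f = glp[da] * glp[dk];
    if ((da == 0) != (dk == 0)) f *= gb;
    return f;
  };

  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < m; ++k) {
      if (w(i, k) == 0.0) continue;
      double acc = 1.0;
      for (int ip = 0; ip < i; ++ip)
        for (int kp = 0; kp < k; ++kp)
          acc += L(ip, kp) * region(i - ip - 1, k - kp - 1);
      L(i, k) = w(i, k) * acc;
    }
  }
  for (int i = n - 1; i >= 0; --i) {
    for (int k = m - 1; k >= 0; --k) {
      if (w(i, k) == 0.0) continue;
      double acc = 1.0;
      for (int ip = i + 1; ip < n; ++ip)
        for (int kp = k + 1; kp < m; ++kp)
          acc += R(ip, kp) * region(ip - i - 1, kp - k - 1);
      R(i, k) = w(i, k) * acc;
    }
  }
  double Z = 1.0;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < m; ++k) Z += L(i, k);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < m; ++k)
      if (w(i, k) > 0.0) P(i, k) = L(i, k) * R(i, k) / (w(i, k) * Z);

  return List::create(_["p"] = P, _["Z"] = Z);
}
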