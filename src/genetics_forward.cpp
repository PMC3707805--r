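#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Forward-time allele-frequency process on a lattice of demes.
//
// The demographic history (deme sizes, resident fractions, per-neighbor
// outflow contributions, which cells may be settled at each step) is
// precomputed and deterministic; this kernel only adds genetic drift:
// at every step each occupied cell's allele frequencies are redrawn
// binomially from its migration-weighted parental pool.
//
// freq: nCells x nSnps matrix, NA for uncolonized cells; a drifted copy
//   at present is returned. sizes: (T+1) x nCells post-step deme sizes.
//   resident, outContrib: T x nCells (outContrib = emigrants per
//   receiving neighbor). allowed: T x nCells (0/1). nbr: nCells x 4
//   one-based neighbor indices, 0 = none.
// [[Rcpp::export(name = ".geneticsForward")]]
NumericMatrix genetics_forward(NumericMatrix freq,
                               NumericMatrix sizes,
                               NumericMatrix resident,
                               NumericMatrix outContrib,
                               IntegerMatrix allowed,
                               IntegerMatrix nbr) {
  const int C = freq.nrow();
  const int S = freq.ncol();
  const int T = resident.nrow();

  // snp-major working buffers: column c holds cell c's S frequencies
  std::vector<double> cur((size_t)C * S), nxt((size_t)C * S);
  std::vector<char> occ(C), occNext(C);
  for (int c = 0; c < C; ++c) {
    occ[c] = !ISNA(freq(c, 0));
    double *dst = &cur[(size_t)c * S];
    for (int s = 0; s < S; ++s) dst[s] = freq(c, s);
  }

  for (int t = 0; t < T; ++t) {
    for (int c = 0; c < C; ++c) {
      double newS = sizes(t + 1, c);
      double *dst = &nxt[(size_t)c * S];
      if (newS <= 0.0) { occNext[c] = 0; continue; }
      double wRes = occ[c] ? resident(t, c) : 0.0;
      const double *src[5];
      double w[5];
      int nIn = 0;
      if (wRes > 0.0) { src[nIn] = &cur[(size_t)c * S]; w[nIn++] = wRes; }
      if (allowed(t, c) != 0) {
        for (int k = 0; k < 4; ++k) {
          int b = nbr(c, k) - 1;
          if (b < 0 || !occ[b]) continue;
          double wb = outContrib(t, b);
          if (wb > 0.0) { src[nIn] = &cur[(size_t)b * S]; w[nIn++] = wb; }
        }
      }
      double den = 0.0;
      for (int k = 0; k < nIn; ++k) den += w[k];
      if (den <= 0.0) {
        // occupied with no sourced gene pool (e.g. an injected founding
        // deme): carry the previous frequencies forward unchanged
        if (occ[c]) {
          const double *prev = &cur[(size_t)c * S];
          for (int s = 0; s < S; ++s) dst[s] = prev[s];
          occNext[c] = 1;
        } else occNext[c] = 0;
        continue;
      }
      for (int k = 0; k < nIn; ++k) w[k] /= den;
      double n2 = 2.0 * std::max(1.0, std::floor(newS + 0.5));
      for (int s = 0; s < S; ++s) {
        double p = 0.0;
        for (int k = 0; k < nIn; ++k) p += w[k] * src[k][s];
        if (p <= 0.0) { dst[s] = 0.0; continue; }
        if (p >= 1.0) { dst[s] = 1.0; continue; }
        dst[s] = R::rbinom(n2, p) / n2;
      }
      occNext[c] = 1;
    }
    cur.swap(nxt);
    occ.swap(occNext);
  }

  NumericMatrix out(C, S);
  for (int c = 0; c < C; ++c) {
    const double *colc = &cur[(size_t)c * S];
    for (int s = 0; s < S; ++s)
      out(c, s) = occ[c] ? colc[s] : NA_REAL;
  }
  return out;
}
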