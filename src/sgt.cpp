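// Trinucleotide tokenizer and sequence-graph-transform encoder.
//
// The pattern matrix entry (u, v) is the mean, over all ordered occurrence
// pairs (u at position l, v at position m, l < m), of exp(-kappa * (m - l)),
// with positions the 1-based start offsets of the trinucleotides in the
// original sequence.  The streaming pass keeps, per symbol u, the decayed
// sum A[u] = sum_l exp(-kappa * (current - l)) and the occurrence count
// n[u]; decaying A by exp(-kappa * delta) between tokens keeps every
// intermediate in [0, T] and avoids the overflow of the textbook
// exp(+kappa*l) / exp(-kappa*m) factorisation.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
using namespace Rcpp;

static const int NSYM = 64;

// -1 = invalid trinucleotide base (skipped window), -2 = not IUPAC (error)
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  case 'U': case 'u':
  case 'N': case 'n':
  case 'R': case 'r': case 'Y': case 'y': case 'S': case 's':
  case 'W': case 'w': case 'K': case 'k': case 'M': case 'm':
  case 'B': case 'b': case 'D': case 'd': case 'H': case 'h':
  case 'V': case 'v':
    return -1;
  default:
    return -2;
  }
}

// [[Rcpp::export(name = ".tokenize_cpp")]]
List tokenize_cpp(std::string bases) {
  const int n = (int) bases.size();
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) {
    code[i] = base_code(bases[i]);
    if (code[i] == -2)
      stop("non-IUPAC character '%s' at position %d",
           std::string(1, bases[i]).c_str(), i + 1);
  }
  std::vector<int> sym, pos;
  for (int i = 0; i + 2 < n; ++i) {
    if (code[i] < 0 || code[i + 1] < 0 || code[i + 2] < 0) continue;
    sym.push_back(code[i] * 16 + code[i + 1] * 4 + code[i + 2]);
    pos.push_back(i + 1);
  }
  return List::create(_["symbols"]   = wrap(sym),
                      _["positions"] = wrap(pos),
                      _["sourceLength"] = n);
}

// [[Rcpp::export(name = ".sgt_matrix_cpp")]]
NumericMatrix sgt_matrix_cpp(IntegerVector symbols, IntegerVector positions,
                             double kappa) {
  if (!(kappa > 0)) stop("'kappa' must be > 0");
  const int T = symbols.size();
  NumericMatrix out(NSYM, NSYM);
  if (T < 2) return out;

  double A[NSYM];            // decayed exp sums, referenced to current pos
  double cnt[NSYM];          // occurrence counts per symbol
  std::memset(A, 0, sizeof(A));
  std::memset(cnt, 0, sizeof(cnt));
  double wsum[NSYM][NSYM];   // sum of exp(-kappa * (m - l)) per ordered pair
  double npair[NSYM][NSYM];  // |Lambda_uv|
  std::memset(wsum, 0, sizeof(wsum));
  std::memset(npair, 0, sizeof(npair));

  int prev_pos = positions[0];
  for (int t = 0; t < T; ++t) {
    const int v = symbols[t], m = positions[t];
    if (t > 0) {
      const double decay = std::exp(-kappa * (double)(m - prev_pos));
      for (int u = 0; u < NSYM; ++u) A[u] *= decay;
      for (int u = 0; u < NSYM; ++u) {
        if (cnt[u] > 0) {
          wsum[u][v]  += A[u];
          npair[u][v] += cnt[u];
        }
      }
    }
    A[v] += 1.0;  // exp(-kappa * 0), decays on subsequent tokens
    cnt[v] += 1.0;
    prev_pos = m;
  }
  for (int u = 0; u < NSYM; ++u)
    for (int v = 0; v < NSYM; ++v)
      if (npair[u][v] > 0) out(u, v) = wsum[u][v] / npair[u][v];
  return out;
}
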