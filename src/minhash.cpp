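#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Eq.-exact MinHash kernel. Components are
//   min_v ((a_i * v + b_i) mod p) mod (2^32 - 1),  p = 2^61 - 1.
// a_i, v < 2^32 so the product needs up to 64 bits and the sum one more;
// unsigned __int128 keeps the arithmetic exact before the reductions.
// Inputs/outputs travel as doubles: R integers are 32-bit signed and cannot
// hold values up to 2^32 - 1, while doubles are exact through 2^53.

static const uint64_t P61 = (1ULL << 61) - 1;
static const uint64_t M32 = 4294967295ULL; // 2^32 - 1

// [[Rcpp::export]]
NumericVector minhash_cpp(NumericVector values, NumericVector a, NumericVector b) {
  const int k = a.size();
  const int n = values.size();
  if (b.size() != k) stop("a and b must have equal length");
  if (n == 0) stop("MinHash of the empty set is undefined");

  std::vector<uint64_t> v(n);
  for (int j = 0; j < n; ++j) v[j] = (uint64_t) values[j];

  NumericVector out(k);
  for (int i = 0; i < k; ++i) {
    const uint64_t ai = (uint64_t) a[i];
    const uint64_t bi = (uint64_t) b[i];
    uint64_t best = UINT64_MAX;
    for (int j = 0; j < n; ++j) {
      unsigned __int128 t = (unsigned __int128) ai * v[j] + bi;
      uint64_t h = (uint64_t)(t % P61) % M32;
      if (h < best) best = h;
    }
    out[i] = (double) best;
  }
  return out;
}

// Batched variant: one call for a list of hash sets, returning a k x n
// matrix. Avoids per-set R call overhead when encoding whole collections.
// [[Rcpp::export]]
NumericMatrix minhash_many_cpp(List value_sets, NumericVector a, NumericVector b) {
  const int k = a.size();
  const int n = value_sets.size();
  NumericMatrix out(k, n);
  for (int s = 0; s < n; ++s) {
    NumericVector vs = value_sets[s];
    NumericVector col = minhash_cpp(vs, a, b);
    for (int i = 0; i < k; ++i) out(i, s) = col[i];
  }
  return out;
}
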