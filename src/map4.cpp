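#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Mersenne prime used by the universal hash family; values are folded to
// 32 bits so signatures are exactly representable as R doubles.
static const uint64_t MERSENNE_P = (1ULL << 61) - 1;
static const uint64_t HASH_MASK = 0xFFFFFFFFULL;

// MinHash signatures for a list of token-hash sets.
// token_sets: list of numeric vectors of 32-bit token hashes (as doubles);
// a, b: hash-family coefficients (< 2^31, exact in doubles).
// Returns an n x dims matrix; row i is the signature of set i.
// [[Rcpp::export]]
NumericMatrix minhash_cpp(List token_sets, NumericVector a, NumericVector b) {
  int n = token_sets.size();
  int dims = a.size();
  std::vector<uint64_t> av(dims), bv(dims);
  for (int j = 0; j < dims; ++j) {
    av[j] = (uint64_t) a[j];
    bv[j] = (uint64_t) b[j];
  }
  NumericMatrix out(n, dims);
  for (int i = 0; i < n; ++i) {
    NumericVector toks = token_sets[i];
    int m = toks.size();
    if (m == 0) stop("empty shingle set: no signature defined");
    std::vector<uint64_t> tv(m);
    for (int t = 0; t < m; ++t) tv[t] = (uint64_t) toks[t];
    for (int j = 0; j < dims; ++j) {
      uint64_t best = UINT64_MAX;
      const uint64_t aj = av[j], bj = bv[j];
      for (int t = 0; t < m; ++t) {
        uint64_t v = (aj * tv[t] + bj) % MERSENNE_P;
        v &= HASH_MASK;
        if (v < best) best = v;
      }
      out(i, j) = (double) best;
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Proportion of signature positions with equal value, for all row pairs of
// A (na x dims) and B (nb x dims). This is the MinHash estimate of the
// Jaccard similarity between the underlying shingle sets.
// [[Rcpp::export]]
NumericMatrix simmat_cpp(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow(), dims = A.ncol();
  if (B.ncol() != dims) stop("signature length mismatch");
  NumericMatrix out(na, nb);
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      int eq = 0;
      for (int k = 0; k < dims; ++k)
        if (A(i, k) == B(j, k)) ++eq;
      out(i, j) = (double) eq / dims;
    }
    if (i % 32 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
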