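// Bitset carrier-set machinery: the locally-distinct-bin scan and the
// permutation counting kernels. Carrier sets are packed into 32-bit words
// (individual s -> word s/32, bit s%32). All set comparisons exploit the
// subset structure of running unions, so equality reduces to popcounts.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static inline int popcount32(uint32_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcount(x);
#else
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
#endif
}

// Pack a logical matrix (individuals x columns) into 32-bit words
// (words x columns). NA is not allowed.
// [[Rcpp::export]]
IntegerMatrix pack_bits_cpp(LogicalMatrix m) {
  int N = m.nrow(), k = m.ncol();
  int W = (N + 31) / 32;
  IntegerMatrix out(W, k);
  for (int c = 0; c < k; ++c) {
    uint32_t *col = reinterpret_cast<uint32_t *>(&out(0, c));
    for (int s = 0; s < N; ++s) {
      int v = m(s, c);
      if (v == NA_LOGICAL) stop("NA in bit matrix");
      if (v) col[s / 32] |= (uint32_t)1 << (s % 32);
    }
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector unpack_bits_cpp(IntegerVector words, int n) {
  LogicalVector out(n);
  const uint32_t *w = reinterpret_cast<const uint32_t *>(&words[0]);
  for (int s = 0; s < n; ++s)
    out[s] = (w[s / 32] >> (s % 32)) & 1u;
  return out;
}

// Enumerate all locally distinct bins of a chromosome panel.
//
// carriers: individuals x variants logical matrix; every column must have at
// least one carrier. For each start i the running union U = B(i..j) and the
// trailing union V = B(i+1..j) (empty while j == i) are maintained; at each j
//   break     if U == V or U == full set,
//   continue  if variant j+1 exists and its carriers are a subset of U,
//   emit      (i, j, U) otherwise.
// Returned indices are 1-based.
// [[Rcpp::export]]
List scan_bins_cpp(LogicalMatrix carriers) {
  int N = carriers.nrow(), n = carriers.ncol();
  int W = (N + 31) / 32;
  // pack site carrier sets
  std::vector<uint32_t> site((size_t)W * n, 0u);
  std::vector<int> site_pc(n, 0);
  for (int v = 0; v < n; ++v) {
    uint32_t *col = &site[(size_t)v * W];
    for (int s = 0; s < N; ++s)
      if (carriers(s, v)) { col[s / 32] |= (uint32_t)1 << (s % 32); ++site_pc[v]; }
    if (site_pc[v] == 0) stop("carrier set of variant %d is empty", v + 1);
  }

  std::vector<int> out_i, out_j, out_pc;
  std::vector<uint32_t> out_words;
  std::vector<uint32_t> U(W), V(W);

  for (int i = 0; i < n; ++i) {
    std::fill(U.begin(), U.end(), 0u);
    std::fill(V.begin(), V.end(), 0u);
    int pcU = 0, pcV = 0;
    for (int j = i; j < n; ++j) {
      const uint32_t *B = &site[(size_t)j * W];
      pcU = 0;
      for (int w = 0; w < W; ++w) { U[w] |= B[w]; pcU += popcount32(U[w]); }
      if (j > i) {
        pcV = 0;
        for (int w = 0; w < W; ++w) { V[w] |= B[w]; pcV += popcount32(V[w]); }
      }
      // V is a subset of U, so U == V iff equal popcounts; V is empty at j == i
      if (pcU == pcV || pcU == N) break;
      if (j + 1 < n) {
        const uint32_t *Bn = &site[(size_t)(j + 1) * W];
        bool subset = true;
        for (int w = 0; w < W; ++w)
          if (Bn[w] & ~U[w]) { subset = false; break; }
        if (subset) continue; // extending by j+1 changes nothing: defer
      }
      out_i.push_back(i + 1);
      out_j.push_back(j + 1);
      out_pc.push_back(pcU);
      out_words.insert(out_words.end(), U.begin(), U.end());
    }
  }

  int nb = (int)out_i.size();
  IntegerMatrix words(W, nb);
  if (nb > 0) {
    uint32_t *dst = reinterpret_cast<uint32_t *>(&words(0, 0));
    std::copy(out_words.begin(), out_words.end(), dst);
  }
  return List::create(_["i"] = wrap(out_i), _["j"] = wrap(out_j),
                      _["popcount"] = wrap(out_pc), _["words"] = words,
                      _["n_words"] = W, _["n_individuals"] = N);
}

// Number of set bits of each column of `bin_words` that fall inside `mask`
// (same word layout). Used for observed case-carrier counts.
// [[Rcpp::export]]
IntegerVector count_in_mask_cpp(IntegerMatrix bin_words, IntegerVector mask) {
  int W = bin_words.nrow(), nb = bin_words.ncol();
  if (mask.size() != W) stop("mask word length mismatch");
  const uint32_t *mw = reinterpret_cast<const uint32_t *>(&mask[0]);
  IntegerVector out(nb);
  for (int b = 0; b < nb; ++b) {
    const uint32_t *bw = reinterpret_cast<const uint32_t *>(&bin_words(0, b));
    int c = 0;
    for (int w = 0; w < W; ++w) c += popcount32(bw[w] & mw[w]);
    out[b] = c;
  }
  return out;
}

// Case-carrier counts for a block of bins under many case masks:
// returns an nb x r integer matrix, entry (b, k) = |bin b  &  mask k|.
// [[Rcpp::export]]
IntegerMatrix count_in_masks_cpp(IntegerMatrix bin_words, IntegerMatrix masks) {
  int W = bin_words.nrow(), nb = bin_words.ncol(), r = masks.ncol();
  if (masks.nrow() != W) stop("mask word length mismatch");
  IntegerMatrix out(nb, r);
  for (int k = 0; k < r; ++k) {
    const uint32_t *mw = reinterpret_cast<const uint32_t *>(&masks(0, k));
    for (int b = 0; b < nb; ++b) {
      const uint32_t *bw = reinterpret_cast<const uint32_t *>(&bin_words(0, b));
      int c = 0;
      for (int w = 0; w < W; ++w) c += popcount32(bw[w] & mw[w]);
      out(b, k) = c;
    }
  }
  return out;
}

// Per-permutation maximum of the 1-df Pearson chi-square over all bins.
//
// For bin b with m = popcount[b] carriers and a of them in the case mask,
// the 2x2 table is a, b = m - a, c = n_case - a, d = n_control - b and
//   stat = N * (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)).
// The floating-point evaluation order mirrors the R expression
//   N * (t * t) / ((a+b) * (c+d) * (a+c) * (b+d))
// exactly, so results are bit-identical to the R implementation.
// [[Rcpp::export]]
NumericVector perm_max_chi2_cpp(IntegerMatrix bin_words, IntegerVector popcount,
                                IntegerMatrix masks, int n_case, int n_individuals) {
  int W = bin_words.nrow(), nb = bin_words.ncol(), r = masks.ncol();
  if (masks.nrow() != W) stop("mask word length mismatch");
  if (popcount.size() != nb) stop("popcount length mismatch");
  double N = (double)n_individuals;
  double n_ctrl = N - (double)n_case;
  NumericVector out(r);
  for (int k = 0; k < r; ++k) {
    const uint32_t *mw = reinterpret_cast<const uint32_t *>(&masks(0, k));
    double best = 0.0;
    for (int b = 0; b < nb; ++b) {
      const uint32_t *bw = reinterpret_cast<const uint32_t *>(&bin_words(0, b));
      int cnt = 0;
      for (int w = 0; w < W; ++w) cnt += popcount32(bw[w] & mw[w]);
      double a = (double)cnt;
      double m = (double)popcount[b];
      double bcell = m - a;
      double ccell = (double)n_case - a;
      double dcell = n_ctrl - bcell;
      double t = a * dcell - bcell * ccell;
      double den = (a + bcell) * (ccell + dcell) * (a + ccell) * (bcell + dcell);
      double stat = (den > 0.0) ? N * (t * t) / den : 0.0;
      if (stat > best) best = stat;
    }
    out[k] = best;
  }
  return out;
}
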