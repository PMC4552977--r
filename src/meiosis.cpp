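#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Gamete formation for one parent: Poisson-distributed crossovers per
// chromosome (Haldane model, no interference), uniform crossover positions,
// then symmetric per-locus mutation. Loci must be ordered by chromosome and
// position. Uses R's RNG so set.seed() governs everything.

static void make_gamete(const IntegerMatrix &haplo, int parent,
                        const std::vector<int> &chr_first,
                        const std::vector<int> &chr_last,
                        const NumericVector &pos, const NumericVector &chr_len,
                        double mu, int *out, int *xo_out) {
  const int n_chr = chr_first.size();
  const int r0 = 2 * parent;     // first haplotype row (0-based)
  std::vector<double> bp;
  for (int c = 0; c < n_chr; ++c) {
    int k = (int)R::rpois(chr_len[c]);
    if (xo_out) xo_out[c] = k;
    bp.resize(k);
    for (int i = 0; i < k; ++i) bp[i] = unif_rand() * chr_len[c];
    std::sort(bp.begin(), bp.end());
    int cur = (unif_rand() < 0.5) ? 0 : 1;
    int ptr = 0;
    for (int j = chr_first[c]; j <= chr_last[c]; ++j) {
      while (ptr < k && bp[ptr] < pos[j]) { cur ^= 1; ++ptr; }
      out[j] = haplo(r0 + cur, j);
    }
  }
  if (mu > 0) {
    const int L = haplo.ncol();
    int n_mut = (int)R::rbinom((double)L, mu);
    for (int m = 0; m < n_mut; ++m) {
      int j = (int)(unif_rand() * L);
      if (j >= L) j = L - 1;
      out[j] = 1 - out[j];
    }
  }
}

static void chr_bounds(const IntegerVector &chr, std::vector<int> &first,
                       std::vector<int> &last) {
  const int L = chr.size();
  int n_chr = 0;
  for (int j = 0; j < L; ++j) n_chr = std::max(n_chr, chr[j]);
  first.assign(n_chr, -1);
  last.assign(n_chr, -1);
  for (int j = 0; j < L; ++j) {
    int c = chr[j] - 1;
    if (first[c] < 0) first[c] = j;
    last[c] = j;
  }
}

// [[Rcpp::export]]
List cpp_gametes(IntegerMatrix haplo, IntegerVector parents, IntegerVector chr,
                 NumericVector pos, NumericVector chr_len, double mu,
                 IntegerVector keep) {
  const int L = haplo.ncol();
  const int n = parents.size();
  std::vector<int> first, last;
  chr_bounds(chr, first, last);
  const int n_chr = first.size();
  const int k = keep.size() > 0 ? keep.size() : L;
  IntegerMatrix gam(n, k);
  IntegerMatrix xo(n, n_chr);
  std::vector<int> tmp(L);
  std::vector<int> xo_tmp(n_chr);
  for (int i = 0; i < n; ++i) {
    make_gamete(haplo, parents[i] - 1, first, last, pos, chr_len, mu,
                tmp.data(), xo_tmp.data());
    for (int c = 0; c < n_chr; ++c) xo(i, c) = xo_tmp[c];
    if (keep.size() > 0) {
      for (int j = 0; j < k; ++j) gam(i, j) = tmp[keep[j] - 1];
    } else {
      for (int j = 0; j < L; ++j) gam(i, j) = tmp[j];
    }
  }
  return List::create(_["gametes"] = gam, _["crossovers"] = xo);
}

// [[Rcpp::export]]
IntegerMatrix cpp_next_generation(IntegerMatrix haplo, IntegerVector sires,
                                  IntegerVector dams, IntegerVector chr,
                                  NumericVector pos, NumericVector chr_len,
                                  double mu) {
  const int L = haplo.ncol();
  const int n = sires.size();
  std::vector<int> first, last;
  chr_bounds(chr, first, last);
  IntegerMatrix out(2 * n, L);
  std::vector<int> tmp(L);
  for (int i = 0; i < n; ++i) {
    make_gamete(haplo, sires[i] - 1, first, last, pos, chr_len, mu,
                tmp.data(), NULL);
    for (int j = 0; j < L; ++j) out(2 * i, j) = tmp[j];
    make_gamete(haplo, dams[i] - 1, first, last, pos, chr_len, mu,
                tmp.data(), NULL);
    for (int j = 0; j < L; ++j) out(2 * i + 1, j) = tmp[j];
  }
  return out;
}
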