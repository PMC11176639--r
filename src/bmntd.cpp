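#include <Rcpp.h>
using namespace Rcpp;

// Between-community mean nearest taxon distance (betaMNTD) for every pair of
// samples, plus its tip-shuffling null distribution.
//
// D      taxa x taxa patristic distance matrix (column order = taxon order)
// W      samples x taxa weight matrix; rows sum to 1 over present taxa
//        (relative abundances when abundance-weighted, 1/richness otherwise)
// perms  n_null x n_taxa matrix of 0-based taxon->tip assignments; row r maps
//        taxon i to tip position perms(r, i), so the null distance between
//        taxa a and b is D(perms(r,a), perms(r,b)). A single shuffle per
//        replicate is shared by all pairs.
//
// Returns obs (n x n betaMNTD), and the running mean / sd (n-1 denominator)
// of the null distribution over replicates.

static void pair_bmntd(const NumericMatrix& D,
                       const NumericMatrix& W,
                       const std::vector<std::vector<int>>& supp,
                       const int* perm,
                       NumericMatrix& out,
                       std::vector<double>& v) {
  const int n = W.nrow(), t = W.ncol();
  // M(k, i) = min over taxa j present in sample k of D(perm[i], perm[j]),
  // stored tip-indexed: v_k[row] = min_j D(row, perm[j]), M(k,i) = v_k[perm[i]]
  NumericMatrix M(n, t);
  for (int k = 0; k < n; ++k) {
    std::fill(v.begin(), v.end(), R_PosInf);
    for (int j : supp[k]) {
      const double* col = &D(0, perm[j]);
      for (int row = 0; row < t; ++row)
        if (col[row] < v[row]) v[row] = col[row];
    }
    for (int i = 0; i < t; ++i) M(k, i) = v[perm[i]];
  }
  for (int j = 0; j < n; ++j) {
    for (int k = j + 1; k < n; ++k) {
      double s = 0.0;
      for (int i : supp[j]) s += W(j, i) * M(k, i);
      for (int i : supp[k]) s += W(k, i) * M(j, i);
      s *= 0.5;
      out(j, k) = s;
      out(k, j) = s;
    }
  }
}

// [[Rcpp::export(name = ".bmntd_engine")]]
List bmntd_engine(NumericMatrix D, NumericMatrix W, IntegerMatrix perms) {
  const int n = W.nrow(), t = W.ncol();
  const int n_null = perms.nrow();
  if (D.nrow() != t || D.ncol() != t)
    stop("distance matrix does not match taxon count");

  std::vector<std::vector<int>> supp(n);
  for (int k = 0; k < n; ++k)
    for (int i = 0; i < t; ++i)
      if (W(k, i) > 0.0) supp[k].push_back(i);

  std::vector<double> v(t);
  std::vector<int> ident(t);
  for (int i = 0; i < t; ++i) ident[i] = i;

  NumericMatrix obs(n, n);
  pair_bmntd(D, W, supp, ident.data(), obs, v);

  NumericMatrix sum(n, n), sumsq(n, n), rep(n, n);
  std::vector<int> perm(t);
  for (int r = 0; r < n_null; ++r) {
    for (int i = 0; i < t; ++i) perm[i] = perms(r, i);
    pair_bmntd(D, W, supp, perm.data(), rep, v);
    for (int j = 0; j < n; ++j)
      for (int k = 0; k < n; ++k) {
        sum(j, k) += rep(j, k);
        sumsq(j, k) += rep(j, k) * rep(j, k);
      }
    if (r % 32 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix mean(n, n), sd(n, n);
  if (n_null > 0) {
    for (int j = 0; j < n; ++j)
      for (int k = 0; k < n; ++k) {
        double m = sum(j, k) / n_null;
        mean(j, k) = m;
        double ss = sumsq(j, k) - n_null * m * m;
        sd(j, k) = (n_null > 1 && ss > 0) ? std::sqrt(ss / (n_null - 1)) : 0.0;
      }
  }
  return List::create(_["obs"] = obs, _["mean"] = mean, _["sd"] = sd,
                      _["n_null"] = n_null);
}
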