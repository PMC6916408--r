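#include <Rcpp.h>
using namespace Rcpp;

// Cross-products Z' V^-1 Z and log|V| for the Brownian-motion covariance V
// implied by a rooted tree, in one postorder pass (pairwise peeling;
// polytomies are merged sequentially, which leaves the totals unchanged).
//
// edge : 2-column (parent, child) matrix in postorder, 1-based ape node ids
// len  : edge lengths, already rate-scaled, aligned with `edge` rows
// Z    : ntip x m data matrix, row i = tip with ape id i
// nnode_total : ntip + internal node count (size of the node id space)
//
// Each internal merge of accumulations (z_p, s_p) and (z_c, v_c) contributes
// a contrast (z_p - z_c) with variance s_p + v_c; the root accumulation
// contributes z_root z_root' / s_root and log(s_root). The sum over
// contrasts equals Z' V^-1 Z and the log-variance sum equals log|V|.
// [[Rcpp::export]]
List tree_gls_cpp(IntegerMatrix edge, NumericVector len, NumericMatrix Z,
                  int nnode_total) {
  const int ntip = Z.nrow(), m = Z.ncol(), ne = edge.nrow();
  std::vector<double> s(nnode_total, 0.0);
  std::vector<int> seen(nnode_total, 0);
  NumericMatrix zval(nnode_total, m);
  for (int i = 0; i < ntip; ++i) {
    seen[i] = 1;
    for (int j = 0; j < m; ++j) zval(i, j) = Z(i, j);
  }
  NumericMatrix C(m, m);
  double logdet = 0.0;
  for (int e = 0; e < ne; ++e) {
    const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    const double vc = len[e] + s[c];
    if (!seen[p]) {
      seen[p] = 1;
      s[p] = vc;
      for (int j = 0; j < m; ++j) zval(p, j) = zval(c, j);
    } else {
      const double tot = s[p] + vc;
      if (tot <= 0.0)
        stop("zero-variance contrast: two zero-length paths meet");
      logdet += std::log(tot);
      for (int j = 0; j < m; ++j) {
        const double dj = zval(p, j) - zval(c, j);
        for (int k = j; k < m; ++k)
          C(j, k) += dj * (zval(p, k) - zval(c, k)) / tot;
      }
      const double w = vc / tot;
      for (int j = 0; j < m; ++j)
        zval(p, j) = w * zval(p, j) + (1.0 - w) * zval(c, j);
      s[p] = s[p] * vc / tot;
    }
  }
  const int root = ntip; // ape convention: root id = ntip + 1
  if (s[root] <= 0.0) stop("root variance is zero");
  logdet += std::log(s[root]);
  for (int j = 0; j < m; ++j)
    for (int k = j; k < m; ++k)
      C(j, k) += zval(root, j) * zval(root, k) / s[root];
  for (int j = 0; j < m; ++j)
    for (int k = 0; k < j; ++k) C(j, k) = C(k, j);
  return List::create(_["C"] = C, _["logdet"] = logdet);
}
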