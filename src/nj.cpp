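#include <Rcpp.h>
using namespace Rcpp;

// Neighbour-joining agglomeration (Saitou & Nei) on a complete distance
// matrix. Joins the pair minimising Q(i,j) = (m-2) d(i,j) - r_i - r_j; exact
// ties are broken by the smallest (row, column) index pair in the current
// active list (new clusters are appended at the end), so the output is fully
// deterministic. Negative branch lengths are clamped to zero and the total
// clamped amount is returned as `neg.deficit`.
//
// Node numbering of the returned edge matrix follows the ape convention:
// tips 1..n in input order, internal nodes n+1..2n-2 with the final
// trifurcation (root of the unrooted tree) at n+1.
// [[Rcpp::export]]
List nj_core(NumericMatrix D) {
  int n = D.nrow();
  if (n < 3) stop("nj_core requires at least 3 taxa");
  std::vector<int> act(n);
  std::vector< std::vector<double> > d(n, std::vector<double>(n));
  for (int i = 0; i < n; i++) {
    act[i] = i + 1;
    for (int j = 0; j < n; j++) d[i][j] = D(i, j);
  }
  int m = n, created = 0;
  double deficit = 0.0;
  std::vector<int> ep, ec;
  std::vector<double> el;
  ep.reserve(2 * n); ec.reserve(2 * n); el.reserve(2 * n);

  while (m > 3) {
    std::vector<double> r(m, 0.0);
    for (int i = 0; i < m; i++) {
      double s = 0.0;
      for (int j = 0; j < m; j++) s += d[i][j];
      r[i] = s;
    }
    int bi = -1, bj = -1;
    double bq = R_PosInf;
    for (int i = 0; i < m; i++) {
      for (int j = i + 1; j < m; j++) {
        double q = (m - 2) * d[i][j] - r[i] - r[j];
        if (q < bq) { bq = q; bi = i; bj = j; }  // strict '<' keeps first tie
      }
    }
    double dij = d[bi][bj];
    double li = dij / 2.0 + (r[bi] - r[bj]) / (2.0 * (m - 2));
    double lj = dij - li;
    if (li < 0) { deficit += -li; li = 0; }
    if (lj < 0) { deficit += -lj; lj = 0; }
    created++;
    int newid = n + created;
    ep.push_back(newid); ec.push_back(act[bi]); el.push_back(li);
    ep.push_back(newid); ec.push_back(act[bj]); el.push_back(lj);

    std::vector<double> nd(m, 0.0);
    for (int k = 0; k < m; k++)
      if (k != bi && k != bj) nd[k] = (d[bi][k] + d[bj][k] - dij) / 2.0;
    for (int k = 0; k < m; k++) { d[bi][k] = nd[k]; d[k][bi] = nd[k]; }
    d[bi][bi] = 0.0;
    act[bi] = newid;
    d.erase(d.begin() + bj);
    for (size_t k = 0; k < d.size(); k++) d[k].erase(d[k].begin() + bj);
    act.erase(act.begin() + bj);
    m--;
  }

  created++;
  int center = n + created;  // created == n - 2
  double ls[3];
  ls[0] = (d[0][1] + d[0][2] - d[1][2]) / 2.0;
  ls[1] = (d[0][1] + d[1][2] - d[0][2]) / 2.0;
  ls[2] = (d[0][2] + d[1][2] - d[0][1]) / 2.0;
  for (int k = 0; k < 3; k++) {
    if (ls[k] < 0) { deficit += -ls[k]; ls[k] = 0; }
    ep.push_back(center); ec.push_back(act[k]); el.push_back(ls[k]);
  }

  int nint = created;  // n - 2 internal nodes
  int ne = ep.size();
  IntegerMatrix edge(ne, 2);
  NumericVector len(ne);
  for (int e = 0; e < ne; e++) {
    int p = ep[e], c = ec[e];
    int pa = (p == n + nint) ? (n + 1) : (n + 1 + (nint - (p - n)));
    int ch = (c <= n) ? c
             : ((c == n + nint) ? (n + 1) : (n + 1 + (nint - (c - n))));
    edge(e, 0) = pa;
    edge(e, 1) = ch;
    len[e] = el[e];
  }
  return List::create(_["edge"] = edge, _["edge.length"] = len,
                      _["Nnode"] = nint, _["neg.deficit"] = deficit);
}
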