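#include <Rcpp.h>
#include <cstdio>
#include <string>
#include <vector>
using namespace Rcpp;

// Saitou-Nei neighbor joining on a distance matrix, emitted as a newick
// string (parsed back with ape::read.tree on the R side). Conventions:
//  - candidate pairs are scanned in current active order with strict
//    improvement, so Q-criterion ties resolve to the smallest (i, j);
//  - negative branch lengths are clamped to 0 with the deficit moved to
//    the sibling branch (output only; distance updates use raw values);
//  - the last three active nodes are joined in a trifurcation.

static std::string fmt_bl(double x) {
  char buf[40];
  std::snprintf(buf, sizeof(buf), "%.10g", x);
  return std::string(buf);
}

static void clamp_pair(double& vi, double& vj) {
  if (vi < 0) { vj += vi; vi = 0; }
  if (vj < 0) { vi += vj; vj = 0; }
  if (vi < 0) vi = 0;
}

// [[Rcpp::export(name = ".nj_newick_cpp")]]
std::string nj_newick_cpp(NumericMatrix dist, CharacterVector labels) {
  const int n = dist.nrow();
  if (n < 2) stop("need at least 2 taxa");
  if (dist.ncol() != n || labels.size() != n)
    stop("distance matrix / label mismatch");

  std::vector<std::string> nk(n);
  for (int i = 0; i < n; ++i) nk[i] = as<std::string>(labels[i]);

  if (n == 2) {
    double h = dist(0, 1) / 2.0;
    return "(" + nk[0] + ":" + fmt_bl(h) + "," + nk[1] + ":" + fmt_bl(h) + ");";
  }

  // dense working copy indexed by active slot
  std::vector<std::vector<double>> d(n, std::vector<double>(n));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) d[i][j] = dist(i, j);
  std::vector<int> act(n);
  for (int i = 0; i < n; ++i) act[i] = i;
  int m = n;

  while (m > 3) {
    std::vector<double> r(m, 0.0);
    for (int i = 0; i < m; ++i) {
      double s = 0;
      for (int j = 0; j < m; ++j) s += d[act[i]][act[j]];
      r[i] = s;
    }
    int bi = -1, bj = -1;
    double bq = R_PosInf;
    for (int i = 0; i < m; ++i)
      for (int j = i + 1; j < m; ++j) {
        const double q = (m - 2) * d[act[i]][act[j]] - r[i] - r[j];
        if (q < bq) { bq = q; bi = i; bj = j; }
      }
    const int ai = act[bi], aj = act[bj];
    const double dij = d[ai][aj];
    double vi = 0.5 * dij + (r[bi] - r[bj]) / (2.0 * (m - 2));
    double vj = dij - vi;
    // raw update first (Studier-Keppler), then clamp for output
    std::vector<double> dn(n, 0.0);
    for (int k = 0; k < m; ++k) {
      const int ak = act[k];
      if (ak == ai || ak == aj) continue;
      dn[ak] = 0.5 * (d[ai][ak] + d[aj][ak] - dij);
    }
    clamp_pair(vi, vj);
    nk[ai] = "(" + nk[ai] + ":" + fmt_bl(vi) + "," + nk[aj] + ":" + fmt_bl(vj) + ")";
    for (int k = 0; k < m; ++k) {
      const int ak = act[k];
      if (ak == ai || ak == aj) continue;
      d[ai][ak] = d[ak][ai] = dn[ak];
    }
    d[ai][ai] = 0;
    act.erase(act.begin() + bj);
    --m;
  }

  const int x = act[0], y = act[1], z = act[2];
  double lx = 0.5 * (d[x][y] + d[x][z] - d[y][z]);
  double ly = 0.5 * (d[x][y] + d[y][z] - d[x][z]);
  double lz = 0.5 * (d[x][z] + d[y][z] - d[x][y]);
  if (lx < 0) lx = 0;
  if (ly < 0) ly = 0;
  if (lz < 0) lz = 0;
  return "(" + nk[x] + ":" + fmt_bl(lx) + "," + nk[y] + ":" + fmt_bl(ly) +
         "," + nk[z] + ":" + fmt_bl(lz) + ");";
}
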