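#include <Rcpp.h>
using namespace Rcpp;

// Alignment coding used throughout src/: 0=A, 1=C, 2=G, 3=T, 4=missing
// (N or gap). Under this coding a transition (A<->G, C<->T) is exactly
// (a ^ b) == 2; any other difference between valid codes is a transversion.

// Weighted pairwise substitution tallies over a site-by-sequence matrix
// (L rows = sites, n cols = sequences; column-major access is contiguous
// over sites). `w` holds per-site multiplicities, so the same routine
// serves plain counting (all 1) and bootstrap column resampling.
// [[Rcpp::export(name = ".pair_counts_cpp")]]
List pair_counts_cpp(IntegerMatrix seqs, NumericVector w) {
  const int L = seqs.nrow(), n = seqs.ncol();
  if (w.size() != L) stop("weight vector length must equal alignment length");
  NumericMatrix ts(n, n), tv(n, n), ns(n, n);
  for (int i = 0; i < n; ++i) {
    const int* a = &seqs(0, i);
    for (int j = i + 1; j < n; ++j) {
      const int* b = &seqs(0, j);
      double cts = 0, ctv = 0, cns = 0;
      for (int k = 0; k < L; ++k) {
        const double wk = w[k];
        if (wk == 0.0) continue;
        const int x = a[k], y = b[k];
        if (x > 3 || y > 3) continue;
        cns += wk;
        if (x != y) {
          if ((x ^ y) == 2) cts += wk; else ctv += wk;
        }
      }
      ts(i, j) = ts(j, i) = cts;
      tv(i, j) = tv(j, i) = ctv;
      ns(i, j) = ns(j, i) = cns;
    }
  }
  return List::create(_["transitions"] = ts, _["transversions"] = tv,
                      _["n_sites"] = ns);
}

// Match / comparable-site counts of each query column against each
// reference column (pairwise deletion), for identity-based assignment.
// [[Rcpp::export(name = ".ident_counts_cpp")]]
List ident_counts_cpp(IntegerMatrix q, IntegerMatrix r) {
  const int L = q.nrow(), nq = q.ncol(), nr = r.ncol();
  if (r.nrow() != L) stop("query and reference alignments differ in length");
  NumericMatrix match(nq, nr), comp(nq, nr);
  for (int i = 0; i < nq; ++i) {
    const int* a = &q(0, i);
    for (int j = 0; j < nr; ++j) {
      const int* b = &r(0, j);
      double m = 0, c = 0;
      for (int k = 0; k < L; ++k) {
        const int x = a[k], y = b[k];
        if (x > 3 || y > 3) continue;
        ++c;
        if (x == y) ++m;
      }
      match(i, j) = m;
      comp(i, j) = c;
    }
  }
  return List::create(_["matches"] = match, _["comparable"] = comp);
}
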