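#include <Rcpp.h>
using namespace Rcpp;

// Multiset intersection size of two diploid allele pairs (values >= 0;
// caller guarantees non-missing). Pairs are canonicalized (a1 <= a2).
static inline int pair_intersection(int a1, int a2, int b1, int b2) {
  if (a1 == a2) {                       // hom
    return (b1 == a1) + (b2 == a1);
  }
  int m = 0;
  if (a1 == b1 || a1 == b2) m++;
  if (a2 == b1 || a2 == b2) m++;
  return m;
}

// Pairwise comparison statistics over all variety pairs.
// a1, a2: n x L integer matrices of allele codes, NA = missing call.
// Returns allele-difference counts, per-pair loci compared, per-pair
// loci differing, and the Nei (1972) identity sums Jxy, Jx, Jy taken
// over loci co-typed in both varieties.
// [[Rcpp::export(name = ".pairwise_stats_cpp")]]
List pairwise_stats_cpp(IntegerMatrix a1, IntegerMatrix a2) {
  int n = a1.nrow(), L = a1.ncol();
  IntegerMatrix diffs(n, n), compared(n, n), loci_diff(n, n);
  NumericMatrix jxy(n, n), jx(n, n), jy(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int d = 0, nc = 0, ld = 0;
      double sxy = 0.0, sxx = 0.0, syy = 0.0;
      for (int l = 0; l < L; ++l) {
        int xi1 = a1(i, l), xi2 = a2(i, l);
        int yj1 = a1(j, l), yj2 = a2(j, l);
        if (xi1 == NA_INTEGER || yj1 == NA_INTEGER) continue;
        nc++;
        int inter = pair_intersection(xi1, xi2, yj1, yj2);
        int dd = 2 - inter;
        d += dd;
        if (dd > 0) ld++;
        // per-variety allele-frequency vectors: hom -> 1, het -> 0.5/0.5
        double xi_hom = (xi1 == xi2) ? 1.0 : 0.5;
        double yj_hom = (yj1 == yj2) ? 1.0 : 0.5;
        sxx += (xi1 == xi2) ? 1.0 : 0.5;
        syy += (yj1 == yj2) ? 1.0 : 0.5;
        double s = 0.0;
        // dot product of the two sparse frequency vectors
        if (xi1 == xi2) {
          if (yj1 == yj2) s = (xi1 == yj1) ? 1.0 : 0.0;
          else s = ((xi1 == yj1) + (xi1 == yj2)) * xi_hom * yj_hom;
        } else if (yj1 == yj2) {
          s = ((yj1 == xi1) + (yj1 == xi2)) * 0.5;
        } else {
          s = 0.25 * ((xi1 == yj1) + (xi1 == yj2) +
                      (xi2 == yj1) + (xi2 == yj2));
        }
        sxy += s;
      }
      diffs(i, j) = diffs(j, i) = d;
      compared(i, j) = compared(j, i) = nc;
      loci_diff(i, j) = loci_diff(j, i) = ld;
      jxy(i, j) = jxy(j, i) = sxy;
      jx(i, j) = jx(j, i) = sxx;
      jy(i, j) = jy(j, i) = syy;
    }
  }
  return List::create(_["diffs"] = diffs, _["compared"] = compared,
                      _["loci_diff"] = loci_diff,
                      _["jxy"] = jxy, _["jx"] = jx, _["jy"] = jy);
}
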