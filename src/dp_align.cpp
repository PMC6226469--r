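#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-programming label-map alignment, layered by matched-pair count.
//
// Layer t < L holds the best score of a monotone pairing with exactly t
// matched pairs ending at (i, j); layer L holds the best with at least L
// pairs. Layering makes the min_labels-constrained optimum exact: without
// it, a cell preferring a short high-scoring path would hide a longer path
// that the min-labels filter requires (the brute-force enumeration oracle
// finds such paths, so the DP must too).
//
// Transitions look back up to max_skip labels on either side; each interior
// skipped label is penalised. In endoutlier mode the unmatched terminal run
// of the query is free (open-ended alignment of a contig whose tip extends
// past the reference); in fit mode terminal unmatched query labels are
// charged at the R level from the returned scores. Reference labels outside
// the aligned window are never penalised (the reference is a whole
// chromosome).
//
// Matched-interval score: m - (q_len - r_len)^2 / (2 * sigma^2),
// sigma^2 = sd_fixed^2 + (sr * r_len)^2 -- a Gaussian sizing-error
// log-likelihood against a match bonus m. Must stay identical to the
// R-level interval_score().

// [[Rcpp::export]]
List dp_align_core(NumericVector q, NumericVector r, double m,
                   double sd_fixed, double sr, double fp_pen, double fn_pen,
                   int max_skip, bool endoutlier, int min_labels) {
  const int n = q.size(), nr = r.size();
  const int L = std::max(1, min_labels);
  const double NEG = -std::numeric_limits<double>::infinity();
  // arrays indexed [t * n * nr + i * nr + j]
  const R_xlen_t sz = (R_xlen_t)L * n * nr;
  std::vector<double> S(sz, NEG);
  std::vector<int> Pt(sz, -1), Pi(sz, -1), Pj(sz, -1);
  auto idx = [&](int t, int i, int j) {
    return (R_xlen_t)t * n * nr + (R_xlen_t)i * nr + j;
  };
  for (int i = 0; i < n; ++i) {
    const double base = endoutlier ? 0.0 : -fp_pen * i;
    const int di_max = std::min(max_skip, i);
    for (int j = 0; j < nr; ++j) {
      const int dj_max = std::min(max_skip, j);
      for (int t = 0; t < L; ++t) {
        double best = (t == 0 && L > 1) ? base : ((L == 1) ? base : NEG);
        int bt = -1, bi = -1, bj = -1;
        if (t > 0 || L == 1) {
          for (int di = 1; di <= di_max; ++di) {
            const double ql = q[i] - q[i - di];
            const double qpen = fp_pen * (di - 1);
            for (int dj = 1; dj <= dj_max; ++dj) {
              const double rl = r[j] - r[j - dj];
              const double sig2 = sd_fixed * sd_fixed + (sr * rl) * (sr * rl);
              const double sc =
                m - (ql - rl) * (ql - rl) / (2.0 * sig2) - qpen -
                fn_pen * (dj - 1);
              // predecessor from the layer below ...
              if (t > 0) {
                const double v = S[idx(t - 1, i - di, j - dj)];
                if (v > NEG && v + sc > best) {
                  best = v + sc;
                  bt = t - 1; bi = i - di; bj = j - dj;
                }
              }
              // ... and, in the top ("at least L") layer, from itself
              if (t == L - 1) {
                const double v = S[idx(t, i - di, j - dj)];
                if (v > NEG && v + sc > best) {
                  best = v + sc;
                  bt = t; bi = i - di; bj = j - dj;
                }
              }
            }
          }
        }
        S[idx(t, i, j)] = best;
        Pt[idx(t, i, j)] = bt;
        Pi[idx(t, i, j)] = bi;
        Pj[idx(t, i, j)] = bj;
      }
    }
  }
  // final-layer scores for candidate ranking
  NumericMatrix Sfin(n, nr);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < nr; ++j)
      Sfin(i, j) = S[idx(L - 1, i, j)];
  IntegerVector pt(Pt.begin(), Pt.end()), pi(Pi.begin(), Pi.end()),
    pj(Pj.begin(), Pj.end());
  return List::create(_["S"] = Sfin, _["Pt"] = pt, _["Pi"] = pi,
                      _["Pj"] = pj, _["L"] = L);
}
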