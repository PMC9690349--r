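#include <Rcpp.h>
#include <map>
#include <cmath>

using namespace Rcpp;

// Euclidean distance between rows a and b of the column-major n x p matrix
// at x, accumulating squared deviations in column order with double
// precision — the same arithmetic stats::dist() uses, so thresholding
// decisions match the dense R path bit for bit.
static inline double row_dist(const double* x, R_xlen_t n, int p, R_xlen_t a,
                              R_xlen_t b) {
  double acc = 0.0;
  for (int c = 0; c < p; ++c) {
    double dev = x[a + c * n] - x[b + c * n];
    acc += dev * dev;
  }
  return std::sqrt(acc);
}

// Mean of the n*(n-1)/2 distinct pairwise distances, visiting pairs in
// stats::dist() storage order (lower triangle, column major) and using the
// two-pass long-double algorithm of R's mean(), so the result is identical
// to mean(dist(em)) while needing O(1) memory. Distances are recomputed in
// the correction pass rather than stored.
// [[Rcpp::export]]
double cpp_mean_pair_dist(NumericMatrix em) {
  R_xlen_t n = em.nrow();
  int p = em.ncol();
  const double* x = em.begin();
  if (n < 2) stop("need at least 2 embedded vectors");
  long double npairs = (long double)n * (n - 1) / 2.0L;
  long double s = 0.0L;
  for (R_xlen_t j = 0; j < n - 1; ++j)
    for (R_xlen_t i = j + 1; i < n; ++i)
      s += row_dist(x, n, p, i, j);
  s /= npairs;
  long double t = 0.0L;
  for (R_xlen_t j = 0; j < n - 1; ++j)
    for (R_xlen_t i = j + 1; i < n; ++i)
      t += (row_dist(x, n, p, i, j) - s);
  return (double)(s + t / npairs);
}

// Streaming recurrence counts. Scans each super-diagonal and each column of
// the (implicit) recurrence matrix, so peak memory is O(n) regardless of
// series length. Cells with min(i, j, n-1-i, n-1-j) < border (0-based) are
// ignored in every count. The main diagonal (LOI) is excluded from the
// recurrence total and from diagonal lines; in vertical scans the LOI cell
// participates in run formation when loi_vertical is true, but is never
// counted towards laminar cells.
//
// Returns:
//   rec        off-LOI recurrent cells in the trimmed region (both triangles)
//   diag_len/diag_count   histogram of maximal diagonal runs >= lmin
//                         (each upper-triangle run counted twice, for its mirror)
//   vert_len/vert_count   histogram of maximal vertical runs >= lmin
//   det_cells  recurrent cells inside counted diagonal runs (both triangles)
//   lam_cells  recurrent cells inside counted vertical runs (LOI cells excluded)
//   diag_rec_k recurrences on upper super-diagonal k = 1..n-1 after trimming
//   lmax       longest diagonal run (0 if none)
// [[Rcpp::export]]
List cpp_rqa_counts(NumericMatrix em, double r, int lmin, int border,
                    bool loi_vertical) {
  int n = em.nrow();
  int p = em.ncol();
  const double* x = em.begin();
  if (n < 1) stop("empty embedding");
  int lo = border, hi = n - 1 - border;

  std::map<int, double> dhist, vhist;
  double rec = 0.0, det_cells = 0.0, lam_cells = 0.0;
  int lmax = 0;
  NumericVector diag_rec_k(n > 1 ? n - 1 : 0);

  // diagonal scans: upper triangle, k = distance from LOI
  for (int k = 1; k <= n - 1; ++k) {
    // valid i range on this diagonal after border trim: j = i + k
    int i0 = lo, i1 = std::min(hi, n - 1 - k - border);
    double cnt = 0.0;
    int run = 0;
    for (int i = i0; i <= i1; ++i) {
      bool hit = row_dist(x, n, p, i, i + k) <= r;
      if (hit) {
        cnt += 1.0;
        ++run;
      }
      if (!hit || i == i1) {
        if (run >= lmin) {
          dhist[run] += 2.0;          // run + its lower-triangle mirror
          det_cells += 2.0 * run;
          if (run > lmax) lmax = run;
        }
        run = 0;
      }
    }
    if (k - 1 < diag_rec_k.size()) diag_rec_k[k - 1] = cnt;
    rec += 2.0 * cnt;                  // both triangles
  }

  // vertical scans: full columns inside the trimmed region
  for (int j = lo; j <= hi; ++j) {
    int run = 0, loi_in_run = 0;
    for (int i = lo; i <= hi; ++i) {
      bool hit;
      if (i == j) {
        hit = loi_vertical;            // LOI cell recurs by definition
      } else {
        hit = row_dist(x, n, p, i, j) <= r;
      }
      if (hit) {
        ++run;
        if (i == j) loi_in_run = 1;
      }
      if (!hit || i == hi) {
        if (run >= lmin) {
          vhist[run] += 1.0;
          lam_cells += (double)(run - loi_in_run);
        }
        run = 0;
        loi_in_run = 0;
      }
    }
  }

  int nd = (int)dhist.size(), nv = (int)vhist.size();
  IntegerVector dlen(nd), vlen(nv);
  NumericVector dcount(nd), vcount(nv);
  int idx = 0;
  for (std::map<int, double>::iterator it = dhist.begin(); it != dhist.end(); ++it) {
    dlen[idx] = it->first;
    dcount[idx] = it->second;
    ++idx;
  }
  idx = 0;
  for (std::map<int, double>::iterator it = vhist.begin(); it != vhist.end(); ++it) {
    vlen[idx] = it->first;
    vcount[idx] = it->second;
    ++idx;
  }

  return List::create(
    _["rec"] = rec,
    _["diag_len"] = dlen, _["diag_count"] = dcount,
    _["vert_len"] = vlen, _["vert_count"] = vcount,
    _["det_cells"] = det_cells, _["lam_cells"] = lam_cells,
    _["diag_rec_k"] = diag_rec_k, _["lmax"] = lmax);
}
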