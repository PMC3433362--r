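#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Plug-in joint mutual information machinery shared by the level-wise search.
//
// Candidate columns and the child are discrete vectors with entries in
// {0,...,k-1}, already aligned (one row per effective observation, no row
// crossing a series boundary).  Joint parent configurations are tracked as
// mixed-radix integer codes; counts are tallied into flat arrays and reset by
// revisiting only the occupied cells, so the per-subset cost is O(Ne).

namespace {

struct SubsetSearcher {
  const int *cand;   // column-major Ne x C
  const int *child;  // length Ne
  int ne, C, k, p;
  std::vector<int> code;     // (p+1) * ne incremental joint codes
  std::vector<int> cnt_j;    // k^p cells
  std::vector<int> cnt_jy;   // k^p * k cells
  std::vector<double> nlog;  // nlog[v] = v * log(v)
  std::vector<int> sel, best;
  double sy, lnne, best_mi;
  double n_eval;

  double leaf(const int *cur) {
    for (int r = 0; r < ne; ++r) {
      const int c = cur[r];
      ++cnt_j[c];
      ++cnt_jy[(size_t)c * k + child[r]];
    }
    double sj = 0.0, sjy = 0.0;
    for (int r = 0; r < ne; ++r) {
      const int c = cur[r];
      const int v = cnt_j[c];
      if (v > 0) {
        sj += nlog[v];
        int *q = &cnt_jy[(size_t)c * k];
        for (int y = 0; y < k; ++y) {
          if (q[y]) {
            sjy += nlog[q[y]];
            q[y] = 0;
          }
        }
        cnt_j[c] = 0;
      }
    }
    return lnne + (sjy - sj - sy) / ne;
  }

  void rec(int depth, int start) {
    const int need = p - depth;
    const int *prev = code.data() + (size_t)depth * ne;
    int *cur = code.data() + (size_t)(depth + 1) * ne;
    for (int a = start; a + need <= C; ++a) {
      const int *col = cand + (size_t)a * ne;
      for (int r = 0; r < ne; ++r) cur[r] = prev[r] * k + col[r];
      sel[depth] = a;
      if (depth + 1 == p) {
        n_eval += 1.0;
        const double mi = leaf(cur);
        if (mi > best_mi) {  // strict: first subset in lexicographic order wins ties
          best_mi = mi;
          best = sel;
        }
      } else {
        rec(depth + 1, a + 1);
      }
    }
  }
};

}  // namespace

//' @keywords internal
// [[Rcpp::export(name = ".mit_best_subset")]]
List mit_best_subset(IntegerMatrix cand, IntegerVector child, int k, int p) {
  const int ne = cand.nrow(), C = cand.ncol();
  if (ne < 1) stop("empty data: no effective observations");
  if (child.size() != ne) stop("child length must match candidate rows");
  if (p < 1 || p > C) stop("invalid subset cardinality");
  double cells = std::pow((double)k, p) * k;
  if (cells > 2e9) stop("joint state space guard exceeded (k^p too large)");

  SubsetSearcher s;
  s.cand = INTEGER(cand);
  s.child = INTEGER(child);
  s.ne = ne;
  s.C = C;
  s.k = k;
  s.p = p;
  s.code.assign((size_t)(p + 1) * ne, 0);
  s.cnt_j.assign((size_t)std::pow((double)k, p), 0);
  s.cnt_jy.assign((size_t)std::pow((double)k, p) * k, 0);
  s.nlog.resize(ne + 1);
  s.nlog[0] = 0.0;
  for (int v = 1; v <= ne; ++v) s.nlog[v] = v * std::log((double)v);
  s.sel.assign(p, 0);
  s.best.assign(p, -1);
  s.lnne = std::log((double)ne);
  std::vector<int> cy(k, 0);
  for (int r = 0; r < ne; ++r) {
    const int y = s.child[r];
    if (y < 0 || y >= k) stop("child state out of range");
    ++cy[y];
  }
  s.sy = 0.0;
  for (int y = 0; y < k; ++y) s.sy += s.nlog[cy[y]];
  s.best_mi = -1.0;
  s.n_eval = 0.0;

  s.rec(0, 0);

  IntegerVector idx(p);
  for (int j = 0; j < p; ++j) idx[j] = s.best[j] + 1;  // 1-based for R
  return List::create(_["subset"] = idx, _["mi"] = s.best_mi,
                      _["n_evaluated"] = s.n_eval);
}

//' @keywords internal
// [[Rcpp::export(name = ".mit_pairwise_mi")]]
NumericVector mit_pairwise_mi(IntegerMatrix cand, IntegerVector child, int k) {
  const int ne = cand.nrow(), C = cand.ncol();
  if (ne < 1) stop("empty data: no effective observations");
  if (child.size() != ne) stop("child length must match candidate rows");
  std::vector<double> nlog(ne + 1);
  nlog[0] = 0.0;
  for (int v = 1; v <= ne; ++v) nlog[v] = v * std::log((double)v);
  std::vector<int> cy(k, 0);
  for (int r = 0; r < ne; ++r) ++cy[child[r]];
  double sy = 0.0;
  for (int y = 0; y < k; ++y) sy += nlog[cy[y]];
  const double lnne = std::log((double)ne);

  NumericVector out(C);
  std::vector<int> cj(k, 0), cjy((size_t)k * k, 0);
  const int *pc = INTEGER(cand);
  const int *py = INTEGER(child);
  for (int a = 0; a < C; ++a) {
    const int *col = pc + (size_t)a * ne;
    std::fill(cj.begin(), cj.end(), 0);
    std::fill(cjy.begin(), cjy.end(), 0);
    for (int r = 0; r < ne; ++r) {
      ++cj[col[r]];
      ++cjy[(size_t)col[r] * k + py[r]];
    }
    double sj = 0.0, sjy = 0.0;
    for (int c = 0; c < k; ++c) {
      sj += nlog[cj[c]];
      for (int y = 0; y < k; ++y) sjy += nlog[cjy[(size_t)c * k + y]];
    }
    out[a] = lnne + (sjy - sj - sy) / ne;
  }
  return out;
}
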