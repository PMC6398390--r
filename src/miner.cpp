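// Depth-first branch-and-bound search for the interval itemset with the
// largest absolute weighted cover sum  g(S) = | sum_{i in cover(S)} w_i |,
// the pricing oracle of the column-generation fit.  The prune bound
// max(sum of positive w in cover, -sum of negative w in cover) dominates
// g on every superset because covers only shrink as items are added.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct MineCtx {
  const LogicalMatrix* trans;   // n x m incidence
  const IntegerVector* feat;    // item -> feature id
  const IntegerVector* dir;     // item -> direction code (0 = LEQ, 1 = GEQ)
  const NumericVector* w;       // per-sample signed weight y_i * u_i
  int m, max_order;
  double best_gain;
  std::vector<int> best_items;
  std::vector<int> cur;
  long nodes;
  static const double EPS;

  void search(int start, const std::vector<int>& cover) {
    const LogicalMatrix& T = *trans;
    for (int q = start; q < m; ++q) {
      // an item repeating the feature+direction of one already chosen can
      // only duplicate or tighten redundantly; the tighter single item is
      // reachable elsewhere in the enumeration
      bool dup = false;
      for (size_t j = 0; j < cur.size(); ++j)
        if ((*feat)[cur[j]] == (*feat)[q] && (*dir)[cur[j]] == (*dir)[q]) {
          dup = true; break;
        }
      if (dup) continue;

      std::vector<int> nc;
      nc.reserve(cover.size());
      double pos = 0.0, neg = 0.0;
      for (size_t t = 0; t < cover.size(); ++t) {
        int i = cover[t];
        if (T(i, q)) {
          nc.push_back(i);
          double wi = (*w)[i];
          if (wi > 0.0) pos += wi; else neg += wi;
        }
      }
      ++nodes;
      if (nc.empty()) continue;
      double gain = std::fabs(pos + neg);
      double bound = pos > -neg ? pos : -neg;
      if (gain > best_gain + EPS) {
        best_gain = gain;
        cur.push_back(q);
        best_items = cur;
        cur.pop_back();
      }
      if ((int)cur.size() + 1 < max_order && bound > best_gain + EPS) {
        cur.push_back(q);
        search(q + 1, nc);
        cur.pop_back();
      }
    }
  }
};

const double MineCtx::EPS = 1e-12;

}  // namespace

// [[Rcpp::export(name = ".mine_best_itemset")]]
List mine_best_itemset(LogicalMatrix trans, NumericVector w,
                       IntegerVector feat, IntegerVector dir,
                       int max_order) {
  int n = trans.nrow(), m = trans.ncol();
  if (w.size() != n) stop("weight vector length must equal row count");
  if (feat.size() != m || dir.size() != m)
    stop("item annotations must match column count");
  if (max_order < 1) stop("max_order must be >= 1");

  MineCtx ctx;
  ctx.trans = &trans; ctx.feat = &feat; ctx.dir = &dir; ctx.w = &w;
  ctx.m = m; ctx.max_order = max_order;
  ctx.best_gain = 0.0; ctx.nodes = 0;

  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  ctx.search(0, all);

  IntegerVector items(ctx.best_items.size());
  for (size_t j = 0; j < ctx.best_items.size(); ++j)
    items[j] = ctx.best_items[j] + 1;  // 1-based for R
  return List::create(_["items"] = items, _["gain"] = ctx.best_gain,
                      _["nodes"] = (double)ctx.nodes);
}
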