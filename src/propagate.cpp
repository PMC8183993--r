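#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Seeded propagation over an intensity image.
//
// Every nucleus pixel is a source with cost 0 carrying its nucleus label.
// A step between 4-adjacent pixels p -> q costs sqrt((I(p)-I(q))^2 + lambda),
// so propagation follows iso-intensity paths when lambda is small and plain
// Euclidean growth when the image is flat. Each candidate pixel takes the
// label of the seed reachable at minimal cumulative cost (multi-source
// Dijkstra). Expansion is limited to paths of at most max_steps steps and to
// pixels whose intensity exceeds bg_threshold; seed pixels always keep their
// own label. Ties are resolved by (cost, label, column-major scan order) so
// the partition is deterministic and invariant to seed numbering.

struct Node {
  double cost;
  int label;
  int order;  // scan-order index, final tie-break
  int idx;
  int steps;
};

struct NodeCmp {
  bool operator()(const Node& a, const Node& b) const {
    if (a.cost != b.cost) return a.cost > b.cost;
    if (a.label != b.label) return a.label > b.label;
    return a.order > b.order;
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_propagate(const IntegerMatrix& seeds,
                            const NumericMatrix& intensity,
                            double lambda, double max_steps,
                            double bg_threshold) {
  const int nr = seeds.nrow(), nc = seeds.ncol(), n = nr * nc;
  std::vector<double> cost(n, R_PosInf);
  std::vector<int> label(n, 0);
  std::vector<bool> done(n, false);
  std::priority_queue<Node, std::vector<Node>, NodeCmp> pq;

  for (int idx = 0; idx < n; ++idx) {
    if (seeds[idx] > 0) {
      cost[idx] = 0.0;
      label[idx] = seeds[idx];
      pq.push({0.0, seeds[idx], idx, idx, 0});
    }
  }

  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};

  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    if (done[nd.idx]) continue;
    if (nd.cost > cost[nd.idx]) continue;          // stale entry
    if (nd.label != label[nd.idx]) continue;       // superseded on a tie
    done[nd.idx] = true;
    const int i = nd.idx % nr, j = nd.idx / nr;
    for (int k = 0; k < 4; ++k) {
      const int ii = i + di[k], jj = j + dj[k];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      const int q = ii + jj * nr;
      if (done[q] || seeds[q] > 0) continue;
      if (intensity[q] <= bg_threshold) continue;
      const int ns = nd.steps + 1;
      if (static_cast<double>(ns) > max_steps) continue;
      const double d = intensity[nd.idx] - intensity[q];
      const double ncost = nd.cost + std::sqrt(d * d + lambda);
      const bool better =
          (ncost < cost[q]) || (ncost == cost[q] && nd.label < label[q]);
      if (better) {
        cost[q] = ncost;
        label[q] = nd.label;
        pq.push({ncost, nd.label, q, q, ns});
      }
    }
  }

  IntegerMatrix out(nr, nc);
  for (int idx = 0; idx < n; ++idx) out[idx] = label[idx];
  return out;
}

// 8-connected components of a logical mask, labeled 1..K in column-major
// scan order of the first pixel encountered.

// [[Rcpp::export]]
IntegerMatrix cpp_label8(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol(), n = nr * nc;
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int start = 0; start < n; ++start) {
    if (!mask[start] || lab[start] != 0) continue;
    ++next;
    lab[start] = next;
    stack.assign(1, start);
    while (!stack.empty()) {
      const int c = stack.back();
      stack.pop_back();
      const int ci = c % nr, cj = c / nr;
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0) continue;
          const int ii = ci + di, jj = cj + dj;
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          const int q = ii + jj * nr;
          if (mask[q] && lab[q] == 0) {
            lab[q] = next;
            stack.push_back(q);
          }
        }
      }
    }
  }
  return lab;
}
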