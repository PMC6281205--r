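// Least-cost accumulation on the raster lattice.
//
// Graph convention: 8-connected lattice; a step between adjacent cells a,b
// costs mean(friction_a, friction_b) * edge_km, scaled by sqrt(2) for
// diagonal steps. Friction is R$/m3/km, so accumulated cost is R$/m3.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  double dist;
  int idx;
  bool operator<(const Node& o) const { return dist > o.dist; } // min-heap
};

const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
const double SQRT2 = 1.4142135623730951;

} // namespace

// Multi-source Dijkstra: accumulated transport cost from every cell to its
// cheapest center, plus the arg-min center id (areas of influence).
// [[Rcpp::export]]
List cpp_cost_distance(NumericMatrix friction, IntegerVector center_row,
                       IntegerVector center_col, IntegerVector center_id,
                       double edge_km) {
  const int nr = friction.nrow(), nc = friction.ncol(), n = nr * nc;
  std::vector<double> dist(n, R_PosInf);
  std::vector<int> alloc(n, NA_INTEGER);
  std::priority_queue<Node> pq;

  for (int k = 0; k < center_row.size(); ++k) {
    int idx = (center_row[k] - 1) + (center_col[k] - 1) * nr; // column-major
    if (dist[idx] > 0.0) {
      dist[idx] = 0.0;
      alloc[idx] = center_id[k];
      pq.push({0.0, idx});
    }
  }

  while (!pq.empty()) {
    Node cur = pq.top(); pq.pop();
    if (cur.dist > dist[cur.idx]) continue;
    int r = cur.idx % nr, c = cur.idx / nr;
    double f0 = friction[cur.idx];
    for (int d = 0; d < 8; ++d) {
      int rr = r + DR[d], cc = c + DC[d];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int j = rr + cc * nr;
      double len = (DR[d] != 0 && DC[d] != 0) ? edge_km * SQRT2 : edge_km;
      double nd = cur.dist + 0.5 * (f0 + friction[j]) * len;
      if (nd < dist[j]) {
        dist[j] = nd;
        alloc[j] = alloc[cur.idx];
        pq.push({nd, j});
      }
    }
  }

  NumericMatrix tc(nr, nc);
  IntegerMatrix am(nr, nc);
  for (int i = 0; i < n; ++i) { tc[i] = dist[i]; am[i] = alloc[i]; }
  return List::create(_["tc"] = tc, _["allocation"] = am);
}

// Early-exit Dijkstra from one target cell to the nearest cell flagged in
// `network`. Returns the path as 1-based (row, col) pairs from the target to
// the attachment cell inclusive, with the accumulated cost as an attribute.
// [[Rcpp::export]]
IntegerMatrix cpp_path_to_network(NumericMatrix friction, LogicalMatrix network,
                                  int target_row, int target_col, double edge_km) {
  const int nr = friction.nrow(), nc = friction.ncol(), n = nr * nc;
  const int start = (target_row - 1) + (target_col - 1) * nr;
  std::vector<double> dist(n, R_PosInf);
  std::vector<int> prev(n, -1);
  std::priority_queue<Node> pq;
  dist[start] = 0.0;
  pq.push({0.0, start});
  int hit = -1;

  if (network[start]) hit = start;
  while (hit < 0 && !pq.empty()) {
    Node cur = pq.top(); pq.pop();
    if (cur.dist > dist[cur.idx]) continue;
    if (network[cur.idx]) { hit = cur.idx; break; }
    int r = cur.idx % nr, c = cur.idx / nr;
    double f0 = friction[cur.idx];
    for (int d = 0; d < 8; ++d) {
      int rr = r + DR[d], cc = c + DC[d];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int j = rr + cc * nr;
      double len = (DR[d] != 0 && DC[d] != 0) ? edge_km * SQRT2 : edge_km;
      double nd = cur.dist + 0.5 * (f0 + friction[j]) * len;
      if (nd < dist[j]) {
        dist[j] = nd;
        prev[j] = cur.idx;
        pq.push({nd, j});
      }
    }
  }

  if (hit < 0) return IntegerMatrix(0, 2); // disconnected (cannot happen on a full lattice)

  std::vector<int> cells;
  for (int i = hit; i >= 0; i = prev[i]) cells.push_back(i);
  std::reverse(cells.begin(), cells.end()); // target first
  IntegerMatrix path(cells.size(), 2);
  for (size_t k = 0; k < cells.size(); ++k) {
    path(k, 0) = cells[k] % nr + 1;
    path(k, 1) = cells[k] / nr + 1;
  }
  path.attr("cost") = dist[hit];
  return path;
}
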