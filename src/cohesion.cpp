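#include <Rcpp.h>
#include <algorithm>
#include <deque>
#include <vector>
using namespace Rcpp;

// Cohesion-matrix dynamic programme and integrated-tree reconstruction with
// the greedy maximal-matching kernel. Vertices are 1..n in BFS order (parent
// index strictly smaller than child index); 0 is the virtual root. The
// cohesion matrix g is (n_a+1) x (n_b+1) with row/col 0 for the virtual
// roots; g(i,j) is the best total closeness achievable when integrating the
// subtree of A rooted at i with the subtree of B rooted at j.

namespace {

struct Edge {
  double w;
  int x, y;
};

// heaviest first; ties by left vertex index then right vertex index, so the
// matching replayed during reconstruction is identical to the one scored
// during the forward pass
inline bool edge_before(const Edge& a, const Edge& b) {
  if (a.w != b.w) return a.w > b.w;
  if (a.x != b.x) return a.x < b.x;
  return a.y < b.y;
}

std::vector<std::vector<int> > children_of(const IntegerVector& parent) {
  int n = parent.size();
  std::vector<std::vector<int> > ch(n + 1);
  for (int v = 1; v <= n; ++v) {
    int p = parent[v - 1];
    if (p < 0 || p >= v) stop("parent indices must precede children");
    ch[p].push_back(v); // ascending since v increases
  }
  return ch;
}

// greedy maximal matching over the positive-weight bipartite graph between
// two child forests; returns the total and fills matched pairs
double greedy_match(const std::vector<int>& ci, const std::vector<int>& cj,
                    const NumericMatrix& g,
                    std::vector<std::pair<int, int> >* pairs) {
  std::vector<Edge> edges;
  edges.reserve(ci.size() * cj.size());
  for (size_t a = 0; a < ci.size(); ++a)
    for (size_t b = 0; b < cj.size(); ++b) {
      double w = g(ci[a], cj[b]);
      if (w > 0) edges.push_back(Edge{w, ci[a], cj[b]});
    }
  std::sort(edges.begin(), edges.end(), edge_before);
  double total = 0.0;
  std::vector<int> used_x, used_y;
  for (size_t e = 0; e < edges.size(); ++e) {
    const Edge& ed = edges[e];
    bool free_x = std::find(used_x.begin(), used_x.end(), ed.x) == used_x.end();
    bool free_y = std::find(used_y.begin(), used_y.end(), ed.y) == used_y.end();
    if (free_x && free_y) {
      used_x.push_back(ed.x);
      used_y.push_back(ed.y);
      total += ed.w;
      if (pairs) pairs->push_back(std::make_pair(ed.x, ed.y));
    }
  }
  return total;
}

inline double closeness_entry(const NumericMatrix& M, int i, int j) {
  return (i > 0 && j > 0) ? M(i - 1, j - 1) : 0.0;
}

struct Builder {
  std::vector<int> na, nb, np; // member vertex of A / of B (-1 absent), parent node
  int add(int a, int b, int parent) {
    na.push_back(a);
    nb.push_back(b);
    np.push_back(parent);
    return (int)na.size(); // 1-based node id
  }
  // attach a whole source subtree as singleton nodes (BFS order)
  void attach_subtree(int root, int parent, bool from_a,
                      const std::vector<std::vector<int> >& ch) {
    std::deque<std::pair<int, int> > q;
    q.push_back(std::make_pair(root, parent));
    while (!q.empty()) {
      std::pair<int, int> cur = q.front();
      q.pop_front();
      int id = from_a ? add(cur.first, -1, cur.second)
                      : add(-1, cur.first, cur.second);
      const std::vector<int>& kids = ch[cur.first];
      for (size_t k = 0; k < kids.size(); ++k)
        q.push_back(std::make_pair(kids[k], id));
    }
  }
};

} // namespace

// [[Rcpp::export]]
List cohesion_dp_greedy_cpp(IntegerVector parent_a, IntegerVector parent_b,
                            NumericMatrix M, bool reconstruct) {
  const int na = parent_a.size(), nb = parent_b.size();
  if (M.nrow() != na || M.ncol() != nb) stop("closeness dimension mismatch");
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j) {
      double w = M(i, j);
      if (ISNAN(w) || w < 0 || !R_finite(w)) stop("negative closeness");
    }
  std::vector<std::vector<int> > cha = children_of(parent_a);
  std::vector<std::vector<int> > chb = children_of(parent_b);
  NumericMatrix g(na + 1, nb + 1);

  for (int i = na; i >= 0; --i) {
    const std::vector<int>& ci = cha[i];
    for (int j = nb; j >= 0; --j) {
      const std::vector<int>& cj = chb[j];
      double score = closeness_entry(M, i, j);
      if (!ci.empty() && !cj.empty()) score += greedy_match(ci, cj, g, NULL);
      double sa = 0.0, sb = 0.0;
      for (size_t y = 0; y < cj.size(); ++y) sa = std::max(sa, g(i, cj[y]));
      for (size_t x = 0; x < ci.size(); ++x) sb = std::max(sb, g(ci[x], j));
      g(i, j) = std::max(score, std::max(sa, sb));
    }
  }

  if (!reconstruct) return List::create(_["g"] = g);

  // breadth-first reconstruction replaying the same matchings; at each
  // queued subtree pair the attaining case is re-derived in the fixed order
  // merge > descend-right > descend-left
  const double tol = 1e-9;
  Builder bl;
  std::deque<std::pair<std::pair<int, int>, int> > q; // ((a, b), parent node)
  q.push_back(std::make_pair(std::make_pair(0, 0), 0));
  while (!q.empty()) {
    int a = q.front().first.first;
    int b = q.front().first.second;
    int par = q.front().second;
    q.pop_front();
    double val = g(a, b);
    const std::vector<int>& ci = cha[a];
    const std::vector<int>& cj = chb[b];

    std::vector<std::pair<int, int> > pairs;
    double score = closeness_entry(M, a, b);
    if (!ci.empty() && !cj.empty()) score += greedy_match(ci, cj, g, &pairs);
    if (std::fabs(score - val) <= tol) {
      int id = bl.add(a, b, par);
      std::vector<bool> ma(ci.size(), false), mb(cj.size(), false);
      for (size_t p = 0; p < pairs.size(); ++p) {
        q.push_back(std::make_pair(pairs[p], id));
        for (size_t x = 0; x < ci.size(); ++x)
          if (ci[x] == pairs[p].first) ma[x] = true;
        for (size_t y = 0; y < cj.size(); ++y)
          if (cj[y] == pairs[p].second) mb[y] = true;
      }
      for (size_t x = 0; x < ci.size(); ++x)
        if (!ma[x]) bl.attach_subtree(ci[x], id, true, cha);
      for (size_t y = 0; y < cj.size(); ++y)
        if (!mb[y]) bl.attach_subtree(cj[y], id, false, chb);
      continue;
    }
    bool done = false;
    for (size_t y = 0; y < cj.size() && !done; ++y) { // descend right
      if (std::fabs(g(a, cj[y]) - val) <= tol) {
        if (b == 0) stop("reconstruction attempted to split a virtual root");
        int id = bl.add(-1, b, par);
        q.push_back(std::make_pair(std::make_pair(a, cj[y]), id));
        for (size_t y2 = 0; y2 < cj.size(); ++y2)
          if (y2 != y) bl.attach_subtree(cj[y2], id, false, chb);
        done = true;
      }
    }
    if (done) continue;
    for (size_t x = 0; x < ci.size() && !done; ++x) { // descend left
      if (std::fabs(g(ci[x], b) - val) <= tol) {
        if (a == 0) stop("reconstruction attempted to split a virtual root");
        int id = bl.add(a, -1, par);
        q.push_back(std::make_pair(std::make_pair(ci[x], b), id));
        for (size_t x2 = 0; x2 < ci.size(); ++x2)
          if (x2 != x) bl.attach_subtree(ci[x2], id, true, cha);
        done = true;
      }
    }
    if (!done) stop("reconstruction failed: no case reproduces entry value");
  }

  return List::create(
      _["g"] = g,
      _["node_a"] = IntegerVector(bl.na.begin(), bl.na.end()),
      _["node_b"] = IntegerVector(bl.nb.begin(), bl.nb.end()),
      _["node_parent"] = IntegerVector(bl.np.begin(), bl.np.end()));
}
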