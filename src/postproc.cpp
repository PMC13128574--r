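// Instance post-processing kernels on (D, H, W) label/probability volumes
// (R column-major: depth index fastest).  6-connectivity throughout.

#include <Rcpp.h>
#include <queue>
#include <tuple>
using namespace Rcpp;

struct Nbr { long off; int axis; };

static std::vector<long> neighbor_offsets(long D, long H) {
  // +/- d, +/- h, +/- w
  return { -1, +1, -D, +D, -D * H, +D * H };
}

static inline void coords(long v, long D, long H, long& d, long& h, long& w) {
  d = v % D; h = (v / D) % H; w = v / (D * H);
}

// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  long D = dims[0], H = dims[1], W = dims[2], n = D * H * W;
  IntegerVector lab(n);
  lab.attr("dim") = dims;
  std::vector<long> stack;
  int next = 0;
  for (long v0 = 0; v0 < n; ++v0) {
    if (!mask[v0] || lab[v0] != 0) continue;
    ++next;
    lab[v0] = next;
    stack.push_back(v0);
    while (!stack.empty()) {
      long v = stack.back(); stack.pop_back();
      long d, h, w; coords(v, D, H, d, h, w);
      long nb[6]; bool ok[6];
      nb[0] = v - 1;     ok[0] = d > 0;
      nb[1] = v + 1;     ok[1] = d < D - 1;
      nb[2] = v - D;     ok[2] = h > 0;
      nb[3] = v + D;     ok[3] = h < H - 1;
      nb[4] = v - D * H; ok[4] = w > 0;
      nb[5] = v + D * H; ok[5] = w < W - 1;
      for (int k = 0; k < 6; ++k)
        if (ok[k] && mask[nb[k]] && lab[nb[k]] == 0) {
          lab[nb[k]] = next;
          stack.push_back(nb[k]);
        }
    }
  }
  return lab;
}

// Marker-controlled priority flood: grow markers over `mask` in order of
// increasing elevation; deterministic via an insertion counter tie-break.
// [[Rcpp::export]]
IntegerVector watershed_flood_cpp(NumericVector elev, IntegerVector markers,
                                  LogicalVector mask, IntegerVector dims) {
  long D = dims[0], H = dims[1], W = dims[2], n = D * H * W;
  IntegerVector lab(n);
  lab.attr("dim") = dims;
  typedef std::tuple<double, long, long> Item;  // (elev, counter, voxel)
  std::priority_queue<Item, std::vector<Item>, std::greater<Item> > pq;
  long counter = 0;
  for (long v = 0; v < n; ++v)
    if (markers[v] > 0) {
      lab[v] = markers[v];
      pq.push(Item(elev[v], counter++, v));
    }
  while (!pq.empty()) {
    long v = std::get<2>(pq.top()); pq.pop();
    long d, h, w; coords(v, D, H, d, h, w);
    long nb[6]; bool ok[6];
    nb[0] = v - 1;     ok[0] = d > 0;
    nb[1] = v + 1;     ok[1] = d < D - 1;
    nb[2] = v - D;     ok[2] = h > 0;
    nb[3] = v + D;     ok[3] = h < H - 1;
    nb[4] = v - D * H; ok[4] = w > 0;
    nb[5] = v + D * H; ok[5] = w < W - 1;
    for (int k = 0; k < 6; ++k)
      if (ok[k] && mask[nb[k]] && lab[nb[k]] == 0) {
        lab[nb[k]] = lab[v];
        pq.push(Item(elev[nb[k]], counter++, nb[k]));
      }
  }
  return lab;
}

struct DSU {
  std::vector<long> parent;
  DSU(long n) : parent(n) { for (long i = 0; i < n; ++i) parent[i] = i; }
  long find(long x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(long a, long b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  }
};

// Greedy agglomeration over nearest-neighbour affinity edges, strongest
// first; ties broken by voxel index then axis.  Voxels with no incident
// supra-threshold edge become background.
// aff: (3, D, H, W) with channel 1 = z (-d), 2 = y (-h), 3 = x (-w).
// [[Rcpp::export]]
IntegerVector affinity_agglomerate_cpp(NumericVector aff, IntegerVector dims,
                                       double threshold) {
  long D = dims[0], H = dims[1], W = dims[2], n = D * H * W;
  struct Edge { double a; long v; int axis; };
  std::vector<Edge> edges;
  const double* ap = aff.begin();
  for (long w = 0; w < W; ++w)
    for (long h = 0; h < H; ++h)
      for (long d = 0; d < D; ++d) {
        long v = d + D * (h + H * w);
        for (int k = 0; k < 3; ++k) {
          bool valid = (k == 0 && d > 0) || (k == 1 && h > 0) || (k == 2 && w > 0);
          if (!valid) continue;
          double a = ap[k + 3 * v];
          if (a > threshold) edges.push_back({a, v, k});
        }
      }
  std::stable_sort(edges.begin(), edges.end(),
                   [](const Edge& x, const Edge& y) {
                     if (x.a != y.a) return x.a > y.a;
                     if (x.v != y.v) return x.v < y.v;
                     return x.axis < y.axis;
                   });
  DSU dsu(n);
  std::vector<char> touched(n, 0);
  long offs[3] = {1, D, D * H};
  for (const Edge& e : edges) {
    long u = e.v - offs[e.axis];
    dsu.unite(e.v, u);
    touched[e.v] = 1; touched[u] = 1;
  }
  IntegerVector lab(n);
  lab.attr("dim") = dims;
  std::vector<int> root_label(n, 0);
  int next = 0;
  for (long v = 0; v < n; ++v) {
    if (!touched[v]) continue;
    long r = dsu.find(v);
    if (root_label[r] == 0) root_label[r] = ++next;
    lab[v] = root_label[r];
  }
  return lab;
}

// Pairwise Rand agreement counts from two labelings, used as the brute-force
// oracle is in R; this is the production path via sums of squares.
// [[Rcpp::export]]
IntegerVector relabel_consecutive_cpp(IntegerVector lab) {
  long n = lab.size();
  IntegerVector out(n);
  out.attr("dim") = lab.attr("dim");
  std::map<int, int> m;
  int next = 0;
  for (long i = 0; i < n; ++i) {
    int v = lab[i];
    if (v == 0) { out[i] = 0; continue; }
    auto it = m.find(v);
    if (it == m.end()) { m[v] = ++next; out[i] = next; }
    else out[i] = it->second;
  }
  return out;
}
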