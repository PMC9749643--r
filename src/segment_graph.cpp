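#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Disjoint-set forest with union by size and path compression, tracking the
// internal difference (max MST edge weight) of each component for the
// graph-based oversegmentation.
struct DSF {
  std::vector<int> parent;
  std::vector<int> size;
  explicit DSF(int n) : parent(n), size(n, 1) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    int r = x;
    while (parent[r] != r) r = parent[r];
    while (parent[x] != r) { int nx = parent[x]; parent[x] = r; x = nx; }
    return r;
  }
  int join(int a, int b) {
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a;
    size[a] += size[b];
    return a;
  }
};

struct Edge { float w; int a, b; };

// Graph-based image oversegmentation (grid graph, 8-connectivity, absolute
// intensity difference edge weights, adaptive threshold tau(C) = scale/|C|),
// followed by a small-component merge pass. Returns a 1-based label matrix
// with contiguous labels.
// [[Rcpp::export(name = ".fh_segment")]]
IntegerMatrix fh_segment(NumericMatrix img, double scale, int min_size) {
  const int H = img.nrow(), W = img.ncol();
  if (H * W == 0) stop("empty image");
  std::vector<Edge> edges;
  edges.reserve(static_cast<size_t>(4) * H * W);
  auto id = [W, H](int r, int c) { return r + c * H; };  // column-major
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double v = img(r, c);
      if (r + 1 < H)
        edges.push_back({(float)std::fabs(v - img(r + 1, c)), id(r, c), id(r + 1, c)});
      if (c + 1 < W)
        edges.push_back({(float)std::fabs(v - img(r, c + 1)), id(r, c), id(r, c + 1)});
      if (r + 1 < H && c + 1 < W)
        edges.push_back({(float)std::fabs(v - img(r + 1, c + 1)), id(r, c), id(r + 1, c + 1)});
      if (r + 1 < H && c > 0)
        edges.push_back({(float)std::fabs(v - img(r + 1, c - 1)), id(r, c), id(r + 1, c - 1)});
    }
  }
  std::stable_sort(edges.begin(), edges.end(),
                   [](const Edge& x, const Edge& y) { return x.w < y.w; });
  const int n = H * W;
  DSF dsf(n);
  std::vector<float> internal(n, 0.0f);
  for (const Edge& e : edges) {
    int a = dsf.find(e.a), b = dsf.find(e.b);
    if (a == b) continue;
    float ta = internal[a] + (float)(scale / dsf.size[a]);
    float tb = internal[b] + (float)(scale / dsf.size[b]);
    if (e.w <= std::min(ta, tb)) {
      int r = dsf.join(a, b);
      internal[r] = e.w;
    }
  }
  // merge components smaller than min_size along the sorted edges
  for (const Edge& e : edges) {
    int a = dsf.find(e.a), b = dsf.find(e.b);
    if (a != b && (dsf.size[a] < min_size || dsf.size[b] < min_size))
      dsf.join(a, b);
  }
  IntegerMatrix lab(H, W);
  std::vector<int> remap(n, 0);
  int next = 0;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      int root = dsf.find(id(r, c));
      if (remap[root] == 0) remap[root] = ++next;
      lab(r, c) = remap[root];
    }
  return lab;
}
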