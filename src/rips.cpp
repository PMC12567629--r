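// Vietoris-Rips persistent homology over Z/2, homology dimensions 0 and 1.
//
// H0 pairs come from a union-find sweep over edges sorted by length (a
// Kruskal pass: every merging edge kills one component at its length).
// H1 pairs come from reducing the triangle boundary matrix against edges in
// filtration order; by the standard pairing theorem the (edge, triangle)
// pivots of the reduced dimension-2 boundary are exactly the finite H1
// pairs, so the dimension-1 reduction never needs to run. Columns are kept
// as sorted index vectors and added by symmetric difference.
//
// Complexity is O(n^3) triangles in the worst case, intended for point
// clouds of up to a few hundred points (callers subsample larger clouds).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <unordered_map>
#include <vector>

namespace {

struct UF {
  std::vector<int> parent;
  explicit UF(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    parent[std::max(a, b)] = std::min(a, b);
    return true;
  }
};

// Z/2 column addition: symmetric difference of sorted vectors.
void xor_into(std::vector<int>& a, const std::vector<int>& b) {
  std::vector<int> out;
  out.reserve(a.size() + b.size());
  std::set_symmetric_difference(a.begin(), a.end(), b.begin(), b.end(),
                                std::back_inserter(out));
  a.swap(out);
}

}  // namespace

// D: full symmetric distance matrix; thresh: max filtration value (Inf = full
// complex). Returns list(h0 = (birth, death) matrix, h1 = matrix); essential
// classes carry death = Inf.
// [[Rcpp::export(name = ".rips_pairs")]]
Rcpp::List rips_pairs(Rcpp::NumericMatrix D, int maxdim, double thresh) {
  const int n = D.nrow();
  if (D.ncol() != n) Rcpp::stop("distance matrix must be square");
  if (maxdim < 0 || maxdim > 1)
    Rcpp::stop("homology dimensions 0 and 1 are supported (got max_dim = %d)",
               maxdim);

  struct Edge { double d; int i, j; };
  std::vector<Edge> edges;
  edges.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (D(i, j) <= thresh) edges.push_back({D(i, j), i, j});
  std::sort(edges.begin(), edges.end(), [](const Edge& a, const Edge& b) {
    if (a.d != b.d) return a.d < b.d;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  const int m = (int)edges.size();

  // ---- H0 ----
  std::vector<double> h0_death;
  UF uf(n);
  std::vector<char> merges(m, 0);
  for (int e = 0; e < m; ++e) {
    if (uf.unite(edges[e].i, edges[e].j)) {
      merges[e] = 1;
      h0_death.push_back(edges[e].d);
    }
  }
  int n_comp = n - (int)h0_death.size();  // essential components
  Rcpp::NumericMatrix h0((int)h0_death.size() + n_comp, 2);
  for (size_t r = 0; r < h0_death.size(); ++r) {
    h0(r, 0) = 0.0;
    h0(r, 1) = h0_death[r];
  }
  for (int r = 0; r < n_comp; ++r) {
    h0(h0_death.size() + r, 0) = 0.0;
    h0(h0_death.size() + r, 1) = R_PosInf;
  }

  Rcpp::NumericMatrix h1(0, 2);
  if (maxdim >= 1 && n >= 3) {
    // edge index lookup (sorted order)
    std::unordered_map<long long, int> eidx;
    eidx.reserve(edges.size() * 2);
    for (int e = 0; e < m; ++e)
      eidx[(long long)edges[e].i * n + edges[e].j] = e;

    struct Tri { double val; int e1, e2, e3; };  // e1<e2<e3 sorted indices
    std::vector<Tri> tris;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (D(i, j) > thresh) continue;
        for (int k = j + 1; k < n; ++k) {
          if (D(i, k) > thresh || D(j, k) > thresh) continue;
          int a = eidx[(long long)i * n + j];
          int b = eidx[(long long)i * n + k];
          int c = eidx[(long long)j * n + k];
          int e3 = std::max({a, b, c});
          int e1 = std::min({a, b, c});
          int e2 = a + b + c - e1 - e3;
          tris.push_back({std::max({edges[a].d, edges[b].d, edges[c].d}),
                          e1, e2, e3});
        }
      }
    std::sort(tris.begin(), tris.end(), [](const Tri& a, const Tri& b) {
      if (a.val != b.val) return a.val < b.val;
      if (a.e3 != b.e3) return a.e3 < b.e3;
      if (a.e2 != b.e2) return a.e2 < b.e2;
      return a.e1 < b.e1;
    });

    std::unordered_map<int, int> pivot;  // low edge -> reduced column id
    std::vector<std::vector<int>> cols;
    std::vector<double> birth, death;
    std::vector<char> paired(m, 0);
    for (const Tri& t : tris) {
      std::vector<int> col = {t.e1, t.e2, t.e3};
      while (!col.empty()) {
        auto it = pivot.find(col.back());
        if (it == pivot.end()) break;
        xor_into(col, cols[it->second]);
      }
      if (col.empty()) continue;
      const int low = col.back();
      pivot[low] = (int)cols.size();
      cols.push_back(std::move(col));
      paired[low] = 1;
      if (t.val > edges[low].d) {
        birth.push_back(edges[low].d);
        death.push_back(t.val);
      }
    }
    // essential H1 classes: cycle-creating edges never killed by a triangle
    std::vector<double> ess;
    for (int e = 0; e < m; ++e)
      if (!merges[e] && !paired[e]) ess.push_back(edges[e].d);
    h1 = Rcpp::NumericMatrix((int)birth.size() + (int)ess.size(), 2);
    for (size_t r = 0; r < birth.size(); ++r) {
      h1(r, 0) = birth[r];
      h1(r, 1) = death[r];
    }
    for (size_t r = 0; r < ess.size(); ++r) {
      h1(birth.size() + r, 0) = ess[r];
      h1(birth.size() + r, 1) = R_PosInf;
    }
  }

  return Rcpp::List::create(Rcpp::Named("h0") = h0, Rcpp::Named("h1") = h1);
}
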