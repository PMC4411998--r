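#include <Rcpp.h>
#include <vector>
#include <queue>
#include <unordered_map>
using namespace Rcpp;

// Voxel arrays are passed as flat vectors in R array order:
// linear index = i + nx*(j + ny*k), all 0-based here.

static inline long long lindex(int i, int j, int k, int nx, int ny) {
  return (long long)i + (long long)nx * ((long long)j + (long long)ny * k);
}

// 26-neighborhood offsets (excluding origin), fixed order.
static const int OFF26[26][3] = {
  {-1,-1,-1},{0,-1,-1},{1,-1,-1},{-1,0,-1},{0,0,-1},{1,0,-1},{-1,1,-1},{0,1,-1},{1,1,-1},
  {-1,-1,0},{0,-1,0},{1,-1,0},{-1,0,0},{1,0,0},{-1,1,0},{0,1,0},{1,1,0},
  {-1,-1,1},{0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},{1,0,1},{-1,1,1},{0,1,1},{1,1,1}
};

// [[Rcpp::export]]
IntegerVector cpp_label_components26(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long long n = (long long)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<long long> stack;
  for (long long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      long long v = stack.back(); stack.pop_back();
      int k = (int)(v / ((long long)nx * ny));
      long long r = v % ((long long)nx * ny);
      int j = (int)(r / nx), i = (int)(r % nx);
      for (int o = 0; o < 26; ++o) {
        int ii = i + OFF26[o][0], jj = j + OFF26[o][1], kk = k + OFF26[o][2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        long long w = lindex(ii, jj, kk, nx, ny);
        if (mask[w] && lab[w] == 0) { lab[w] = next; stack.push_back(w); }
      }
    }
  }
  return lab;
}

// --- simple-point machinery for (26,6) thinning ------------------------------

// Gather the 3x3x3 occupancy around (i,j,k); cube[13] is the center.
static inline void neighborhood(const std::vector<char>& fg, int i, int j, int k,
                                int nx, int ny, int nz, char cube[27]) {
  int t = 0;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di, ++t) {
        int ii = i + di, jj = j + dj, kk = k + dk;
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          cube[t] = 0;
        else
          cube[t] = fg[lindex(ii, jj, kk, nx, ny)];
      }
}

// Number of 26-connected foreground components in N26 (cube minus center).
static int count_fg_components26(const char cube[27]) {
  char seen[27] = {0};
  int comps = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !cube[s] || seen[s]) continue;
    ++comps;
    std::vector<int> st(1, s);
    seen[s] = 1;
    while (!st.empty()) {
      int v = st.back(); st.pop_back();
      int vz = v / 9, vy = (v % 9) / 3, vx = v % 3;
      for (int w = 0; w < 27; ++w) {
        if (w == 13 || !cube[w] || seen[w]) continue;
        int wz = w / 9, wy = (w % 9) / 3, wx = w % 3;
        int dx = wx - vx, dy = wy - vy, dz = wz - vz;
        if (dx >= -1 && dx <= 1 && dy >= -1 && dy <= 1 && dz >= -1 && dz <= 1) {
          seen[w] = 1; st.push_back(w);
        }
      }
    }
  }
  return comps;
}

// Number of 6-connected background components within N18 that touch a face
// neighbor of the center (the standard background condition for (26,6)).
static int count_bg_components6(const char cube[27]) {
  // N18: cells with Manhattan distance <= 2 from center, excluding corners
  // and the center itself.
  char in18[27], seen[27] = {0};
  for (int s = 0; s < 27; ++s) {
    int sz = s / 9 - 1, sy = (s % 9) / 3 - 1, sx = s % 3 - 1;
    int man = (sx < 0 ? -sx : sx) + (sy < 0 ? -sy : sy) + (sz < 0 ? -sz : sz);
    in18[s] = (s != 13 && man <= 2) ? 1 : 0;
  }
  int comps = 0;
  for (int s = 0; s < 27; ++s) {
    if (!in18[s] || cube[s] || seen[s]) continue;
    // grow the 6-connected background component containing s within N18
    std::vector<int> st(1, s);
    seen[s] = 1;
    bool touches_face = false;
    while (!st.empty()) {
      int v = st.back(); st.pop_back();
      int vz = v / 9 - 1, vy = (v % 9) / 3 - 1, vx = v % 3 - 1;
      int man = (vx < 0 ? -vx : vx) + (vy < 0 ? -vy : vy) + (vz < 0 ? -vz : vz);
      if (man == 1) touches_face = true;
      for (int w = 0; w < 27; ++w) {
        if (!in18[w] || cube[w] || seen[w]) continue;
        int wz = w / 9 - 1, wy = (w % 9) / 3 - 1, wx = w % 3 - 1;
        int ad = (wx - vx) * (wx - vx) + (wy - vy) * (wy - vy) + (wz - vz) * (wz - vz);
        if (ad == 1) { seen[w] = 1; st.push_back(w); }
      }
    }
    if (touches_face) ++comps;
  }
  return comps;
}

static inline bool is_simple(const char cube[27]) {
  return count_fg_components26(cube) == 1 && count_bg_components6(cube) == 1;
}

static inline int n_fg_neighbors(const char cube[27]) {
  int c = 0;
  for (int s = 0; s < 27; ++s) if (s != 13 && cube[s]) ++c;
  return c;
}

// Sequential directional thinning with (26,6) simple-point deletion and
// endpoint preservation; returns a 1-voxel-thick curve skeleton.
// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long long n = (long long)nx * ny * nz;
  std::vector<char> fg(n);
  for (long long s = 0; s < n; ++s) fg[s] = mask[s] ? 1 : 0;

  const int FACE[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};
  char cube[27];
  bool changed = true;
  // subfield thinning: each pass visits the 8 parity octants in turn, so
  // voxels deleted in one subiteration are never face-adjacent, which
  // stops a sweep from eating axially through a thin column; sequential
  // re-checks at deletion time keep the topology exact
  while (changed) {
    changed = false;
    for (int sf = 0; sf < 8; ++sf) {
      const int pi = sf & 1, pj = (sf >> 1) & 1, pk = (sf >> 2) & 1;
      std::vector<long long> cand;
      for (long long s = 0; s < n; ++s) {
        if (!fg[s]) continue;
        int k = (int)(s / ((long long)nx * ny));
        long long r = s % ((long long)nx * ny);
        int j = (int)(r / nx), i = (int)(r % nx);
        if ((i & 1) != pi || (j & 1) != pj || (k & 1) != pk) continue;
        bool border = false;
        for (int d = 0; d < 6 && !border; ++d) {
          int ii = i + FACE[d][0], jj = j + FACE[d][1], kk = k + FACE[d][2];
          border = (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) ||
                   !fg[lindex(ii, jj, kk, nx, ny)];
        }
        if (!border) continue;
        neighborhood(fg, i, j, k, nx, ny, nz, cube);
        if (n_fg_neighbors(cube) <= 1) continue;  // endpoint: keep
        if (is_simple(cube)) cand.push_back(s);
      }
      for (long long s : cand) {
        int k = (int)(s / ((long long)nx * ny));
        long long r = s % ((long long)nx * ny);
        int j = (int)(r / nx), i = (int)(r % nx);
        neighborhood(fg, i, j, k, nx, ny, nz, cube);
        if (n_fg_neighbors(cube) <= 1) continue;
        if (is_simple(cube)) { fg[s] = 0; changed = true; }
      }
    }
  }
  LogicalVector out(n);
  for (long long s = 0; s < n; ++s) out[s] = fg[s] != 0;
  return out;
}

// HU-gated layer growing around a labeled skeleton.
// comp/ord: 0 = unassigned, compartment 1=lower 2=upper 3=stem-seed,
// order 1=primary 2=secondary. layer: -1 = unassigned, 0 = skeleton voxel.
// Growth claims voxels one layer at a time; within a layer, source voxels are
// visited in ascending linear index so the lowest-index claim wins ties.
// [[Rcpp::export]]
List cpp_expand_layers(NumericVector hu, IntegerVector comp, IntegerVector ord,
                       IntegerVector layer, LogicalVector excluded,
                       IntegerVector dims, NumericVector hu_max_by_order,
                       IntegerVector max_layers_by_order) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long long n = (long long)nx * ny * nz;
  IntegerVector comp_out = clone(comp), ord_out = clone(ord), layer_out = clone(layer);
  int max_layers = 0;
  for (int o = 0; o < max_layers_by_order.size(); ++o)
    if (max_layers_by_order[o] > max_layers) max_layers = max_layers_by_order[o];

  std::vector<long long> frontier;
  for (long long s = 0; s < n; ++s)
    if (layer_out[s] == 0) frontier.push_back(s);

  for (int L = 1; L <= max_layers; ++L) {
    std::vector<long long> next;
    for (long long s : frontier) {
      int o = ord_out[s];
      if (o < 1 || o > max_layers_by_order.size()) continue;
      if (L > max_layers_by_order[o - 1]) continue;
      double cap = hu_max_by_order[o - 1];
      int k = (int)(s / ((long long)nx * ny));
      long long r = s % ((long long)nx * ny);
      int j = (int)(r / nx), i = (int)(r % nx);
      for (int t = 0; t < 26; ++t) {
        int ii = i + OFF26[t][0], jj = j + OFF26[t][1], kk = k + OFF26[t][2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        long long w = lindex(ii, jj, kk, nx, ny);
        if (layer_out[w] != -1 || excluded[w]) continue;
        if (hu[w] > cap) continue;
        layer_out[w] = L;
        comp_out[w] = comp_out[s];
        ord_out[w] = o;
        next.push_back(w);
      }
    }
    frontier.swap(next);
  }
  return List::create(_["compartment"] = comp_out, _["order"] = ord_out,
                      _["layer"] = layer_out);
}

// 26-adjacency edge list for a set of voxels given as 0-based (i,j,k) rows.
// Returns 1-based row index pairs (a, b) with a < b.
// [[Rcpp::export]]
IntegerMatrix cpp_adjacency_pairs(IntegerMatrix coords, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nv = coords.nrow();
  std::unordered_map<long long, int> where;
  where.reserve(nv * 2);
  for (int v = 0; v < nv; ++v)
    where[lindex(coords(v, 0), coords(v, 1), coords(v, 2), nx, ny)] = v;
  std::vector<int> a, b;
  for (int v = 0; v < nv; ++v) {
    int i = coords(v, 0), j = coords(v, 1), k = coords(v, 2);
    for (int t = 0; t < 26; ++t) {
      int ii = i + OFF26[t][0], jj = j + OFF26[t][1], kk = k + OFF26[t][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      long long w = lindex(ii, jj, kk, nx, ny);
      auto it = where.find(w);
      if (it != where.end() && it->second > v) {
        a.push_back(v + 1);
        b.push_back(it->second + 1);
      }
    }
  }
  IntegerMatrix out(a.size(), 2);
  for (size_t e = 0; e < a.size(); ++e) { out(e, 0) = a[e]; out(e, 1) = b[e]; }
  return out;
}
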