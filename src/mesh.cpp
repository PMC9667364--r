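#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <array>
#include <cstdint>
#include <queue>
using namespace Rcpp;

// Isosurface extraction from a binary voxel mask by marching tetrahedra.
// Each grid cell (8 voxel centers) is split into 6 tetrahedra sharing the
// main diagonal; the 0/1 field is interpolated at level 0.5, so surface
// vertices sit at midpoints of cell edges crossing the boundary. Cells are
// walked one voxel beyond the grid (outside = background), so the mesh is
// always closed, including for labels touching the grid boundary.

static const int TETS[6][4] = {
  {0, 5, 1, 7}, {0, 1, 3, 7}, {0, 3, 2, 7},
  {0, 2, 6, 7}, {0, 6, 4, 7}, {0, 4, 5, 7}
};

// [[Rcpp::export(name = ".march_tets")]]
List march_tets(LogicalVector mask, NumericVector spacing) {
  IntegerVector dims = mask.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const long long NX2 = nx + 2, NY2 = ny + 2;

  auto val = [&](int i, int j, int k) -> int {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0;
    return mask[i + (long long)nx * (j + (long long)ny * k)] ? 1 : 0;
  };
  // unique key of a voxel-center lattice point, shifted so -1 maps to 0
  auto key = [&](int i, int j, int k) -> uint64_t {
    return (uint64_t)((i + 1) + NX2 * ((j + 1) + NY2 * (k + 1)));
  };

  std::unordered_map<uint64_t, int> vertex_of_edge;
  std::vector<double> vx, vy, vzc;
  std::vector<int> f1, f2, f3;

  int ci[8], cj[8], ck[8], cv[8];

  // midpoint vertex on the edge between corners a and b (indices into cube)
  auto edge_vertex = [&](int a, int b) -> int {
    uint64_t ka = key(ci[a], cj[a], ck[a]);
    uint64_t kb = key(ci[b], cj[b], ck[b]);
    uint64_t ek = ka < kb ? (ka << 32) | kb : (kb << 32) | ka;
    auto it = vertex_of_edge.find(ek);
    if (it != vertex_of_edge.end()) return it->second;
    int id = (int)vx.size();
    vx.push_back((ci[a] + ci[b] + 1.0) * 0.5 * sx);
    vy.push_back((cj[a] + cj[b] + 1.0) * 0.5 * sy);
    vzc.push_back((ck[a] + ck[b] + 1.0) * 0.5 * sz);
    vertex_of_edge.emplace(ek, id);
    return id;
  };

  auto add_tri = [&](int a, int b, int c) {
    f1.push_back(a + 1); f2.push_back(b + 1); f3.push_back(c + 1);
  };

  for (int k = -1; k < nz; ++k)
    for (int j = -1; j < ny; ++j)
      for (int i = -1; i < nx; ++i) {
        int s = 0;
        for (int c = 0; c < 8; ++c) {
          ci[c] = i + (c & 1);
          cj[c] = j + ((c >> 1) & 1);
          ck[c] = k + ((c >> 2) & 1);
          cv[c] = val(ci[c], cj[c], ck[c]);
          s += cv[c];
        }
        if (s == 0 || s == 8) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = TETS[t];
          int inside[4], nin = 0;
          for (int c = 0; c < 4; ++c) if (cv[T[c]]) inside[nin++] = c;
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            // one apex on one side: single triangle on the three edges at it
            int apex = -1;
            if (nin == 1) apex = inside[0];
            else {
              for (int c = 0; c < 4; ++c) {
                bool in = false;
                for (int q = 0; q < 3; ++q) if (inside[q] == c) in = true;
                if (!in) { apex = c; break; }
              }
            }
            int e[3], m = 0;
            for (int c = 0; c < 4; ++c)
              if (c != apex) e[m++] = edge_vertex(T[apex], T[c]);
            add_tri(e[0], e[1], e[2]);
          } else {
            // two corners on each side: quad split into two triangles
            int a = inside[0], b = inside[1], o[2], m = 0;
            for (int c = 0; c < 4; ++c)
              if (c != a && c != b) o[m++] = c;
            int eA0 = edge_vertex(T[a], T[o[0]]);
            int eA1 = edge_vertex(T[a], T[o[1]]);
            int eB0 = edge_vertex(T[b], T[o[0]]);
            int eB1 = edge_vertex(T[b], T[o[1]]);
            add_tri(eA0, eA1, eB1);
            add_tri(eA0, eB1, eB0);
          }
        }
      }

  int nv = (int)vx.size(), nf = (int)f1.size();
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = vx[v]; V(v, 1) = vy[v]; V(v, 2) = vzc[v];
  }
  IntegerMatrix F(nf, 3);
  for (int f = 0; f < nf; ++f) {
    F(f, 0) = f1[f]; F(f, 1) = f2[f]; F(f, 2) = f3[f];
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Connected-component labelling of a binary 3D mask (26-connectivity).
// Returns an integer array of component ids (0 = background), components
// numbered in decreasing voxel-count order (1 = largest).

// [[Rcpp::export(name = ".label_components_26")]]
IntegerVector label_components_26(LogicalVector mask) {
  IntegerVector dims = mask.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long long n = (long long)nx * ny * nz;
  IntegerVector out(n, 0);
  out.attr("dim") = dims;
  std::vector<long long> sizes;  // per provisional component
  int ncomp = 0;
  std::vector<long long> stack;
  for (long long p = 0; p < n; ++p) {
    if (!mask[p] || out[p] != 0) continue;
    ++ncomp;
    long long sz = 0;
    stack.push_back(p);
    out[p] = ncomp;
    while (!stack.empty()) {
      long long q = stack.back(); stack.pop_back();
      ++sz;
      int i = (int)(q % nx), j = (int)((q / nx) % ny), k = (int)(q / ((long long)nx * ny));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            long long r = ii + (long long)nx * (jj + (long long)ny * kk);
            if (mask[r] && out[r] == 0) { out[r] = ncomp; stack.push_back(r); }
          }
    }
    sizes.push_back(sz);
  }
  // renumber so component 1 is the largest
  std::vector<int> order(ncomp);
  for (int c = 0; c < ncomp; ++c) order[c] = c;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return sizes[a] > sizes[b]; });
  std::vector<int> rank(ncomp);
  for (int r = 0; r < ncomp; ++r) rank[order[r]] = r + 1;
  for (long long p = 0; p < n; ++p)
    if (out[p] != 0) out[p] = rank[out[p] - 1];
  return out;
}
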