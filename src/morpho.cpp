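// Voxel morphology: connected components and the multi-source L1 (Manhattan)
// nearest-region transform used by the white-matter Voronoi tessellation.

#include <Rcpp.h>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Connected components of a binary volume. connectivity: 6 or 26.
// Returns integer volume with components labeled 1..k, background 0.
// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const std::size_t nv = (std::size_t)nx * ny * nz;
  IntegerVector out(nv);
  out.attr("dim") = dims;
  std::vector<int> offs_x, offs_y, offs_z;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs_x.push_back(dx); offs_y.push_back(dy); offs_z.push_back(dz);
      }
  const int no = (int)offs_x.size();
  int comp = 0;
  std::vector<std::size_t> stack;
  for (std::size_t s = 0; s < nv; ++s) {
    if (!mask[s] || out[s] != 0) continue;
    ++comp;
    stack.clear();
    stack.push_back(s);
    out[s] = comp;
    while (!stack.empty()) {
      const std::size_t v = stack.back();
      stack.pop_back();
      const int x = v % nx, y = (v / nx) % ny, z = v / ((std::size_t)nx * ny);
      for (int o = 0; o < no; ++o) {
        const int xx = x + offs_x[o], yy = y + offs_y[o], zz = z + offs_z[o];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        const std::size_t u = xx + (std::size_t)nx * (yy + (std::size_t)ny * zz);
        if (mask[u] && out[u] == 0) { out[u] = comp; stack.push_back(u); }
      }
    }
  }
  return out;
}

// Multi-source layered BFS over the full grid with 6-connected unit steps,
// which realises exact Manhattan distance to the nearest seed voxel.
// seeds: integer volume, >0 marks a seed with its region id.
// Returns for every voxel the id of the L1-nearest seed region; ties between
// regions at equal distance resolve to the smallest region id.
// [[Rcpp::export(name = ".l1_nearest_region")]]
IntegerVector l1_nearest_region(IntegerVector seeds, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const std::size_t nv = (std::size_t)nx * ny * nz;
  IntegerVector lab(nv);
  lab.attr("dim") = dims;
  std::vector<std::size_t> frontier, nxt;
  for (std::size_t v = 0; v < nv; ++v)
    if (seeds[v] > 0) { lab[v] = seeds[v]; frontier.push_back(v); }
  if (frontier.empty()) return lab;
  // seeds of distinct regions may touch: enforce min-id at distance 0 is not
  // needed (seed voxels keep their own region), ties only arise for non-seeds
  const int dx6[6] = {1, -1, 0, 0, 0, 0};
  const int dy6[6] = {0, 0, 1, -1, 0, 0};
  const int dz6[6] = {0, 0, 0, 0, 1, -1};
  while (!frontier.empty()) {
    nxt.clear();
    for (std::size_t i = 0; i < frontier.size(); ++i) {
      const std::size_t v = frontier[i];
      const int x = v % nx, y = (v / nx) % ny, z = v / ((std::size_t)nx * ny);
      const int lv = lab[v];
      for (int o = 0; o < 6; ++o) {
        const int xx = x + dx6[o], yy = y + dy6[o], zz = z + dz6[o];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        const std::size_t u = xx + (std::size_t)nx * (yy + (std::size_t)ny * zz);
        if (lab[u] == 0) {
          lab[u] = -lv;  // negative marks "assigned in this layer"
          nxt.push_back(u);
        } else if (lab[u] < 0 && -lv > lab[u]) {
          lab[u] = -lv;  // same layer, keep the smallest region id
        }
      }
    }
    for (std::size_t i = 0; i < nxt.size(); ++i) lab[nxt[i]] = -lab[nxt[i]];
    frontier.swap(nxt);
  }
  return lab;
}
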