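#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Neighbour offsets for a 3D grid under 6/18/26-connectivity.
// 6 = face neighbours, 18 = face+edge, 26 = full Moore neighbourhood.
static std::vector<std::array<int, 3>> neighbour_offsets(int connectivity) {
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offs.push_back({dx, dy, dz});
      }
  return offs;
}

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

//' @noRd
// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  std::vector<std::array<int, 3>> offs = neighbour_offsets(connectivity);
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<int> q;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = lin(x, y, z, nx, ny);
        if (!mask[i] || lab[i] != 0) continue;
        ++next;
        lab[i] = next;
        q.push(i);
        while (!q.empty()) {
          int c = q.front(); q.pop();
          int cx = c % nx, cy = (c / nx) % ny, cz = c / (nx * ny);
          for (auto &o : offs) {
            int px = cx + o[0], py = cy + o[1], pz = cz + o[2];
            if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz)
              continue;
            int j = lin(px, py, pz, nx, ny);
            if (mask[j] && lab[j] == 0) { lab[j] = next; q.push(j); }
          }
        }
      }
  return lab;
}

//' @noRd
// [[Rcpp::export(name = ".dilate_once")]]
LogicalVector dilate_once(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  std::vector<std::array<int, 3>> offs = neighbour_offsets(connectivity);
  LogicalVector out = clone(mask);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = lin(x, y, z, nx, ny);
        if (!mask[i]) continue;
        for (auto &o : offs) {
          int px = x + o[0], py = y + o[1], pz = z + o[2];
          if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz)
            continue;
          out[lin(px, py, pz, nx, ny)] = true;
        }
      }
  return out;
}
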