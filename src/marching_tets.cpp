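// Iso-surface triangulation of a scalar voxel field by marching tetrahedra.
// Each voxel cell is split into six tetrahedra sharing the main diagonal;
// surface vertices are placed on cell edges by linear interpolation and
// de-duplicated, so the mesh is watertight. Face winding is arbitrary:
// normals are taken from the field gradient on the R side.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

const int TETS[6][4] = {
  {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
  {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}
};

struct MeshAcc {
  std::unordered_map<uint64_t, int> edge_vert;
  std::vector<double> vx, vy, vz;
  std::vector<int> f1, f2, f3;
};

} // namespace

// [[Rcpp::export(name = ".march_tets")]]
List march_tets(NumericVector field, IntegerVector dims, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto fidx = [&](int x, int y, int z) -> int { return x + nx * (y + ny * z); };

  MeshAcc M;
  // positions of the 8 cube corners (x, y, z offsets, bit-free explicit)
  const int CX[8] = {0, 1, 1, 0, 0, 1, 1, 0};
  const int CY[8] = {0, 0, 1, 1, 0, 0, 1, 1};
  const int CZ[8] = {0, 0, 0, 0, 1, 1, 1, 1};

  auto edge_point = [&](int ga, int gb, double fa, double fb,
                        const int pa[3], const int pb[3]) -> int {
    uint64_t key = (ga < gb)
      ? ((uint64_t) ga << 32) | (uint64_t) gb
      : ((uint64_t) gb << 32) | (uint64_t) ga;
    auto it = M.edge_vert.find(key);
    if (it != M.edge_vert.end()) return it->second;
    double t = (iso - fa) / (fb - fa);
    if (!std::isfinite(t)) t = 0.5;
    if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
    M.vx.push_back(pa[0] + t * (pb[0] - pa[0]));
    M.vy.push_back(pa[1] + t * (pb[1] - pa[1]));
    M.vz.push_back(pa[2] + t * (pb[2] - pa[2]));
    int id = (int) M.vx.size(); // 1-based
    M.edge_vert[key] = id;
    return id;
  };

  int gid[8];
  double fv[8];
  int pos[8][3];

  for (int z = 0; z + 1 < nz; ++z)
  for (int y = 0; y + 1 < ny; ++y)
  for (int x = 0; x + 1 < nx; ++x) {
    bool any_in = false, any_out = false;
    for (int c = 0; c < 8; ++c) {
      const int xx = x + CX[c], yy = y + CY[c], zz = z + CZ[c];
      gid[c] = fidx(xx, yy, zz);
      fv[c] = field[gid[c]];
      pos[c][0] = xx; pos[c][1] = yy; pos[c][2] = zz;
      if (fv[c] > iso) any_in = true; else any_out = true;
    }
    if (!any_in || !any_out) continue;

    for (int t = 0; t < 6; ++t) {
      const int* T = TETS[t];
      int in[4], ni = 0, out[4], no = 0;
      for (int c = 0; c < 4; ++c) {
        if (fv[T[c]] > iso) in[ni++] = T[c]; else out[no++] = T[c];
      }
      if (ni == 0 || ni == 4) continue;
      if (ni == 1 || ni == 3) {
        const int apex = (ni == 1) ? in[0] : out[0];
        const int* oth = (ni == 1) ? out : in;
        int e[3];
        for (int c = 0; c < 3; ++c)
          e[c] = edge_point(gid[apex], gid[oth[c]], fv[apex], fv[oth[c]],
                            pos[apex], pos[oth[c]]);
        M.f1.push_back(e[0]); M.f2.push_back(e[1]); M.f3.push_back(e[2]);
      } else { // 2 in, 2 out -> quad -> two triangles
        int eAC = edge_point(gid[in[0]], gid[out[0]], fv[in[0]], fv[out[0]],
                             pos[in[0]], pos[out[0]]);
        int eAD = edge_point(gid[in[0]], gid[out[1]], fv[in[0]], fv[out[1]],
                             pos[in[0]], pos[out[1]]);
        int eBC = edge_point(gid[in[1]], gid[out[0]], fv[in[1]], fv[out[0]],
                             pos[in[1]], pos[out[0]]);
        int eBD = edge_point(gid[in[1]], gid[out[1]], fv[in[1]], fv[out[1]],
                             pos[in[1]], pos[out[1]]);
        M.f1.push_back(eAC); M.f2.push_back(eAD); M.f3.push_back(eBD);
        M.f1.push_back(eAC); M.f2.push_back(eBD); M.f3.push_back(eBC);
      }
    }
  }

  const int nv = (int) M.vx.size();
  NumericMatrix verts(nv, 3);
  for (int i = 0; i < nv; ++i) {
    verts(i, 0) = M.vx[i]; verts(i, 1) = M.vy[i]; verts(i, 2) = M.vz[i];
  }
  const int nf = (int) M.f1.size();
  IntegerMatrix faces(nf, 3);
  for (int i = 0; i < nf; ++i) {
    faces(i, 0) = M.f1[i]; faces(i, 1) = M.f2[i]; faces(i, 2) = M.f3[i];
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}
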