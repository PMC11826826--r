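#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Connected-component labeling of a 3D binary mask by iterative flood fill
// (explicit stack). connectivity: 6 (faces), 18 (faces+edges) or 26 (full).
// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);

  // neighbor offsets for the requested connectivity
  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        if (cx == 0 && cy == 0 && cz == 0) continue;
        int ord = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (connectivity == 6 && ord > 1) continue;
        if (connectivity == 18 && ord > 2) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }
  const int nn = (int)dx.size();

  int next_label = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next_label;
    labels[start] = next_label;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int x = (int)(cur % nx);
      int y = (int)((cur / nx) % ny);
      int z = (int)(cur / ((R_xlen_t)nx * ny));
      for (int k = 0; k < nn; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t nb = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[nb] && labels[nb] == 0) {
          labels[nb] = next_label;
          stack.push_back(nb);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}

// Joint (guided) bilateral filter of one 3D volume. Spatial weights are an
// anisotropic Gaussian (sd per axis, truncated at 3 sd); range weights are a
// Gaussian on guide-image differences, so smoothing does not bleed across
// guide edges. Weights are renormalized per voxel (identity on constants).
// [[Rcpp::export(name = ".joint_bilateral")]]
NumericVector joint_bilateral(NumericVector x, NumericVector guide,
                              IntegerVector dims, NumericVector sd_voxels,
                              double range_sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int rx = std::max(1, (int)std::ceil(3.0 * sd_voxels[0]));
  const int ry = std::max(1, (int)std::ceil(3.0 * sd_voxels[1]));
  const int rz = std::max(1, (int)std::ceil(3.0 * sd_voxels[2]));

  // precompute spatial weights over the window
  const int wx = 2 * rx + 1, wy = 2 * ry + 1, wz = 2 * rz + 1;
  std::vector<double> sw((size_t)wx * wy * wz);
  {
    size_t k = 0;
    for (int cz = -rz; cz <= rz; ++cz)
      for (int cy = -ry; cy <= ry; ++cy)
        for (int cx = -rx; cx <= rx; ++cx, ++k)
          sw[k] = std::exp(-0.5 * (cx * cx / (sd_voxels[0] * sd_voxels[0]) +
                                   cy * cy / (sd_voxels[1] * sd_voxels[1]) +
                                   cz * cz / (sd_voxels[2] * sd_voxels[2])));
  }
  const double inv2r = (range_sigma > 0 && std::isfinite(range_sigma))
                           ? 0.5 / (range_sigma * range_sigma)
                           : 0.0;

  NumericVector out(n);
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x0 = 0; x0 < nx; ++x0) {
        R_xlen_t cur = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x0;
        double g0 = guide[cur];
        double num = 0.0, den = 0.0;
        size_t k = 0;
        for (int cz = -rz; cz <= rz; ++cz) {
          int zz = z + cz;
          if (zz < 0 || zz >= nz) { k += (size_t)wx * wy; continue; }
          for (int cy = -ry; cy <= ry; ++cy) {
            int yy = y + cy;
            if (yy < 0 || yy >= ny) { k += wx; continue; }
            R_xlen_t base = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx;
            for (int cx = -rx; cx <= rx; ++cx, ++k) {
              int xx = x0 + cx;
              if (xx < 0 || xx >= nx) continue;
              double w = sw[k];
              double dg = guide[base + xx] - g0;
              if (dg != 0.0 && inv2r > 0.0) w *= std::exp(-dg * dg * inv2r);
              num += w * x[base + xx];
              den += w;
            }
          }
        }
        out[cur] = (den > 0.0) ? num / den : x[cur];
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
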