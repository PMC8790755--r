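// Voxelization kernel: for each atom and each channel whose property it
// carries, voxels within the cutoff accumulate n(r) = 1 - exp(-(rvdw/r)^12),
// aggregated per voxel by maximum. Returned layout is channels-last
// (x fastest), matching an R array of dim c(n, n, n, nchan).

#include <Rcpp.h>
#include <cmath>

// [[Rcpp::export]]
Rcpp::NumericVector voxelize_cpp(Rcpp::NumericMatrix coords,
                                 Rcpp::NumericVector radii,
                                 Rcpp::LogicalMatrix chanFlags,
                                 int n, Rcpp::NumericVector origin,
                                 double spacing, double cutoff) {
  const int natoms = coords.nrow();
  const int nchan = chanFlags.ncol();
  const size_t M = (size_t)n * n * n;
  Rcpp::NumericVector out(M * nchan); // zero-initialised

  for (int a = 0; a < natoms; ++a) {
    bool any = false;
    for (int c = 0; c < nchan; ++c) if (chanFlags(a, c)) { any = true; break; }
    if (!any) continue;
    const double px = coords(a, 0), py = coords(a, 1), pz = coords(a, 2);
    const double rv = radii[a];
    const int x0 = std::max(0, (int)std::ceil((px - cutoff - origin[0]) / spacing));
    const int x1 = std::min(n - 1, (int)std::floor((px + cutoff - origin[0]) / spacing));
    const int y0 = std::max(0, (int)std::ceil((py - cutoff - origin[1]) / spacing));
    const int y1 = std::min(n - 1, (int)std::floor((py + cutoff - origin[1]) / spacing));
    const int z0 = std::max(0, (int)std::ceil((pz - cutoff - origin[2]) / spacing));
    const int z1 = std::min(n - 1, (int)std::floor((pz + cutoff - origin[2]) / spacing));
    const double cut2 = cutoff * cutoff;
    for (int iz = z0; iz <= z1; ++iz) {
      const double dz = origin[2] + spacing * iz - pz;
      for (int iy = y0; iy <= y1; ++iy) {
        const double dy = origin[1] + spacing * iy - py;
        for (int ix = x0; ix <= x1; ++ix) {
          const double dx = origin[0] + spacing * ix - px;
          const double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 > cut2) continue;
          double val;
          if (r2 == 0.0) {
            val = 1.0;
          } else {
            const double q = rv * rv / r2;            // (rvdw/r)^2
            val = 1.0 - std::exp(-(q * q * q * q * q * q)); // ^12
          }
          const size_t vox = (size_t)ix + (size_t)n * (iy + (size_t)n * iz);
          for (int c = 0; c < nchan; ++c) {
            if (!chanFlags(a, c)) continue;
            const size_t k = vox + M * c;
            if (val > out[k]) out[k] = val;
          }
        }
      }
    }
  }
  return out;
}
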