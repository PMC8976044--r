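// Hot loops of the toy imaging engine: central-slice extraction and
// insertion in a centered Fourier grid, and real-space trilinear
// resampling.  All grids are cubic with the physical origin at voxel
// index N/2 (0-based); Fourier grids hold centered integer frequencies
// kx = i - N/2 in cycles/box.  Pose matrices map reference -> particle
// frame; a slice at in-plane frequency k = (kx, ky, 0) samples the 3D
// transform at q = R^T k.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Extract central slices from a centered 3D Fourier transform.
// fvol: M x M x M complex (possibly an oversampled/padded transform),
// rots: 3 x 3 x P pose matrices; n_out: slice size in image pixels;
// scale: oversampling factor (padded grid index per image frequency).
// Returns n_out x n_out x P complex slices (trilinear, zero outside).
// [[Rcpp::export]]
arma::cx_cube cpp_slice_extract(const arma::cx_cube& fvol,
                                const arma::cube& rots,
                                const int n_out, const double scale) {
  const int N = fvol.n_rows;
  const int M = rots.n_slices;
  const int h = N / 2;
  const int ho = n_out / 2;
  arma::cx_cube out(n_out, n_out, M, arma::fill::zeros);
  for (int m = 0; m < M; ++m) {
    const arma::mat& R = rots.slice(m);
    for (int j = 0; j < n_out; ++j) {
      const double ky = (j - ho) * scale;
      for (int i = 0; i < n_out; ++i) {
        const double kx = (i - ho) * scale;
        // q = R^T (kx, ky, 0)
        const double qx = R(0, 0) * kx + R(1, 0) * ky + h;
        const double qy = R(0, 1) * kx + R(1, 1) * ky + h;
        const double qz = R(0, 2) * kx + R(1, 2) * ky + h;
        const int x0 = (int)std::floor(qx);
        const int y0 = (int)std::floor(qy);
        const int z0 = (int)std::floor(qz);
        if (x0 < -1 || y0 < -1 || z0 < -1 ||
            x0 > N - 1 || y0 > N - 1 || z0 > N - 1) continue;
        const double fx = qx - x0, fy = qy - y0, fz = qz - z0;
        std::complex<double> acc(0.0, 0.0);
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              const int xi = x0 + dx, yi = y0 + dy, zi = z0 + dz;
              if (xi < 0 || yi < 0 || zi < 0 || xi >= N || yi >= N || zi >= N)
                continue;   // out-of-grid neighbors contribute zero
              const double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                               (dz ? fz : 1 - fz);
              if (w > 0)
                acc += w * fvol(xi, yi, zi);
            }
        out(i, j, m) = acc;
      }
    }
  }
  return out;
}

// Fourier insertion of CTF-premultiplied slices for Wiener reconstruction.
// slices: N x N x P centered 2D transforms (already shift-corrected),
// ctfs: N x N x P transfer values, rots: 3 x 3 x P pose matrices.
// Accumulates num += w * ctf * F, den += w * ctf^2 at q = R^T k.
// [[Rcpp::export]]
List cpp_fourier_insert(const arma::cx_cube& slices, const arma::cube& ctfs,
                        const arma::cube& rots) {
  const int N = slices.n_rows;
  const int P = slices.n_slices;
  const int h = N / 2;
  arma::cx_cube num(N, N, N, arma::fill::zeros);
  arma::cube den(N, N, N, arma::fill::zeros);
  for (int p = 0; p < P; ++p) {
    const arma::mat& R = rots.slice(p);
    for (int j = 0; j < N; ++j) {
      const double ky = j - h;
      for (int i = 0; i < N; ++i) {
        const double kx = i - h;
        const double c = ctfs(i, j, p);
        const std::complex<double> v = c * slices(i, j, p);
        const double c2 = c * c;
        const double qx = R(0, 0) * kx + R(1, 0) * ky + h;
        const double qy = R(0, 1) * kx + R(1, 1) * ky + h;
        const double qz = R(0, 2) * kx + R(1, 2) * ky + h;
        const int x0 = (int)std::floor(qx);
        const int y0 = (int)std::floor(qy);
        const int z0 = (int)std::floor(qz);
        if (x0 < -1 || y0 < -1 || z0 < -1 ||
            x0 > N - 1 || y0 > N - 1 || z0 > N - 1) continue;
        const double fx = qx - x0, fy = qy - y0, fz = qz - z0;
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              const int xi = x0 + dx, yi = y0 + dy, zi = z0 + dz;
              if (xi < 0 || yi < 0 || zi < 0 || xi >= N || yi >= N || zi >= N)
                continue;
              const double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                               (dz ? fz : 1 - fz);
              if (w > 0) {
                num(xi, yi, zi) += w * v;
                den(xi, yi, zi) += w * c2;
              }
            }
      }
    }
  }
  return List::create(Named("num") = num, Named("den") = den);
}

// Real-space trilinear resampling under a rigid transform.
// Returns w with w(x) = v(R^{-1} (x - t)), coordinates centered at N/2,
// t in voxels; zero outside the source grid.
// [[Rcpp::export]]
arma::cube cpp_resample(const arma::cube& v, const arma::mat& R,
                        const arma::vec& t, const int n_out) {
  const int Nv = v.n_rows;
  const int hv = Nv / 2;
  const int ho = n_out / 2;
  arma::mat Ri = R.t();  // inverse of a rotation
  arma::cube out(n_out, n_out, n_out, arma::fill::zeros);
  for (int k = 0; k < n_out; ++k) {
    const double z = k - ho - t(2);
    for (int j = 0; j < n_out; ++j) {
      const double y = j - ho - t(1);
      for (int i = 0; i < n_out; ++i) {
        const double x = i - ho - t(0);
        const double sx = Ri(0, 0) * x + Ri(0, 1) * y + Ri(0, 2) * z + hv;
        const double sy = Ri(1, 0) * x + Ri(1, 1) * y + Ri(1, 2) * z + hv;
        const double sz = Ri(2, 0) * x + Ri(2, 1) * y + Ri(2, 2) * z + hv;
        const int x0 = (int)std::floor(sx);
        const int y0 = (int)std::floor(sy);
        const int z0 = (int)std::floor(sz);
        if (x0 < -1 || y0 < -1 || z0 < -1 ||
            x0 > Nv - 1 || y0 > Nv - 1 || z0 > Nv - 1) continue;
        const double fx = sx - x0, fy = sy - y0, fz = sz - z0;
        double acc = 0.0;
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              const int xi = x0 + dx, yi = y0 + dy, zi = z0 + dz;
              if (xi < 0 || yi < 0 || zi < 0 ||
                  xi >= Nv || yi >= Nv || zi >= Nv)
                continue;
              acc += (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                     (dz ? fz : 1 - fz) * v(xi, yi, zi);
            }
        out(i, j, k) = acc;
      }
    }
  }
  return out;
}

// Sum of anisotropic Gaussian blobs on a grid (synthetic densities).
// centers: n x 3 (voxel units, centered), weights, sigmas (voxels).
// [[Rcpp::export]]
arma::cube cpp_gaussian_splat(const arma::mat& centers,
                              const arma::vec& weights,
                              const arma::vec& sigmas, const int n) {
  const int h = n / 2;
  arma::cube out(n, n, n, arma::fill::zeros);
  for (arma::uword b = 0; b < centers.n_rows; ++b) {
    const double cx = centers(b, 0) + h, cy = centers(b, 1) + h,
                 cz = centers(b, 2) + h;
    const double s = sigmas(b);
    const double inv2s2 = 1.0 / (2.0 * s * s);
    const double cut = 5.0 * s;
    const int x0 = std::max(0, (int)std::floor(cx - cut));
    const int x1 = std::min(n - 1, (int)std::ceil(cx + cut));
    const int y0 = std::max(0, (int)std::floor(cy - cut));
    const int y1 = std::min(n - 1, (int)std::ceil(cy + cut));
    const int z0 = std::max(0, (int)std::floor(cz - cut));
    const int z1 = std::min(n - 1, (int)std::ceil(cz + cut));
    for (int k = z0; k <= z1; ++k)
      for (int j = y0; j <= y1; ++j)
        for (int i = x0; i <= x1; ++i) {
          const double d2 = (i - cx) * (i - cx) + (j - cy) * (j - cy) +
                            (k - cz) * (k - cz);
          out(i, j, k) += weights(b) * std::exp(-d2 * inv2s2);
        }
  }
  return out;
}
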