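// Direct 3D convolution (kernel 3, stride 1, zero padding 1) via im2col +
// BLAS gemm. Volumes are stored as (V, C) matrices where V = nx*ny*nz and
// the spatial index is v = ix + nx*(iy + ny*iz) (x fastest), matching how R
// flattens an array of dim c(nx, ny, nz).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col3(const mat& x, int nx, int ny, int nz) {
  const int V = nx * ny * nz;
  const int Cin = x.n_cols;
  mat P(V, 27 * Cin, fill::zeros);
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x.colptr(ci);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          const int t = (dz + 1) * 9 + (dy + 1) * 3 + (dx + 1);
          double* pc = P.colptr(ci * 27 + t);
          const int iz0 = std::max(0, -dz), iz1 = std::min(nz, nz - dz);
          const int iy0 = std::max(0, -dy), iy1 = std::min(ny, ny - dy);
          const int ix0 = std::max(0, -dx), ix1 = std::min(nx, nx - dx);
          for (int iz = iz0; iz < iz1; ++iz)
            for (int iy = iy0; iy < iy1; ++iy) {
              const int vb = ix0 + nx * (iy + ny * iz);
              const int sb = (ix0 + dx) + nx * ((iy + dy) + ny * (iz + dz));
              std::copy(xc + sb, xc + sb + (ix1 - ix0), pc + vb);
            }
        }
  }
  return P;
}

static mat col2im3(const mat& G, int nx, int ny, int nz, int Cin) {
  const int V = nx * ny * nz;
  mat gx(V, Cin, fill::zeros);
  for (int ci = 0; ci < Cin; ++ci) {
    double* xc = gx.colptr(ci);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          const int t = (dz + 1) * 9 + (dy + 1) * 3 + (dx + 1);
          const double* pc = G.colptr(ci * 27 + t);
          const int iz0 = std::max(0, -dz), iz1 = std::min(nz, nz - dz);
          const int iy0 = std::max(0, -dy), iy1 = std::min(ny, ny - dy);
          const int ix0 = std::max(0, -dx), ix1 = std::min(nx, nx - dx);
          for (int iz = iz0; iz < iz1; ++iz)
            for (int iy = iy0; iy < iy1; ++iy) {
              const int vb = ix0 + nx * (iy + ny * iz);
              const int sb = (ix0 + dx) + nx * ((iy + dy) + ny * (iz + dz));
              for (int k = 0; k < ix1 - ix0; ++k) xc[sb + k] += pc[vb + k];
            }
        }
  }
  return gx;
}

// y[v, co] = b[co] + sum_{off, ci} W[(ci,off), co] * x[v + off, ci]
// [[Rcpp::export]]
arma::mat cpp_conv3d_fw(const arma::mat& x, const arma::mat& W,
                        const arma::vec& b, const Rcpp::IntegerVector& dims) {
  mat P = im2col3(x, dims[0], dims[1], dims[2]);
  mat y = P * W;
  y.each_row() += b.t();
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv3d_bw(const arma::mat& x, const arma::mat& W,
                         const arma::mat& gy, const Rcpp::IntegerVector& dims) {
  const int Cin = x.n_cols;
  mat P = im2col3(x, dims[0], dims[1], dims[2]);
  mat gW = P.t() * gy;
  vec gb = sum(gy, 0).t();
  mat gP = gy * W.t();
  mat gx = col2im3(gP, dims[0], dims[1], dims[2], Cin);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// occupancy/charge featurization inner loop: for each voxel center, the max
// over atoms of 1 - exp(-(r/d)^12) and the charge-weighted Gaussian sum.
// centers: (V,3); apos: (A,3); avdw, aq: length A.
// [[Rcpp::export]]
Rcpp::List cpp_featurize(const arma::mat& centers, const arma::mat& apos,
                         const arma::vec& avdw, const arma::vec& aq,
                         double sigma) {
  const int V = centers.n_rows, A = apos.n_rows;
  vec occ(V, fill::zeros), chg(V, fill::zeros);
  const double s2 = 2.0 * sigma * sigma;
  for (int a = 0; a < A; ++a) {
    const double ax = apos(a, 0), ay = apos(a, 1), az = apos(a, 2);
    const double rv = avdw(a), q = aq(a);
    for (int v = 0; v < V; ++v) {
      const double dx = centers(v, 0) - ax, dy = centers(v, 1) - ay,
                   dz = centers(v, 2) - az;
      const double d2 = dx * dx + dy * dy + dz * dz;
      double o;
      if (d2 < 1e-24) {
        o = 1.0;
      } else {
        const double r = (rv * rv) / d2;
        const double r12 = r * r * r * r * r * r;
        o = 1.0 - std::exp(-r12);
      }
      if (o > occ(v)) occ(v) = o;
      chg(v) += q * std::exp(-d2 / s2);
    }
  }
  return Rcpp::List::create(Rcpp::Named("occupancy") = occ,
                            Rcpp::Named("charge") = chg);
}
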