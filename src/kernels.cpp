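// Dense array kernels for the reconstruction pipeline.
//
// Conventions (see also the package vignette):
//  * volumes are cubic arrays indexed [x, y, z], 0-based here, with the
//    geometric origin at voxel floor(N/2) (so index N/2 for even N);
//  * rotation matrices map model-frame coordinates into the image frame
//    (reference-into-image); projection integrates along image-frame z;
//  * shifts are in voxels and displace the image content.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double trilerp(const arma::cube& v, double x, double y, double z) {
  // zero outside the grid
  const int nx = v.n_rows, ny = v.n_cols, nz = v.n_slices;
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
      z1 = std::min(z0 + 1, nz - 1);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double c00 = v(x0, y0, z0) * (1 - fx) + v(x1, y0, z0) * fx;
  double c10 = v(x0, y1, z0) * (1 - fx) + v(x1, y1, z0) * fx;
  double c01 = v(x0, y0, z1) * (1 - fx) + v(x1, y0, z1) * fx;
  double c11 = v(x0, y1, z1) * (1 - fx) + v(x1, y1, z1) * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static inline double bilerp(const arma::mat& im, double x, double y) {
  const int nx = im.n_rows, ny = im.n_cols;
  if (x < 0 || y < 0 || x > nx - 1 || y > ny - 1) return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1);
  double fx = x - x0, fy = y - y0;
  return (im(x0, y0) * (1 - fx) + im(x1, y0) * fx) * (1 - fy) +
         (im(x0, y1) * (1 - fx) + im(x1, y1) * fx) * fy;
}

// Apply rigid transform y = R x + t (voxel units, about the box centre) to a
// volume: out(y) = in(R^T (y - t)).
// [[Rcpp::export]]
arma::cube cpp_transform_volume(const arma::cube& vol, const arma::mat& R,
                                const arma::vec& t_vox) {
  const int n = vol.n_rows;
  const double c = std::floor(n / 2.0);
  arma::cube out(n, n, n, arma::fill::zeros);
  arma::mat Rt = R.t();
  for (int k = 0; k < n; ++k) {
    for (int j = 0; j < n; ++j) {
      for (int i = 0; i < n; ++i) {
        double x = i - c - t_vox(0);
        double y = j - c - t_vox(1);
        double z = k - c - t_vox(2);
        double sx = Rt(0, 0) * x + Rt(0, 1) * y + Rt(0, 2) * z + c;
        double sy = Rt(1, 0) * x + Rt(1, 1) * y + Rt(1, 2) * z + c;
        double sz = Rt(2, 0) * x + Rt(2, 1) * y + Rt(2, 2) * z + c;
        out(i, j, k) = trilerp(vol, sx, sy, sz);
      }
    }
  }
  return out;
}

// Project a volume: I(x, y) = sum_z V(R^T p), p = (x - sx, y - sy, z)
// relative to the box centre. Shift in voxels.
// [[Rcpp::export]]
arma::mat cpp_project(const arma::cube& vol, const arma::mat& R,
                      double sx, double sy) {
  const int n = vol.n_rows;
  const double c = std::floor(n / 2.0);
  arma::mat Rt = R.t();
  arma::mat out(n, n, arma::fill::zeros);
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < n; ++i) {
      double x = i - c - sx;
      double y = j - c - sy;
      double acc = 0.0;
      // precompute the x,y part of the rotated ray
      double bx = Rt(0, 0) * x + Rt(0, 1) * y;
      double by = Rt(1, 0) * x + Rt(1, 1) * y;
      double bz = Rt(2, 0) * x + Rt(2, 1) * y;
      for (int k = 0; k < n; ++k) {
        double z = k - c;
        acc += trilerp(vol, bx + Rt(0, 2) * z + c, by + Rt(1, 2) * z + c,
                       bz + Rt(2, 2) * z + c);
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Real-space back-projection with per-voxel hit counting.
// images: n x n x n_img cube; Rs: 3 x 3*n_img (column blocks); shifts:
// n_img x 2 (voxels). Returns list(sum = cube, weight = cube).
// [[Rcpp::export]]
List cpp_backproject(const arma::cube& images, const arma::mat& Rs,
                     const arma::mat& shifts) {
  const int n = images.n_rows;
  const int nimg = images.n_slices;
  const double c = std::floor(n / 2.0);
  arma::cube acc(n, n, n, arma::fill::zeros);
  arma::cube wt(n, n, n, arma::fill::zeros);
  for (int m = 0; m < nimg; ++m) {
    arma::mat R = Rs.cols(3 * m, 3 * m + 2);
    arma::mat im = images.slice(m);
    double sx = shifts(m, 0), sy = shifts(m, 1);
    for (int k = 0; k < n; ++k) {
      for (int j = 0; j < n; ++j) {
        for (int i = 0; i < n; ++i) {
          double x = i - c, y = j - c, z = k - c;
          // voxel position in the image frame
          double px = R(0, 0) * x + R(0, 1) * y + R(0, 2) * z + sx + c;
          double py = R(1, 0) * x + R(1, 1) * y + R(1, 2) * z + sy + c;
          if (px < 0 || py < 0 || px > n - 1 || py > n - 1) continue;
          acc(i, j, k) += bilerp(im, px, py);
          wt(i, j, k) += 1.0;
        }
      }
    }
  }
  return List::create(Named("sum") = acc, Named("weight") = wt);
}

// Exhaustive match of a stack against a projection gallery over integer
// shifts. images: n x n x n_img; gallery: n x n x n_gal, each gallery slice
// already zero-mean and unit-L2-normalised. Returns best gallery index
// (1-based), the full cc-vs-shift matrix for the best gallery entry, and the
// best cc. Ties broken by the lowest gallery index (strict improvement).
// [[Rcpp::export]]
List cpp_match_stack(const arma::cube& images, const arma::cube& gallery,
                     int max_shift) {
  const int n = images.n_rows;
  const int nimg = images.n_slices;
  const int ngal = gallery.n_slices;
  const int ns = 2 * max_shift + 1;
  IntegerVector best_g(nimg);
  NumericVector best_cc(nimg);
  IntegerVector best_dx(nimg), best_dy(nimg);
  arma::cube ccbest(ns, ns, nimg, arma::fill::zeros);

  for (int m = 0; m < nimg; ++m) {
    arma::mat im = images.slice(m);
    im -= arma::accu(im) / (n * n);
    double nrm = std::sqrt(arma::accu(im % im));
    if (nrm > 0) im /= nrm;
    double bc = -2.0;
    int bg = 0, bdx = 0, bdy = 0;
    arma::mat bmat(ns, ns, arma::fill::zeros);
    arma::mat cc(ns, ns);
    for (int g = 0; g < ngal; ++g) {
      const arma::mat& gal = gallery.slice(g);
      for (int dy = -max_shift; dy <= max_shift; ++dy) {
        for (int dx = -max_shift; dx <= max_shift; ++dx) {
          // correlate image shifted by (dx, dy) against gallery
          double s = 0.0;
          int i0 = std::max(0, -dx), i1 = std::min(n, n - dx);
          int j0 = std::max(0, -dy), j1 = std::min(n, n - dy);
          for (int j = j0; j < j1; ++j)
            for (int i = i0; i < i1; ++i)
              s += im(i + dx, j + dy) * gal(i, j);
          cc(dx + max_shift, dy + max_shift) = s;
        }
      }
      double mx = cc.max();
      if (mx > bc + 1e-12) {
        bc = mx;
        bg = g;
        bmat = cc;
        arma::uword idx = cc.index_max();
        bdx = (int)(idx % ns) - max_shift;
        bdy = (int)(idx / ns) - max_shift;
      }
    }
    best_g[m] = bg + 1;
    best_cc[m] = bc;
    best_dx[m] = bdx;
    best_dy[m] = bdy;
    ccbest.slice(m) = bmat;
  }
  return List::create(Named("gallery_index") = best_g, Named("cc") = best_cc,
                      Named("dx") = best_dx, Named("dy") = best_dy,
                      Named("cc_shift") = ccbest);
}

// Normalised cross-correlation between stack slices and a set of class mean
// images inside a pixel mask. images: n x n x n_img; means: n x n x k;
// mask: n x n (0/1 weights). Returns n_img x k matrix of NCC values.
// [[Rcpp::export]]
arma::mat cpp_masked_ncc(const arma::cube& images, const arma::cube& means,
                         const arma::mat& mask) {
  const int nimg = images.n_slices, k = means.n_slices;
  arma::uvec idx = arma::find(mask > 0.5);
  arma::mat out(nimg, k);
  arma::mat M(idx.n_elem, k);
  for (int c = 0; c < k; ++c) {
    arma::vec v = means.slice(c).elem(idx);
    v -= arma::mean(v);
    double nv = arma::norm(v);
    M.col(c) = nv > 0 ? v / nv : v;
  }
  for (int m = 0; m < nimg; ++m) {
    arma::vec v = images.slice(m).elem(idx);
    v -= arma::mean(v);
    double nv = arma::norm(v);
    if (nv > 0) v /= nv;
    out.row(m) = (v.t() * M);
  }
  return out;
}
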