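// Rotation-based attenuated parallel-beam SPECT projector with a
// distance-dependent Gaussian collimator-detector response, its exact
// matched adjoint, and the OSEM/MLEM reconstruction loop built on the pair.
//
// Conventions:
//  * volumes are arma::cube with dimensions (x, y, z); z is the scanner axis;
//  * for view angle theta the volume is rotated about z so that rays run
//    along +y and the detector plane sits at y = +detector_radius;
//  * detector bins coincide with the (x, z) voxel raster (bin size = voxel
//    size), so a projection view is an (nx x nz) matrix;
//  * the adjoint is the exact transpose of the discretized forward operator
//    (bilinear gather <-> bilinear scatter, symmetric truncated blur,
//    diagonal attenuation), which makes the EM update monotone.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

namespace {

struct RotMap {
  // per destination pixel (flattened within a z-slice): source corner
  // indices and bilinear weights; only in-bounds destinations are kept
  uvec dest, i00, i10, i01, i11;
  vec w00, w10, w01, w11;
};

RotMap build_rot_map(int nx, int ny, double theta) {
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const double c = std::cos(theta), s = std::sin(theta);
  std::vector<uword> dest, i00, i10, i01, i11;
  std::vector<double> w00, w10, w01, w11;
  dest.reserve((size_t)nx * ny);
  for (int iy = 0; iy < ny; ++iy) {
    for (int ix = 0; ix < nx; ++ix) {
      const double dx = ix - cx, dy = iy - cy;
      const double xs = c * dx - s * dy + cx;
      const double ys = s * dx + c * dy + cy;
      if (xs < 0.0 || xs > nx - 1 || ys < 0.0 || ys > ny - 1) continue;
      int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
      if (x0 > nx - 2) x0 = nx - 2;
      if (y0 > ny - 2) y0 = ny - 2;
      if (nx == 1) x0 = 0;
      if (ny == 1) y0 = 0;
      const double fx = xs - x0, fy = ys - y0;
      dest.push_back((uword)(iy * nx + ix));
      i00.push_back((uword)(y0 * nx + x0));
      i10.push_back((uword)(y0 * nx + std::min(x0 + 1, nx - 1)));
      i01.push_back((uword)(std::min(y0 + 1, ny - 1) * nx + x0));
      i11.push_back((uword)(std::min(y0 + 1, ny - 1) * nx + std::min(x0 + 1, nx - 1)));
      w00.push_back((1 - fx) * (1 - fy));
      w10.push_back(fx * (1 - fy));
      w01.push_back((1 - fx) * fy);
      w11.push_back(fx * fy);
    }
  }
  RotMap m;
  m.dest = uvec(dest); m.i00 = uvec(i00); m.i10 = uvec(i10);
  m.i01 = uvec(i01);  m.i11 = uvec(i11);
  m.w00 = vec(w00); m.w10 = vec(w10); m.w01 = vec(w01); m.w11 = vec(w11);
  return m;
}

// out(dest) = sum of bilinear-weighted source values; out zeroed first
void rot_gather(const cube& in, cube& out, const RotMap& m) {
  out.zeros();
  const uword n = m.dest.n_elem;
  for (uword z = 0; z < in.n_slices; ++z) {
    const double* A = in.slice(z).memptr();
    double* B = out.slice(z).memptr();
    for (uword k = 0; k < n; ++k) {
      B[m.dest[k]] = m.w00[k] * A[m.i00[k]] + m.w10[k] * A[m.i10[k]] +
                     m.w01[k] * A[m.i01[k]] + m.w11[k] * A[m.i11[k]];
    }
  }
}

// exact transpose of rot_gather; accumulates into out (caller zeroes)
void rot_scatter(const cube& g, cube& out, const RotMap& m) {
  const uword n = m.dest.n_elem;
  for (uword z = 0; z < g.n_slices; ++z) {
    const double* G = g.slice(z).memptr();
    double* A = out.slice(z).memptr();
    for (uword k = 0; k < n; ++k) {
      const double v = G[m.dest[k]];
      if (v == 0.0) continue;
      A[m.i00[k]] += m.w00[k] * v;
      A[m.i10[k]] += m.w10[k] * v;
      A[m.i01[k]] += m.w01[k] * v;
      A[m.i11[k]] += m.w11[k] * v;
    }
  }
}

// normalized symmetric 1-D Gaussian kernel in voxel units; empty => identity
vec gauss_kernel(double sigma_vox) {
  if (sigma_vox < 0.05) return vec();
  const int r = std::max(1, (int)std::ceil(2.5 * sigma_vox));
  vec k(2 * r + 1);
  for (int i = -r; i <= r; ++i)
    k[i + r] = std::exp(-0.5 * (i * i) / (sigma_vox * sigma_vox));
  k /= accu(k);
  return k;
}

// separable symmetric truncated convolution of an (nx x nz) plane, in place.
// Truncation without edge renormalization keeps the operator self-adjoint.
void blur_plane(mat& P, const vec& k, mat& tmp) {
  if (k.n_elem == 0) return;
  const int r = ((int)k.n_elem - 1) / 2;
  const int nx = P.n_rows, nz = P.n_cols;
  tmp.zeros(nx, nz);
  // along x (rows): shifted axpy per tap, contiguous inner loops
  for (int j = 0; j < nz; ++j) {
    const double* src = P.colptr(j);
    double* dst = tmp.colptr(j);
    for (int t = -r; t <= r; ++t) {
      const double w = k[t + r];
      const int lo = std::max(0, -t), hi = std::min(nx - 1, nx - 1 - t);
      for (int i = lo; i <= hi; ++i) dst[i] += w * src[i + t];
    }
  }
  // along z (columns): axpy over whole columns
  P.zeros();
  for (int j = 0; j < nz; ++j) {
    const double* src = tmp.colptr(j);
    const int lo = std::max(-r, -j), hi = std::min(r, nz - 1 - j);
    for (int t = lo; t <= hi; ++t) {
      const double w = k[t + r];
      double* dst = P.colptr(j + t);
      for (int i = 0; i < nx; ++i) dst[i] += w * src[i];
    }
  }
}

// attenuation survival factors in the rotated frame: detector at +y side
cube att_factors(const cube& mu_rot, double voxel_cm) {
  const uword nx = mu_rot.n_rows, ny = mu_rot.n_cols, nz = mu_rot.n_slices;
  cube att(nx, ny, nz);
  for (uword z = 0; z < nz; ++z) {
    const mat& M = mu_rot.slice(z);
    mat& A = att.slice(z);
    for (uword ix = 0; ix < nx; ++ix) {
      double path = 0.0; // integral of mu from voxel (half) to detector
      for (int j = (int)ny - 1; j >= 0; --j) {
        const double m = M(ix, (uword)j);
        A(ix, (uword)j) = std::exp(-voxel_cm * (path + 0.5 * m));
        path += m;
      }
    }
  }
  return att;
}

std::vector<vec> slab_kernels(int ny, double voxel_mm, double sigma0_mm,
                              double sigma_slope, double det_radius_mm) {
  std::vector<vec> ks((size_t)ny);
  const double cy = (ny - 1) / 2.0;
  for (int j = 0; j < ny; ++j) {
    const double y_mm = (j - cy) * voxel_mm;
    const double d = std::max(0.0, det_radius_mm - y_mm);
    ks[(size_t)j] = gauss_kernel((sigma0_mm + sigma_slope * d) / voxel_mm);
  }
  return ks;
}

// forward: rotated, attenuation-weighted slab sums with per-slab blur
void forward_view(const cube& act_rot, const cube& att,
                  const std::vector<vec>& ks,
                  mat& P, mat& S, mat& tmp) {
  const uword nx = act_rot.n_rows, ny = act_rot.n_cols, nz = act_rot.n_slices;
  P.zeros(nx, nz);
  for (uword j = 0; j < ny; ++j) {
    bool any = false;
    for (uword z = 0; z < nz; ++z) {
      const double* a = act_rot.slice(z).colptr(j);
      const double* w = att.slice(z).colptr(j);
      double* s = S.colptr(z);
      for (uword i = 0; i < nx; ++i) {
        const double v = a[i] * w[i];
        s[i] = v;
        if (v != 0.0) any = true;
      }
    }
    if (!any) continue;
    blur_plane(S, ks[(size_t)j], tmp);
    P += S;
  }
}

// adjoint of forward_view, into the rotated frame (caller rotates back)
void adjoint_view_rot(const mat& G, const cube& att, const std::vector<vec>& ks,
                      cube& out_rot, mat& S, mat& tmp) {
  const uword nx = att.n_rows, ny = att.n_cols, nz = att.n_slices;
  for (uword j = 0; j < ny; ++j) {
    S = G;
    blur_plane(S, ks[(size_t)j], tmp);
    for (uword z = 0; z < nz; ++z) {
      const double* s = S.colptr(z);
      const double* w = att.slice(z).colptr(j);
      double* o = out_rot.slice(z).colptr(j);
      for (uword i = 0; i < nx; ++i) o[i] = s[i] * w[i];
    }
  }
}

} // namespace

// [[Rcpp::export]]
arma::cube cpp_forward_project(const arma::cube& act, const arma::cube& mu,
                               const arma::vec& angles, double voxel_mm,
                               double sigma0_mm, double sigma_slope,
                               double det_radius_mm) {
  const uword nx = act.n_rows, ny = act.n_cols, nz = act.n_slices;
  const uword nv = angles.n_elem;
  const double voxlen_cm = voxel_mm / 10.0;
  const std::vector<vec> ks =
      slab_kernels((int)ny, voxel_mm, sigma0_mm, sigma_slope, det_radius_mm);
  cube proj(nx, nz, nv, fill::zeros);
  cube act_rot(nx, ny, nz), mu_rot(nx, ny, nz);
  mat P, S(nx, nz), tmp(nx, nz);
  const bool has_mu = accu(mu) > 0.0;
  for (uword v = 0; v < nv; ++v) {
    const RotMap m = build_rot_map((int)nx, (int)ny, angles[v]);
    rot_gather(act, act_rot, m);
    cube att;
    if (has_mu) {
      rot_gather(mu, mu_rot, m);
      att = att_factors(mu_rot, voxlen_cm);
    } else {
      att = cube(nx, ny, nz, fill::ones);
    }
    forward_view(act_rot, att, ks, P, S, tmp);
    proj.slice(v) = P;
  }
  return proj;
}

// [[Rcpp::export]]
arma::cube cpp_backproject(const arma::cube& proj, const arma::cube& mu,
                           const arma::vec& angles, arma::uword nx,
                           arma::uword ny, double voxel_mm, double sigma0_mm,
                           double sigma_slope, double det_radius_mm) {
  const uword nz = proj.n_cols, nv = angles.n_elem;
  const double voxlen_cm = voxel_mm / 10.0;
  const std::vector<vec> ks =
      slab_kernels((int)ny, voxel_mm, sigma0_mm, sigma_slope, det_radius_mm);
  cube out(nx, ny, nz, fill::zeros), work(nx, ny, nz), mu_rot(nx, ny, nz);
  mat S(nx, nz), tmp(nx, nz);
  const bool has_mu = accu(mu) > 0.0;
  for (uword v = 0; v < nv; ++v) {
    const RotMap m = build_rot_map((int)nx, (int)ny, angles[v]);
    cube att;
    if (has_mu) {
      rot_gather(mu, mu_rot, m);
      att = att_factors(mu_rot, voxlen_cm);
    } else {
      att = cube(nx, ny, nz, fill::ones);
    }
    adjoint_view_rot(proj.slice(v), att, ks, work, S, tmp);
    rot_scatter(work, out, m);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_osem(const arma::cube& proj, const arma::cube& mu,
                    const arma::vec& angles, const Rcpp::List& subsets,
                    int n_iter, const arma::cube& init,
                    const arma::ivec& snapshot_iters, double voxel_mm,
                    double sigma0_mm, double sigma_slope, double det_radius_mm,
                    double sens_eps) {
  const uword nx = init.n_rows, ny = init.n_cols, nz = init.n_slices;
  const uword nv = angles.n_elem;
  const double voxlen_cm = voxel_mm / 10.0;
  const std::vector<vec> ks =
      slab_kernels((int)ny, voxel_mm, sigma0_mm, sigma_slope, det_radius_mm);
  const bool has_mu = accu(mu) > 0.0;

  // per-view precomputations shared across all updates
  std::vector<RotMap> maps((size_t)nv);
  std::vector<cube> atts((size_t)nv);
  cube mu_rot(nx, ny, nz);
  for (uword v = 0; v < nv; ++v) {
    maps[(size_t)v] = build_rot_map((int)nx, (int)ny, angles[v]);
    if (has_mu) {
      rot_gather(mu, mu_rot, maps[(size_t)v]);
      atts[(size_t)v] = att_factors(mu_rot, voxlen_cm);
    } else {
      atts[(size_t)v] = cube(nx, ny, nz, fill::ones);
    }
  }

  const int n_sub = subsets.size();
  std::vector<uvec> subs((size_t)n_sub);
  for (int k = 0; k < n_sub; ++k)
    subs[(size_t)k] = Rcpp::as<uvec>(subsets[k]);

  // subset sensitivity images: A_k^T 1
  mat ones_det(nx, nz, fill::ones);
  std::vector<cube> sens((size_t)n_sub);
  cube work(nx, ny, nz);
  mat S(nx, nz), tmp(nx, nz);
  for (int k = 0; k < n_sub; ++k) {
    cube sk(nx, ny, nz, fill::zeros);
    for (uword iv = 0; iv < subs[(size_t)k].n_elem; ++iv) {
      const uword v = subs[(size_t)k][iv];
      adjoint_view_rot(ones_det, atts[(size_t)v], ks, work, S, tmp);
      rot_scatter(work, sk, maps[(size_t)v]);
    }
    sens[(size_t)k] = sk;
  }

  cube x = init;
  cube x_rot(nx, ny, nz), back(nx, ny, nz);
  mat P(nx, nz), ratio(nx, nz);
  Rcpp::List snaps;
  std::vector<std::string> snap_names;
  uword si = 0;

  for (int it = 1; it <= n_iter; ++it) {
    for (int k = 0; k < n_sub; ++k) {
      back.zeros();
      for (uword iv = 0; iv < subs[(size_t)k].n_elem; ++iv) {
        const uword v = subs[(size_t)k][iv];
        rot_gather(x, x_rot, maps[(size_t)v]);
        forward_view(x_rot, atts[(size_t)v], ks, P, S, tmp);
        const mat& y = proj.slice(v);
        for (uword i = 0; i < P.n_elem; ++i)
          ratio[i] = (P[i] > 1e-12) ? y[i] / P[i] : 0.0;
        adjoint_view_rot(ratio, atts[(size_t)v], ks, work, S, tmp);
        rot_scatter(work, back, maps[(size_t)v]);
      }
      const cube& sk = sens[(size_t)k];
      for (uword i = 0; i < x.n_elem; ++i)
        x[i] = (sk[i] > sens_eps) ? x[i] * back[i] / sk[i] : 0.0;
    }
    if (si < snapshot_iters.n_elem && snapshot_iters[si] == it) {
      snaps.push_back(x);
      snap_names.push_back(std::to_string(it));
      ++si;
    }
    Rcpp::checkUserInterrupt();
  }
  snaps.attr("names") = Rcpp::wrap(snap_names);
  return Rcpp::List::create(Rcpp::Named("final") = x,
                            Rcpp::Named("snapshots") = snaps);
}
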