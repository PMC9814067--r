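#include <Rcpp.h>
using namespace Rcpp;

// Voxel-driven parallel-beam projector: rigid-transform sample-frame points
// and splat their attenuation onto the detector with bilinear weights.
// Bilinear splatting preserves total mass and first moments exactly, so
// projected centroids are sub-pixel accurate by construction.
//
// pts  : N x 3 sample-frame coordinates relative to the rotation-axis origin
// val  : N attenuation values (already scaled by voxel size)
// rot  : 3 x 3 rigid transform, lab = rot * sample
// u_c, v_c : detector center in 0-based pixel coordinates
// nu, nv   : detector width / height in pixels
// Returns an nv x nu image (row = v, col = u); out-of-bounds mass is clipped.
// [[Rcpp::export]]
NumericMatrix splat_project(const NumericMatrix& pts,
                            const NumericVector& val,
                            const NumericMatrix& rot,
                            double u_c, double v_c,
                            int nu, int nv) {
  const int n = pts.nrow();
  NumericMatrix img(nv, nu);
  const double r00 = rot(0, 0), r01 = rot(0, 1), r02 = rot(0, 2);
  const double r10 = rot(1, 0), r11 = rot(1, 1), r12 = rot(1, 2);
  for (int i = 0; i < n; ++i) {
    const double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    const double u = u_c + r00 * x + r01 * y + r02 * z;
    const double v = v_c + r10 * x + r11 * y + r12 * z;
    const double uf = std::floor(u), vf = std::floor(v);
    const int u0 = (int)uf, v0 = (int)vf;
    const double fu = u - uf, fv = v - vf;
    const double w = val[i];
    if (u0 >= 0 && u0 < nu && v0 >= 0 && v0 < nv)
      img(v0, u0) += w * (1.0 - fu) * (1.0 - fv);
    if (u0 + 1 >= 0 && u0 + 1 < nu && v0 >= 0 && v0 < nv)
      img(v0, u0 + 1) += w * fu * (1.0 - fv);
    if (u0 >= 0 && u0 < nu && v0 + 1 >= 0 && v0 + 1 < nv)
      img(v0 + 1, u0) += w * (1.0 - fu) * fv;
    if (u0 + 1 >= 0 && u0 + 1 < nu && v0 + 1 >= 0 && v0 + 1 < nv)
      img(v0 + 1, u0 + 1) += w * fu * fv;
  }
  return img;
}
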