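// Voxel rasterization of strut lattices, separable 3D convolution and
// frame-element assembly kernels.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rasterize capsule-free cylinders (finite struts) onto a voxel grid by
// exact point-to-segment distance, visiting each strut's bounding box.
// Returns the solid mask and, if near_field > 0, the distance from voxel
// centre to the nearest strut *surface* up to near_field (Inf elsewhere).
// [[Rcpp::export]]
List cpp_rasterize(NumericMatrix A, NumericMatrix B, NumericVector radii,
                   NumericVector origin, double h, IntegerVector dims,
                   double near_field) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  LogicalVector mask(ntot, false);
  NumericVector cov(ntot);  // first-order partial-volume coverage in [0,1]
  NumericVector dist(0);
  bool want_dist = near_field > 0;
  if (want_dist) {
    dist = NumericVector(ntot);
    std::fill(dist.begin(), dist.end(), R_PosInf);
  }
  const int m = A.nrow();
  for (int s = 0; s < m; ++s) {
    const double ax = A(s, 0), ay = A(s, 1), az = A(s, 2);
    const double bx = B(s, 0), by = B(s, 1), bz = B(s, 2);
    const double r = radii[s];
    const double reach = r + near_field + 0.5 * h;
    const double r2 = r * r;
    const double ux = bx - ax, uy = by - ay, uz = bz - az;
    const double L2 = ux * ux + uy * uy + uz * uz;
    int lo[3], hi[3];
    const double mn[3] = {std::min(ax, bx), std::min(ay, by), std::min(az, bz)};
    const double mx[3] = {std::max(ax, bx), std::max(ay, by), std::max(az, bz)};
    const int dd[3] = {nx, ny, nz};
    bool empty = false;
    for (int k = 0; k < 3; ++k) {
      lo[k] = (int)std::floor((mn[k] - reach - origin[k]) / h);
      hi[k] = (int)std::ceil((mx[k] + reach - origin[k]) / h) - 1;
      if (lo[k] < 0) lo[k] = 0;
      if (hi[k] > dd[k] - 1) hi[k] = dd[k] - 1;
      if (lo[k] > hi[k]) empty = true;
    }
    if (empty) continue;
    for (int kz = lo[2]; kz <= hi[2]; ++kz) {
      const double pz = origin[2] + (kz + 0.5) * h;
      for (int ky = lo[1]; ky <= hi[1]; ++ky) {
        const double py = origin[1] + (ky + 0.5) * h;
        const R_xlen_t base = (R_xlen_t)nx * (ky + (R_xlen_t)ny * kz);
        for (int kx = lo[0]; kx <= hi[0]; ++kx) {
          const double px = origin[0] + (kx + 0.5) * h;
          double t = ((px - ax) * ux + (py - ay) * uy + (pz - az) * uz) / L2;
          if (t < 0) t = 0; else if (t > 1) t = 1;
          const double dx = px - (ax + t * ux);
          const double dy = py - (ay + t * uy);
          const double dz = pz - (az + t * uz);
          const double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 > reach * reach) continue;
          const R_xlen_t lin = base + kx;
          const double dd = std::sqrt(d2);
          if (d2 <= r2) mask[lin] = true;
          double w = 0.5 + (r - dd) / h;
          if (w > 1) w = 1; else if (w < 0) w = 0;
          if (w > cov[lin]) cov[lin] = w;
          if (want_dist) {
            const double surf = dd - r;
            if (surf < dist[lin]) dist[lin] = surf;
          }
        }
      }
    }
  }
  if (want_dist)
    return List::create(_["mask"] = mask, _["cov"] = cov, _["dist"] = dist);
  return List::create(_["mask"] = mask, _["cov"] = cov);
}

// Separable convolution along one axis (1 = x, 2 = y, 3 = z) with
// replicate boundary handling. kernel length must be odd.
// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector vol, IntegerVector dims,
                            NumericVector kernel, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int kl = kernel.size();
  const int kh = kl / 2;
  NumericVector out((R_xlen_t)nx * ny * nz);
  const int n_ax = (axis == 1) ? nx : (axis == 2) ? ny : nz;
  const R_xlen_t stride = (axis == 1) ? 1 :
    (axis == 2) ? (R_xlen_t)nx : (R_xlen_t)nx * ny;
  // iterate over all lines along the axis
  const R_xlen_t nlines = ((R_xlen_t)nx * ny * nz) / n_ax;
  for (R_xlen_t line = 0; line < nlines; ++line) {
    // compute the base index of this line
    R_xlen_t base;
    if (axis == 1) {
      base = line * nx;
    } else if (axis == 2) {
      const R_xlen_t xz = line;          // combined x and z counter
      const R_xlen_t x = xz % nx, z = xz / nx;
      base = x + (R_xlen_t)nx * ny * z;
    } else {
      base = line;                        // x + nx*y
    }
    for (int i = 0; i < n_ax; ++i) {
      double acc = 0;
      for (int k = 0; k < kl; ++k) {
        int j = i + k - kh;
        if (j < 0) j = 0; else if (j > n_ax - 1) j = n_ax - 1;
        acc += kernel[k] * vol[base + (R_xlen_t)j * stride];
      }
      out[base + (R_xlen_t)i * stride] = acc;
    }
  }
  return out;
}

// Triplets (i, j, x) of the assembled 3D Euler-Bernoulli frame stiffness
// matrix, 6 DOF per node. klocal entries are built per element from
// (E, G, A, I, J, L); T is block-diagonal from the element rotation.
// shear_kappa > 0 enables Timoshenko shear deformation with that shear
// coefficient (0.9 for circular sections); 0 gives Euler-Bernoulli.
// bending_factor scales I and J; a tiny value approximates pin-jointed
// (axial-only truss) behaviour while keeping the system nonsingular.
// [[Rcpp::export]]
List cpp_frame_triplets(NumericMatrix nodes, IntegerMatrix struts,
                        NumericVector radii, double E, double G,
                        double shear_kappa, double bending_factor) {
  const int m = struts.nrow();
  IntegerVector ii(m * 144), jj(m * 144);
  NumericVector xx(m * 144);
  double kl[12][12], T[12][12], kg[12][12], tmp[12][12];
  for (int e = 0; e < m; ++e) {
    const int n1 = struts(e, 0) - 1, n2 = struts(e, 1) - 1;
    double u[3] = {nodes(n2, 0) - nodes(n1, 0),
                   nodes(n2, 1) - nodes(n1, 1),
                   nodes(n2, 2) - nodes(n1, 2)};
    const double L = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    const double r = radii[e];
    const double Aa = M_PI * r * r;
    const double I = bending_factor * M_PI * r * r * r * r / 4.0;
    const double Jt = 2.0 * I;
    for (int a = 0; a < 12; ++a)
      for (int b = 0; b < 12; ++b) { kl[a][b] = 0; T[a][b] = 0; }
    const double ax = E * Aa / L, tz = G * Jt / L;
    double phi = 0;
    if (shear_kappa > 0)
      phi = 12.0 * E * I / (shear_kappa * Aa * G * L * L);
    const double b1 = 12 * E * I / ((1 + phi) * L * L * L);
    const double b2 = 6 * E * I / ((1 + phi) * L * L);
    const double b3 = (4 + phi) * E * I / ((1 + phi) * L);
    const double b4 = (2 - phi) * E * I / ((1 + phi) * L);
    kl[0][0] = kl[6][6] = ax; kl[0][6] = kl[6][0] = -ax;
    kl[3][3] = kl[9][9] = tz; kl[3][9] = kl[9][3] = -tz;
    kl[1][1] = kl[7][7] = b1; kl[1][7] = kl[7][1] = -b1;
    kl[1][5] = kl[5][1] = b2; kl[1][11] = kl[11][1] = b2;
    kl[7][5] = kl[5][7] = -b2; kl[7][11] = kl[11][7] = -b2;
    kl[5][5] = kl[11][11] = b3; kl[5][11] = kl[11][5] = b4;
    kl[2][2] = kl[8][8] = b1; kl[2][8] = kl[8][2] = -b1;
    kl[2][4] = kl[4][2] = -b2; kl[2][10] = kl[10][2] = -b2;
    kl[8][4] = kl[4][8] = b2; kl[8][10] = kl[10][8] = b2;
    kl[4][4] = kl[10][10] = b3; kl[4][10] = kl[10][4] = b4;
    // local axes: x along strut, y/z any orthonormal complement
    double x0 = u[0] / L, x1 = u[1] / L, x2 = u[2] / L;
    double ref[3] = {0, 0, 1};
    if (std::fabs(x2) >= 0.9) { ref[0] = 1; ref[2] = 0; }
    double dot = ref[0] * x0 + ref[1] * x1 + ref[2] * x2;
    double y0 = ref[0] - dot * x0, y1 = ref[1] - dot * x1,
      y2 = ref[2] - dot * x2;
    const double ny_ = std::sqrt(y0 * y0 + y1 * y1 + y2 * y2);
    y0 /= ny_; y1 /= ny_; y2 /= ny_;
    const double z0 = x1 * y2 - x2 * y1;
    const double z1 = x2 * y0 - x0 * y2;
    const double z2 = x0 * y1 - x1 * y0;
    const double Rm[3][3] = {{x0, x1, x2}, {y0, y1, y2}, {z0, z1, z2}};
    for (int b = 0; b < 4; ++b)
      for (int p = 0; p < 3; ++p)
        for (int q = 0; q < 3; ++q)
          T[b * 3 + p][b * 3 + q] = Rm[p][q];
    // kg = T' kl T
    for (int a = 0; a < 12; ++a)
      for (int b = 0; b < 12; ++b) {
        double acc = 0;
        for (int c = 0; c < 12; ++c) acc += kl[a][c] * T[c][b];
        tmp[a][b] = acc;
      }
    for (int a = 0; a < 12; ++a)
      for (int b = 0; b < 12; ++b) {
        double acc = 0;
        for (int c = 0; c < 12; ++c) acc += T[c][a] * tmp[c][b];
        kg[a][b] = acc;
      }
    int dof[12];
    for (int p = 0; p < 6; ++p) { dof[p] = n1 * 6 + p + 1; dof[6 + p] = n2 * 6 + p + 1; }
    const R_xlen_t off = (R_xlen_t)e * 144;
    for (int a = 0; a < 12; ++a)
      for (int b = 0; b < 12; ++b) {
        ii[off + a * 12 + b] = dof[a];
        jj[off + a * 12 + b] = dof[b];
        xx[off + a * 12 + b] = kg[a][b];
      }
  }
  return List::create(_["i"] = ii, _["j"] = jj, _["x"] = xx);
}
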