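#include <Rcpp.h>
using namespace Rcpp;

// Shared analytic pencil-beam kernel helpers.
//
// Geometry convention: the dose grid is a 3D array in column-major order
// (x fastest), voxel centre of index (i,j,k) at origin + index * spacing.
// Beams travel along one grid axis; `wed` holds the water-equivalent depth
// (mm) of each voxel along that beam, precomputed in R.

static inline double idd_interp(const NumericMatrix& idd, int eidx,
                                double z, double dz, int ndepth) {
  if (z < 0.0) return 0.0;
  double fi = z / dz;
  int i0 = (int)fi;
  if (i0 >= ndepth - 1) return 0.0;
  double f = fi - i0;
  return idd(i0, eidx) * (1.0 - f) + idd(i0 + 1, eidx) * f;
}

static inline double sigma_at_depth(double sigma_iso, double r0,
                                    double z, double mcs_k, double mcs_p) {
  double t = z / r0;
  if (t > 1.0) t = 1.0;
  if (t < 0.0) t = 0.0;
  double s_mcs = mcs_k * r0 * std::pow(t, mcs_p);
  return std::sqrt(sigma_iso * sigma_iso + s_mcs * s_mcs);
}

// Deposit a set of spots of one field into the full dose grid (in place).
// spots columns: u (mm, lateral axis la1), v (mm, lateral axis la2),
// mu, eidx (0-based energy index).
// [[Rcpp::export]]
void cpp_deposit_spots(NumericVector dose, IntegerVector dims,
                       NumericVector spacing, NumericVector origin,
                       NumericVector wed, int axis,
                       NumericMatrix spots,
                       NumericVector r0_e, NumericVector sigma_e,
                       NumericMatrix idd, double idd_dz,
                       double mcs_k, double mcs_p,
                       NumericVector shift, double depth_shift,
                       double range_scale, double cutoff_sigmas,
                       double output_factor) {
  const int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  int la1, la2;
  if (axis == 0)      { la1 = 1; la2 = 2; }
  else if (axis == 1) { la1 = 0; la2 = 2; }
  else                { la1 = 0; la2 = 1; }
  const int nd[3] = {n0, n1, n2};
  const long strides[3] = {1L, (long)n0, (long)n0 * n1};
  const int ndepth = idd.nrow();
  const double max_z = (ndepth - 1) * idd_dz;
  const int nspots = spots.nrow();

  for (int s = 0; s < nspots; ++s) {
    const double mu = spots(s, 2);
    if (mu <= 0.0) continue;
    const int eidx = (int)spots(s, 3);
    const double r0 = r0_e[eidx];
    const double sig_iso = sigma_e[eidx];
    const double cu = spots(s, 0) + shift[la1];
    const double cv = spots(s, 1) + shift[la2];
    const double sig_max = std::sqrt(sig_iso * sig_iso +
                                     mcs_k * r0 * mcs_k * r0);
    const double rad = cutoff_sigmas * sig_max;
    const double rad2 = rad * rad;

    int i1lo = (int)std::ceil((cu - rad - origin[la1]) / spacing[la1]);
    int i1hi = (int)std::floor((cu + rad - origin[la1]) / spacing[la1]);
    int i2lo = (int)std::ceil((cv - rad - origin[la2]) / spacing[la2]);
    int i2hi = (int)std::floor((cv + rad - origin[la2]) / spacing[la2]);
    if (i1lo < 0) i1lo = 0;
    if (i2lo < 0) i2lo = 0;
    if (i1hi > nd[la1] - 1) i1hi = nd[la1] - 1;
    if (i2hi > nd[la2] - 1) i2hi = nd[la2] - 1;

    for (int i1 = i1lo; i1 <= i1hi; ++i1) {
      const double du = origin[la1] + i1 * spacing[la1] - cu;
      const double du2 = du * du;
      for (int i2 = i2lo; i2 <= i2hi; ++i2) {
        const double dv = origin[la2] + i2 * spacing[la2] - cv;
        const double l2 = du2 + dv * dv;
        if (l2 > rad2) continue;
        const long base = i1 * strides[la1] + i2 * strides[la2];
        for (int ib = 0; ib < nd[axis]; ++ib) {
          const long idx = base + ib * strides[axis];
          const double z = (wed[idx] - depth_shift) / range_scale;
          if (z < 0.0 || z >= max_z) continue;
          const double dval = idd_interp(idd, eidx, z, idd_dz, ndepth);
          if (dval <= 0.0) continue;
          const double sig = sigma_at_depth(sig_iso, r0, z, mcs_k, mcs_p);
          const double g = std::exp(-l2 / (2.0 * sig * sig)) /
                           (2.0 * M_PI * sig * sig);
          dose[idx] += mu * dval * g * output_factor;
        }
      }
    }
  }
}

// Influence matrix of one field's spots at arbitrary sample points:
// returns npts x nspots matrix of dose per unit MU.
// pts columns: x, y, z (mm); wed_pts: water-equivalent depth at each point.
// [[Rcpp::export]]
NumericMatrix cpp_influence(NumericMatrix pts, NumericVector wed_pts,
                            int axis, NumericMatrix spots,
                            NumericVector r0_e, NumericVector sigma_e,
                            NumericMatrix idd, double idd_dz,
                            double mcs_k, double mcs_p,
                            NumericVector shift, double depth_shift,
                            double range_scale, double cutoff_sigmas,
                            double output_factor) {
  int la1, la2;
  if (axis == 0)      { la1 = 1; la2 = 2; }
  else if (axis == 1) { la1 = 0; la2 = 2; }
  else                { la1 = 0; la2 = 1; }
  const int npts = pts.nrow();
  const int nspots = spots.nrow();
  const int ndepth = idd.nrow();
  NumericMatrix out(npts, nspots);

  for (int s = 0; s < nspots; ++s) {
    const int eidx = (int)spots(s, 3);
    const double r0 = r0_e[eidx];
    const double sig_iso = sigma_e[eidx];
    const double cu = spots(s, 0) + shift[la1];
    const double cv = spots(s, 1) + shift[la2];
    const double sig_max = std::sqrt(sig_iso * sig_iso +
                                     mcs_k * r0 * mcs_k * r0);
    const double rad2 = cutoff_sigmas * sig_max * cutoff_sigmas * sig_max;
    for (int p = 0; p < npts; ++p) {
      const double du = pts(p, la1) - cu;
      const double dv = pts(p, la2) - cv;
      const double l2 = du * du + dv * dv;
      if (l2 > rad2) continue;
      const double z = (wed_pts[p] - depth_shift) / range_scale;
      const double dval = idd_interp(idd, eidx, z, idd_dz, ndepth);
      if (dval <= 0.0) continue;
      const double sig = sigma_at_depth(sig_iso, r0, z, mcs_k, mcs_p);
      out(p, s) = dval * std::exp(-l2 / (2.0 * sig * sig)) /
                  (2.0 * M_PI * sig * sig) * output_factor;
    }
  }
  return out;
}

static inline double trilinear(const NumericVector& vol, const int* nd,
                               const double* sp, const double* org,
                               double x, double y, double z) {
  double fx = (x - org[0]) / sp[0];
  double fy = (y - org[1]) / sp[1];
  double fz = (z - org[2]) / sp[2];
  if (fx < 0.0 || fy < 0.0 || fz < 0.0 ||
      fx > nd[0] - 1 || fy > nd[1] - 1 || fz > nd[2] - 1)
    return 0.0;
  int i0 = (int)fx, j0 = (int)fy, k0 = (int)fz;
  if (i0 > nd[0] - 2) i0 = nd[0] - 2;
  if (j0 > nd[1] - 2) j0 = nd[1] - 2;
  if (k0 > nd[2] - 2) k0 = nd[2] - 2;
  if (nd[0] == 1) i0 = 0;
  if (nd[1] == 1) j0 = 0;
  if (nd[2] == 1) k0 = 0;
  double ax = fx - i0, ay = fy - j0, az = fz - k0;
  const long sx = 1, sy = nd[0], sz = (long)nd[0] * nd[1];
  long b = i0 * sx + j0 * sy + k0 * sz;
  int i1 = (nd[0] > 1) ? 1 : 0;
  int j1 = (nd[1] > 1) ? 1 : 0;
  int k1 = (nd[2] > 1) ? 1 : 0;
  double c00 = vol[b] * (1 - ax) + vol[b + i1 * sx] * ax;
  double c10 = vol[b + j1 * sy] * (1 - ax) + vol[b + i1 * sx + j1 * sy] * ax;
  double c01 = vol[b + k1 * sz] * (1 - ax) + vol[b + i1 * sx + k1 * sz] * ax;
  double c11 = vol[b + j1 * sy + k1 * sz] * (1 - ax) +
               vol[b + i1 * sx + j1 * sy + k1 * sz] * ax;
  double c0 = c00 * (1 - ay) + c10 * ay;
  double c1 = c01 * (1 - ay) + c11 * ay;
  return c0 * (1 - az) + c1 * az;
}

// Trilinear samples of a volume at arbitrary points (outside -> 0).
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dims,
                            NumericVector spacing, NumericVector origin,
                            NumericMatrix pts) {
  const int nd[3] = {dims[0], dims[1], dims[2]};
  const double sp[3] = {spacing[0], spacing[1], spacing[2]};
  const double org[3] = {origin[0], origin[1], origin[2]};
  const int n = pts.nrow();
  NumericVector out(n);
  for (int p = 0; p < n; ++p)
    out[p] = trilinear(vol, nd, sp, org, pts(p, 0), pts(p, 1), pts(p, 2));
  return out;
}

// Pull a phase dose back to the reference phase: out(r) = dose(r + u(r)),
// where u (nvox x 3, mm) is the displacement field from reference to phase.
// [[Rcpp::export]]
NumericVector cpp_pullback(NumericVector dose, IntegerVector dims,
                           NumericVector spacing, NumericVector origin,
                           NumericMatrix disp) {
  const int nd[3] = {dims[0], dims[1], dims[2]};
  const double sp[3] = {spacing[0], spacing[1], spacing[2]};
  const double org[3] = {origin[0], origin[1], origin[2]};
  NumericVector out((long)nd[0] * nd[1] * nd[2]);
  long v = 0;
  for (int k = 0; k < nd[2]; ++k) {
    const double z = org[2] + k * sp[2];
    for (int j = 0; j < nd[1]; ++j) {
      const double y = org[1] + j * sp[1];
      for (int i = 0; i < nd[0]; ++i, ++v) {
        const double x = org[0] + i * sp[0];
        out[v] = trilinear(dose, nd, sp, org,
                           x + disp(v, 0), y + disp(v, 1), z + disp(v, 2));
      }
    }
  }
  return out;
}
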