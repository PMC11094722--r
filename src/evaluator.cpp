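// Hot path of the pose search: torsion-tree kinematics, rigid rotation,
// and trilinear grid scoring. The R-level score_pose()/apply_genome() are
// the reference implementations; the test suite asserts both paths agree.

#include <Rcpp.h>
using namespace Rcpp;

static inline void rotate_point(double *p, const double *axis_p1,
                                const double *u, double c, double s) {
  // rotate p about the unit axis u anchored at axis_p1 (Rodrigues)
  double v[3] = {p[0] - axis_p1[0], p[1] - axis_p1[1], p[2] - axis_p1[2]};
  double cross[3] = {u[1] * v[2] - u[2] * v[1],
                     u[2] * v[0] - u[0] * v[2],
                     u[0] * v[1] - u[1] * v[0]};
  double dot = u[0] * v[0] + u[1] * v[1] + u[2] * v[2];
  for (int d = 0; d < 3; ++d) {
    p[d] = axis_p1[d] + v[d] * c + cross[d] * s + u[d] * dot * (1.0 - c);
  }
}

// Apply a genome (torsion increments, orientation quaternion, centroid
// translation) to the input coordinates.
// [[Rcpp::export]]
NumericMatrix pose_from_genome_cpp(const NumericMatrix &xyz0,
                                   const IntegerVector &tor_i,
                                   const IntegerVector &tor_j,
                                   const List &tor_moving,
                                   const NumericVector &torsions,
                                   const NumericVector &quat,
                                   const NumericVector &translation) {
  const int n = xyz0.nrow();
  NumericMatrix out(n, 3);
  std::vector<double> X(3 * n);
  for (int a = 0; a < n; ++a) {
    X[3 * a] = xyz0(a, 0); X[3 * a + 1] = xyz0(a, 1); X[3 * a + 2] = xyz0(a, 2);
  }
  const int k = torsions.size();
  for (int t = 0; t < k; ++t) {
    double ang = torsions[t];
    if (ang == 0.0) continue;
    const int ai = tor_i[t] - 1, aj = tor_j[t] - 1;
    double u[3] = {X[3 * aj] - X[3 * ai], X[3 * aj + 1] - X[3 * ai + 1],
                   X[3 * aj + 2] - X[3 * ai + 2]};
    double nrm = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    if (nrm < 1e-12) continue;
    for (int d = 0; d < 3; ++d) u[d] /= nrm;
    // torsion gene = dihedral increment; right-handed rotation about the
    // i->j axis changes the dihedral by -ang (matches apply_genome in R)
    double c = std::cos(-ang), s = std::sin(-ang);
    IntegerVector mv = tor_moving[t];
    double anchor[3] = {X[3 * ai], X[3 * ai + 1], X[3 * ai + 2]};
    for (int m = 0; m < mv.size(); ++m) {
      rotate_point(&X[3 * (mv[m] - 1)], anchor, u, c, s);
    }
  }
  // centroid of the post-torsion conformation
  double ctr[3] = {0, 0, 0};
  for (int a = 0; a < n; ++a)
    for (int d = 0; d < 3; ++d) ctr[d] += X[3 * a + d];
  for (int d = 0; d < 3; ++d) ctr[d] /= n;
  // rotation matrix from the unit quaternion (w, x, y, z)
  const double w = quat[0], x = quat[1], y = quat[2], z = quat[3];
  const double R[3][3] = {
    {1 - 2 * (y * y + z * z), 2 * (x * y - w * z), 2 * (x * z + w * y)},
    {2 * (x * y + w * z), 1 - 2 * (x * x + z * z), 2 * (y * z - w * x)},
    {2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x * x + y * y)}};
  for (int a = 0; a < n; ++a) {
    double v[3] = {X[3 * a] - ctr[0], X[3 * a + 1] - ctr[1],
                   X[3 * a + 2] - ctr[2]};
    for (int d = 0; d < 3; ++d) {
      out(a, d) = R[d][0] * v[0] + R[d][1] * v[1] + R[d][2] * v[2] +
        ctr[d] + translation[d];
    }
  }
  return out;
}

// Trilinear grid score: per-atom affinity lookup (maps grouped by atom
// type) plus charge-weighted electrostatic lookup; fixed penalty per atom
// outside the box.
// [[Rcpp::export]]
double grid_score_cpp(const NumericMatrix &xyz, const List &group_values,
                      const List &group_idx, const NumericVector &evalues,
                      const NumericVector &charges,
                      const NumericVector &org, double h,
                      const IntegerVector &npts, double penalty) {
  const int n = xyz.nrow();
  const int d1 = npts[0] + 1, d12 = d1 * (npts[1] + 1);
  std::vector<int> base(n);
  std::vector<double> w(8 * n);
  std::vector<bool> ok(n);
  double total = 0.0;
  for (int a = 0; a < n; ++a) {
    double fx = (xyz(a, 0) - org[0]) / h;
    double fy = (xyz(a, 1) - org[1]) / h;
    double fz = (xyz(a, 2) - org[2]) / h;
    bool inside = fx >= 0 && fy >= 0 && fz >= 0 &&
      fx <= npts[0] && fy <= npts[1] && fz <= npts[2];
    ok[a] = inside;
    if (!inside) { total += penalty; continue; }
    int i0 = std::min((int)std::floor(fx), npts[0] - 1);
    int j0 = std::min((int)std::floor(fy), npts[1] - 1);
    int k0 = std::min((int)std::floor(fz), npts[2] - 1);
    double tx = fx - i0, ty = fy - j0, tz = fz - k0;
    base[a] = i0 + j0 * d1 + k0 * d12;
    double *wa = &w[8 * a];
    wa[0] = (1 - tx) * (1 - ty) * (1 - tz); wa[1] = tx * (1 - ty) * (1 - tz);
    wa[2] = (1 - tx) * ty * (1 - tz);       wa[3] = tx * ty * (1 - tz);
    wa[4] = (1 - tx) * (1 - ty) * tz;       wa[5] = tx * (1 - ty) * tz;
    wa[6] = (1 - tx) * ty * tz;             wa[7] = tx * ty * tz;
  }
  for (int g = 0; g < group_values.size(); ++g) {
    NumericVector vals = group_values[g];
    IntegerVector idx = group_idx[g];
    const double *v = REAL(vals);
    for (int m = 0; m < idx.size(); ++m) {
      const int a = idx[m] - 1;
      if (!ok[a]) continue;
      const int b = base[a];
      const double *wa = &w[8 * a];
      total += v[b] * wa[0] + v[b + 1] * wa[1] +
        v[b + d1] * wa[2] + v[b + 1 + d1] * wa[3] +
        v[b + d12] * wa[4] + v[b + 1 + d12] * wa[5] +
        v[b + d1 + d12] * wa[6] + v[b + 1 + d1 + d12] * wa[7];
    }
  }
  const double *ev = REAL(evalues);
  for (int a = 0; a < n; ++a) {
    if (!ok[a] || charges[a] == 0.0) continue;
    const int b = base[a];
    const double *wa = &w[8 * a];
    total += charges[a] * (ev[b] * wa[0] + ev[b + 1] * wa[1] +
      ev[b + d1] * wa[2] + ev[b + 1 + d1] * wa[3] +
      ev[b + d12] * wa[4] + ev[b + 1 + d12] * wa[5] +
      ev[b + d1 + d12] * wa[6] + ev[b + 1 + d1 + d12] * wa[7]);
  }
  return total;
}
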