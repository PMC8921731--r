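#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Forward kinematics of a rigid-body tree.  The flattened model (built by
// assemble_model on the R side) stores, per segment, the joint frame in the
// parent (Rp, pp), the inverse of the joint frame in the child (Rci, pci),
// the joint type and a map from local DOF slots to indices of the free
// coordinate vector.  Segments are topologically ordered (parent before
// child).
//
// Joint types: 0 = free6 (tx ty tz rx ry rz), 1 = ball3 (rx ry rz,
// intrinsic x-y-z), 2 = hinge1 (rz), 3 = locked0.
// Pose of a child segment: X_child = X_parent * Fp * J(q) * Fc^{-1}.

static inline void mat33_mult(const double* A, const double* B, double* C) {
  // column-major 3x3: C = A * B
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < 3; ++i)
      C[i + 3 * j] = A[i] * B[3 * j] + A[i + 3] * B[1 + 3 * j] +
                     A[i + 6] * B[2 + 3 * j];
}

static inline void mat33_vec(const double* A, const double* v, double* w) {
  for (int i = 0; i < 3; ++i)
    w[i] = A[i] * v[0] + A[i + 3] * v[1] + A[i + 6] * v[2];
}

static inline void set_identity(double* R) {
  R[0] = 1; R[1] = 0; R[2] = 0;
  R[3] = 0; R[4] = 1; R[5] = 0;
  R[6] = 0; R[7] = 0; R[8] = 1;
}

// R = Rx(a) * Ry(b) * Rz(c), column-major
static inline void rot_xyz(double a, double b, double c, double* R) {
  const double ca = std::cos(a), sa = std::sin(a);
  const double cb = std::cos(b), sb = std::sin(b);
  const double cc = std::cos(c), sc = std::sin(c);
  // row-wise expansion of Rx*Ry*Rz
  R[0] = cb * cc;
  R[1] = sa * sb * cc + ca * sc;
  R[2] = -ca * sb * cc + sa * sc;
  R[3] = -cb * sc;
  R[4] = -sa * sb * sc + ca * cc;
  R[5] = ca * sb * sc + sa * cc;
  R[6] = sb;
  R[7] = -sa * cb;
  R[8] = ca * cb;
}

static inline void joint_transform(int type, const double* ql,
                                   double* RJ, double* pJ) {
  pJ[0] = pJ[1] = pJ[2] = 0.0;
  switch (type) {
  case 0:  // free6
    pJ[0] = ql[0]; pJ[1] = ql[1]; pJ[2] = ql[2];
    rot_xyz(ql[3], ql[4], ql[5], RJ);
    break;
  case 1:  // ball3
    rot_xyz(ql[0], ql[1], ql[2], RJ);
    break;
  case 2: {  // hinge1 about z
    const double cc = std::cos(ql[0]), sc = std::sin(ql[0]);
    RJ[0] = cc; RJ[1] = sc; RJ[2] = 0;
    RJ[3] = -sc; RJ[4] = cc; RJ[5] = 0;
    RJ[6] = 0; RJ[7] = 0; RJ[8] = 1;
    break;
  }
  default:
    set_identity(RJ);
  }
}

struct FlatModel {
  int nseg, nmark, nfree;
  IntegerVector parent, jtype, markerSeg;
  IntegerMatrix dofmap;            // 6 x nseg, -1 = unused/locked
  NumericMatrix Rp, pp, Rci, pci;  // per-segment placement
  NumericMatrix markerLoc;         // 3 x nmark
  FlatModel(List cm)
      : parent(cm["parent"]), jtype(cm["jtype"]),
        markerSeg(cm["marker_seg"]), dofmap(cm["dofmap"]),
        Rp(cm["Rp"]), pp(cm["pp"]), Rci(cm["Rci"]), pci(cm["pci"]),
        markerLoc(cm["marker_loc"]) {
    nseg = parent.size();
    nmark = markerSeg.size();
    nfree = as<int>(cm["n_free"]);
  }
};

static void fk_core(const FlatModel& m, const double* q,
                    std::vector<double>& Rg, std::vector<double>& pg) {
  double RJ[9], pJ[9], T1[9], T2[9], v1[3], v2[3], ql[6];
  for (int s = 0; s < m.nseg; ++s) {
    for (int k = 0; k < 6; ++k) {
      const int idx = m.dofmap(k, s);
      ql[k] = (idx >= 0) ? q[idx] : 0.0;
    }
    joint_transform(m.jtype[s], ql, RJ, pJ);
    // local = Fp * J * Fc^{-1}
    const double* Rp = &m.Rp(0, s);
    const double* pp = &m.pp(0, s);
    const double* Rci = &m.Rci(0, s);
    const double* pci = &m.pci(0, s);
    mat33_mult(Rp, RJ, T1);   // Rp*RJ
    mat33_mult(T1, Rci, T2);  // Rp*RJ*Rci
    // p_local = pp + Rp*pJ + (Rp*RJ)*pci
    mat33_vec(Rp, pJ, v1);
    mat33_vec(T1, pci, v2);
    double pl[3] = {pp[0] + v1[0] + v2[0], pp[1] + v1[1] + v2[1],
                    pp[2] + v1[2] + v2[2]};
    const int par = m.parent[s];
    double* Rs = &Rg[9 * s];
    double* ps = &pg[3 * s];
    if (par < 0) {
      std::copy(T2, T2 + 9, Rs);
      std::copy(pl, pl + 3, ps);
    } else {
      const double* Rpar = &Rg[9 * par];
      const double* ppar = &pg[3 * par];
      mat33_mult(Rpar, T2, Rs);
      mat33_vec(Rpar, pl, v1);
      ps[0] = ppar[0] + v1[0];
      ps[1] = ppar[1] + v1[1];
      ps[2] = ppar[2] + v1[2];
    }
  }
}

static void markers_core(const FlatModel& m, const std::vector<double>& Rg,
                         const std::vector<double>& pg, double* out) {
  double v[3];
  for (int k = 0; k < m.nmark; ++k) {
    const int s = m.markerSeg[k];
    mat33_vec(&Rg[9 * s], &m.markerLoc(0, k), v);
    out[3 * k] = pg[3 * s] + v[0];
    out[3 * k + 1] = pg[3 * s + 1] + v[1];
    out[3 * k + 2] = pg[3 * s + 2] + v[2];
  }
}

// [[Rcpp::export]]
NumericMatrix fk_markers_cpp(List cm, NumericVector qfree) {
  FlatModel m(cm);
  if (qfree.size() != m.nfree) stop("pose vector length mismatch");
  std::vector<double> Rg(9 * m.nseg), pg(3 * m.nseg), mk(3 * m.nmark);
  fk_core(m, qfree.begin(), Rg, pg);
  markers_core(m, Rg, pg, mk.data());
  NumericMatrix out(m.nmark, 3);
  for (int k = 0; k < m.nmark; ++k)
    for (int j = 0; j < 3; ++j) out(k, j) = mk[3 * k + j];
  return out;
}

// [[Rcpp::export]]
List fk_segments_cpp(List cm, NumericVector qfree) {
  FlatModel m(cm);
  if (qfree.size() != m.nfree) stop("pose vector length mismatch");
  std::vector<double> Rg(9 * m.nseg), pg(3 * m.nseg);
  fk_core(m, qfree.begin(), Rg, pg);
  NumericMatrix R(9, m.nseg), p(3, m.nseg);
  std::copy(Rg.begin(), Rg.end(), R.begin());
  std::copy(pg.begin(), pg.end(), p.begin());
  return List::create(Named("R") = R, Named("p") = p);
}

static void residual_core(const FlatModel& m, const double* q,
                          const NumericMatrix& obs, const NumericVector& sw,
                          const std::vector<int>& use, double* out) {
  std::vector<double> Rg(9 * m.nseg), pg(3 * m.nseg), mk(3 * m.nmark);
  fk_core(m, q, Rg, pg);
  markers_core(m, Rg, pg, mk.data());
  int r = 0;
  for (size_t u = 0; u < use.size(); ++u) {
    const int k = use[u];
    const double w = sw[k];
    out[r++] = w * (mk[3 * k] - obs(k, 0));
    out[r++] = w * (mk[3 * k + 1] - obs(k, 1));
    out[r++] = w * (mk[3 * k + 2] - obs(k, 2));
  }
}

static std::vector<int> used_markers(const FlatModel& m,
                                     const NumericMatrix& obs,
                                     const NumericVector& sw) {
  std::vector<int> use;
  for (int k = 0; k < m.nmark; ++k) {
    if (sw[k] > 0 && R_finite(obs(k, 0)) && R_finite(obs(k, 1)) &&
        R_finite(obs(k, 2)))
      use.push_back(k);
  }
  return use;
}

// Residuals sqrt(w_i) * (model_i - obs_i), stacked xyz per used marker.
// Markers with weight 0 or non-finite observations are skipped.
// [[Rcpp::export]]
NumericVector ik_residual_cpp(List cm, NumericVector qfree, NumericMatrix obs,
                              NumericVector sw) {
  FlatModel m(cm);
  if (qfree.size() != m.nfree) stop("pose vector length mismatch");
  std::vector<int> use = used_markers(m, obs, sw);
  NumericVector out(3 * use.size());
  residual_core(m, qfree.begin(), obs, sw, use, out.begin());
  return out;
}

// Instantaneous axes of the free coordinates: the derivative of a marker
// position wrt a rotational coordinate on an ancestor joint is
// axis x (marker - joint origin); wrt a base translation it is the
// translated axis.  For the intrinsic x-y-z parameterization the axes are
// the intermediate rotated axes (x before Rx, y after Rx, z after Rx*Ry).
static void compute_dof_axes(const FlatModel& m, const NumericVector& qfree,
                             const std::vector<double>& Rg,
                             const std::vector<double>& pg,
                             std::vector<double>& axis,
                             std::vector<double>& point,
                             std::vector<int>& owner,
                             std::vector<int>& is_trans) {
  double RparRp[9], Rx[9], Rxy[9], tmp[9], v[3], ql[6];
  for (int s = 0; s < m.nseg; ++s) {
    bool any = false;
    for (int k = 0; k < 6; ++k) any = any || (m.dofmap(k, s) >= 0);
    if (!any) continue;
    for (int k = 0; k < 6; ++k) {
      const int idx = m.dofmap(k, s);
      ql[k] = (idx >= 0) ? qfree[idx] : 0.0;
    }
    const int par = m.parent[s];
    const double* Rpar = (par >= 0) ? &Rg[9 * par] : NULL;
    double ppar[3] = {0, 0, 0};
    if (par >= 0) { ppar[0] = pg[3 * par]; ppar[1] = pg[3 * par + 1];
                    ppar[2] = pg[3 * par + 2]; }
    if (Rpar) {
      mat33_mult(Rpar, &m.Rp(0, s), RparRp);
    } else {
      std::copy(&m.Rp(0, s), &m.Rp(0, s) + 9, RparRp);
    }
    // joint origin in global, including the base translation if any
    double pJ[3] = {0, 0, 0};
    const int type = m.jtype[s];
    int rot0 = 0;  // local slot of the first rotational coordinate
    if (type == 0) { pJ[0] = ql[0]; pJ[1] = ql[1]; pJ[2] = ql[2]; rot0 = 3; }
    double og[3];
    mat33_vec(&m.Rp(0, s), pJ, v);
    double loc[3] = {m.pp(0, s) + v[0], m.pp(1, s) + v[1], m.pp(2, s) + v[2]};
    if (Rpar) {
      mat33_vec(Rpar, loc, og);
      og[0] += ppar[0]; og[1] += ppar[1]; og[2] += ppar[2];
    } else {
      std::copy(loc, loc + 3, og);
    }
    // translations: axes are the columns of Rpar*Rp
    if (type == 0) {
      for (int e = 0; e < 3; ++e) {
        const int idx = m.dofmap(e, s);
        if (idx < 0) continue;
        owner[idx] = s; is_trans[idx] = 1;
        axis[3 * idx] = RparRp[3 * e];
        axis[3 * idx + 1] = RparRp[3 * e + 1];
        axis[3 * idx + 2] = RparRp[3 * e + 2];
      }
    }
    if (type == 0 || type == 1) {  // x-y-z rotations
      const double a = ql[rot0], b = ql[rot0 + 1];
      const double ca = std::cos(a), sa = std::sin(a);
      const double cb = std::cos(b), sb = std::sin(b);
      Rx[0] = 1; Rx[1] = 0; Rx[2] = 0;
      Rx[3] = 0; Rx[4] = ca; Rx[5] = sa;
      Rx[6] = 0; Rx[7] = -sa; Rx[8] = ca;
      mat33_mult(RparRp, Rx, tmp);     // Rpar*Rp*Rx
      double Ry[9] = {cb, 0, -sb, 0, 1, 0, sb, 0, cb};
      mat33_mult(tmp, Ry, Rxy);        // Rpar*Rp*Rx*Ry
      const double* axmat[3] = {RparRp, tmp, Rxy};
      for (int e = 0; e < 3; ++e) {
        const int idx = m.dofmap(rot0 + e, s);
        if (idx < 0) continue;
        owner[idx] = s; is_trans[idx] = 0;
        axis[3 * idx] = axmat[e][3 * e];
        axis[3 * idx + 1] = axmat[e][3 * e + 1];
        axis[3 * idx + 2] = axmat[e][3 * e + 2];
        point[3 * idx] = og[0]; point[3 * idx + 1] = og[1];
        point[3 * idx + 2] = og[2];
      }
    } else if (type == 2) {  // hinge about the joint z-axis
      const int idx = m.dofmap(0, s);
      if (idx >= 0) {
        owner[idx] = s; is_trans[idx] = 0;
        axis[3 * idx] = RparRp[6];
        axis[3 * idx + 1] = RparRp[7];
        axis[3 * idx + 2] = RparRp[8];
        point[3 * idx] = og[0]; point[3 * idx + 1] = og[1];
        point[3 * idx + 2] = og[2];
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix ik_jacobian_analytic_cpp(List cm, NumericVector qfree,
                                       NumericMatrix obs, NumericVector sw) {
  FlatModel m(cm);
  if (qfree.size() != m.nfree) stop("pose vector length mismatch");
  std::vector<int> use = used_markers(m, obs, sw);
  const int nr = 3 * (int)use.size();
  NumericMatrix J(nr, m.nfree);

  std::vector<double> Rg(9 * m.nseg), pg(3 * m.nseg), mk(3 * m.nmark);
  fk_core(m, qfree.begin(), Rg, pg);
  markers_core(m, Rg, pg, mk.data());
  std::vector<double> axis(3 * m.nfree), point(3 * m.nfree);
  std::vector<int> owner(m.nfree), is_trans(m.nfree, 0);
  compute_dof_axes(m, qfree, Rg, pg, axis, point, owner, is_trans);

  // ancestry: chain[s] true if segment s is on the path from the marker's
  // segment to the root (recomputed per marker; trees are shallow)
  std::vector<char> chain(m.nseg);
  for (size_t u = 0; u < use.size(); ++u) {
    const int k = use[u];
    std::fill(chain.begin(), chain.end(), 0);
    for (int s = m.markerSeg[k]; s >= 0; s = m.parent[s]) chain[s] = 1;
    const double w = sw[k];
    const double* x = &mk[3 * k];
    for (int j = 0; j < m.nfree; ++j) {
      double d0 = 0, d1 = 0, d2 = 0;
      if (chain[owner[j]]) {
        const double* a = &axis[3 * j];
        if (is_trans[j]) {
          d0 = a[0]; d1 = a[1]; d2 = a[2];
        } else {
          const double r0 = x[0] - point[3 * j];
          const double r1 = x[1] - point[3 * j + 1];
          const double r2 = x[2] - point[3 * j + 2];
          d0 = a[1] * r2 - a[2] * r1;
          d1 = a[2] * r0 - a[0] * r2;
          d2 = a[0] * r1 - a[1] * r0;
        }
      }
      J(3 * u, j) = w * d0;
      J(3 * u + 1, j) = w * d1;
      J(3 * u + 2, j) = w * d2;
    }
  }
  return J;
}

// Weighted least-squares cost only (for candidate-step evaluation).
// [[Rcpp::export]]
double ik_cost_cpp(List cm, NumericVector qfree, NumericMatrix obs,
                   NumericVector sw) {
  FlatModel m(cm);
  if (qfree.size() != m.nfree) stop("pose vector length mismatch");
  std::vector<int> use = used_markers(m, obs, sw);
  std::vector<double> Rg(9 * m.nseg), pg(3 * m.nseg), mk(3 * m.nmark);
  fk_core(m, qfree.begin(), Rg, pg);
  markers_core(m, Rg, pg, mk.data());
  double cost = 0;
  for (size_t u = 0; u < use.size(); ++u) {
    const int k = use[u];
    const double w2 = sw[k] * sw[k];
    for (int j = 0; j < 3; ++j) {
      const double d = mk[3 * k + j] - obs(k, j);
      cost += w2 * d * d;
    }
  }
  return cost;
}

// Gauss-Newton normal equations H = J'J, g = J'r and the cost, assembled
// directly from the analytic per-marker Jacobian blocks.  Only the
// coordinates on a marker's kinematic chain contribute, so assembly
// exploits the tree sparsity.
// [[Rcpp::export]]
List ik_normal_cpp(List cm, NumericVector qfree, NumericMatrix obs,
                   NumericVector sw) {
  FlatModel m(cm);
  if (qfree.size() != m.nfree) stop("pose vector length mismatch");
  std::vector<int> use = used_markers(m, obs, sw);
  const int nf = m.nfree;
  NumericMatrix H(nf, nf);
  NumericVector g(nf);
  double cost = 0;

  std::vector<double> Rg(9 * m.nseg), pg(3 * m.nseg), mk(3 * m.nmark);
  fk_core(m, qfree.begin(), Rg, pg);
  markers_core(m, Rg, pg, mk.data());
  std::vector<double> axis(3 * nf), point(3 * nf);
  std::vector<int> owner(nf), is_trans(nf, 0);
  compute_dof_axes(m, qfree, Rg, pg, axis, point, owner, is_trans);

  std::vector<char> chain(m.nseg);
  std::vector<int> act; act.reserve(nf);
  std::vector<double> B(3 * nf);
  for (size_t u = 0; u < use.size(); ++u) {
    const int k = use[u];
    std::fill(chain.begin(), chain.end(), 0);
    for (int s = m.markerSeg[k]; s >= 0; s = m.parent[s]) chain[s] = 1;
    const double w = sw[k];
    const double* x = &mk[3 * k];
    double r[3];
    for (int j = 0; j < 3; ++j) r[j] = w * (x[j] - obs(k, j));
    cost += r[0] * r[0] + r[1] * r[1] + r[2] * r[2];
    act.clear();
    for (int j = 0; j < nf; ++j) {
      if (!chain[owner[j]]) continue;
      const double* a = &axis[3 * j];
      double* b = &B[3 * (int)act.size()];
      if (is_trans[j]) {
        b[0] = w * a[0]; b[1] = w * a[1]; b[2] = w * a[2];
      } else {
        const double r0 = x[0] - point[3 * j];
        const double r1 = x[1] - point[3 * j + 1];
        const double r2 = x[2] - point[3 * j + 2];
        b[0] = w * (a[1] * r2 - a[2] * r1);
        b[1] = w * (a[2] * r0 - a[0] * r2);
        b[2] = w * (a[0] * r1 - a[1] * r0);
      }
      act.push_back(j);
    }
    for (size_t ii = 0; ii < act.size(); ++ii) {
      const double* bi = &B[3 * ii];
      g[act[ii]] += bi[0] * r[0] + bi[1] * r[1] + bi[2] * r[2];
      for (size_t jj = ii; jj < act.size(); ++jj) {
        const double* bj = &B[3 * jj];
        H(act[ii], act[jj]) += bi[0] * bj[0] + bi[1] * bj[1] + bi[2] * bj[2];
      }
    }
  }
  for (int i = 0; i < nf; ++i)
    for (int j = 0; j < i; ++j) H(i, j) = H(j, i);
  return List::create(Named("H") = H, Named("g") = g, Named("cost") = cost);
}

// Central-difference Jacobian of the residual vector wrt the free
// coordinates (step 1e-6 rad / mm).  Kept as an independent check of the
// analytic Jacobian.
// [[Rcpp::export]]
NumericMatrix ik_jacobian_cpp(List cm, NumericVector qfree, NumericMatrix obs,
                              NumericVector sw) {
  FlatModel m(cm);
  if (qfree.size() != m.nfree) stop("pose vector length mismatch");
  std::vector<int> use = used_markers(m, obs, sw);
  const int nr = 3 * (int)use.size();
  NumericMatrix J(nr, m.nfree);
  std::vector<double> q(qfree.begin(), qfree.end());
  std::vector<double> rp(nr), rm(nr);
  const double h = 1e-6;
  for (int j = 0; j < m.nfree; ++j) {
    const double q0 = q[j];
    q[j] = q0 + h;
    residual_core(m, q.data(), obs, sw, use, rp.data());
    q[j] = q0 - h;
    residual_core(m, q.data(), obs, sw, use, rm.data());
    q[j] = q0;
    for (int i = 0; i < nr; ++i) J(i, j) = (rp[i] - rm[i]) / (2 * h);
  }
  return J;
}
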