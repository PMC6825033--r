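// Element-level kernels for the coupled deformation / crack phase-field solver.
//
// Conventions: Cartesian coordinates, reference and spatial metrics absorbed
// (identity).  Mechanics is assembled in updated-Lagrangian form: internal
// virtual work  int_B tau : grad_x(du) dV  with the Kirchhoff stress tau and
// integration over the *reference* volume; spatial shape-function gradients
// are F^{-T} grad_X N.  The phase-field problem lives entirely in the
// reference configuration.
//
// Units: kPa, mm, mN (1 kPa * 1 mm^2 = 1 mN), pseudo-time in s.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct MatPoint {
  double mu, k1, k2, kappa, a_iso, a_ani;
};

// Fibre exponential: psi(I) = k1/(2 k2) [exp(k2 E^2) - 1], E = <I - 1>.
// Returns psi, dpsi/dI, d2psi/dI2 (zero in compression when tension_only).
inline void fiber_psi(double I, double k1, double k2, bool tension_only,
                      double& psi, double& dpsi, double& ddpsi) {
  double E = I - 1.0;
  if (tension_only && E <= 0.0) { psi = 0.0; dpsi = 0.0; ddpsi = 0.0; return; }
  double q = k2 * E * E;
  if (q > 500.0) q = 500.0;  // solver guard; Newton will cut the step anyway
  double ex = std::exp(q);
  psi   = 0.5 * k1 / k2 * (ex - 1.0);
  dpsi  = k1 * E * ex;
  ddpsi = k1 * ex * (1.0 + 2.0 * k2 * E * E);
}

// Effective (undegraded) energies, Kirchhoff stress and spatial tangent
// coefficients at one material point.
//
// tau = giso [ mu (b - I) + kappa/2 (J^2-1) I ] + gani sum_f 2 psi' m_f x m_f
// c   = giso [ kappa J^2 I x I + (2 mu - kappa (J^2-1)) IIsym ]
//       + gani sum_f 4 psi'' m_f x m_f x m_f x m_f
// Geometric stiffness uses the (degraded) tau itself.
struct PointState {
  mat33 tau;          // degraded Kirchhoff stress
  double psi_iso, psi_ani;   // effective energies
  double A, B;        // degraded I x I and IIsym coefficients
  double Cf[2];       // degraded fibre 4th-order coefficients
  vec3 m[2];          // spatial fibre vectors
  int nfib;
  double J;
};

inline bool point_eval(const mat33& F, const MatPoint& mp,
                       const vec3* M, int nfib, double d,
                       bool tension_only, double resid, bool degrade_vol,
                       PointState& out) {
  double J = det(F);
  if (!(J > 0.0) || !F.is_finite()) return false;
  mat33 b = F * F.t();
  double I1 = trace(b);
  double logJ = std::log(J);

  out.psi_iso = 0.5 * mp.mu * (I1 - 3.0 - 2.0 * logJ)
              + 0.25 * mp.kappa * (J * J - 1.0 - 2.0 * logJ);

  double dd = d;
  if (dd < 0.0) dd = 0.0;
  if (dd > 1.0) dd = 1.0;
  double giso = std::pow(1.0 - dd, mp.a_iso) + resid;
  double gani = std::pow(1.0 - dd, mp.a_ani) + resid;

  double gvol = degrade_vol ? giso : 1.0;
  mat33 I3 = eye(3, 3);
  out.tau = giso * mp.mu * (b - I3) + gvol * 0.5 * mp.kappa * (J * J - 1.0) * I3;
  out.A = gvol * mp.kappa * J * J;
  out.B = giso * 2.0 * mp.mu - gvol * mp.kappa * (J * J - 1.0);

  out.psi_ani = 0.0;
  out.nfib = nfib;
  for (int f = 0; f < nfib; ++f) {
    vec3 m = F * M[f];
    double I4 = dot(m, m);
    double psi, dpsi, ddpsi;
    fiber_psi(I4, mp.k1, mp.k2, tension_only, psi, dpsi, ddpsi);
    out.psi_ani += psi;
    out.m[f] = m;
    out.Cf[f] = gani * 4.0 * ddpsi;
    out.tau += gani * 2.0 * dpsi * (m * m.t());
  }
  out.J = J;
  return out.tau.is_finite();
}

// ---- shape functions -----------------------------------------------------

// 4-node quadrilateral, 2x2 Gauss.
const double GP = 0.577350269189625764509148780502;

inline void quad4_shape(double xi, double eta, vec& N, mat& dN) {
  N.set_size(4); dN.set_size(4, 2);
  N[0] = 0.25 * (1 - xi) * (1 - eta);
  N[1] = 0.25 * (1 + xi) * (1 - eta);
  N[2] = 0.25 * (1 + xi) * (1 + eta);
  N[3] = 0.25 * (1 - xi) * (1 + eta);
  dN(0,0) = -0.25*(1-eta); dN(0,1) = -0.25*(1-xi);
  dN(1,0) =  0.25*(1-eta); dN(1,1) = -0.25*(1+xi);
  dN(2,0) =  0.25*(1+eta); dN(2,1) =  0.25*(1+xi);
  dN(3,0) = -0.25*(1+eta); dN(3,1) =  0.25*(1-xi);
}

} // namespace

// ---------------------------------------------------------------------------
// Point-level evaluation, exported for cross-checking the R reference
// implementation (the R functions are the documented reference; this is the
// kernel the assembler uses).
// [[Rcpp::export(name = ".cpp_point_eval")]]
Rcpp::List cpp_point_eval(const arma::mat& F, const arma::mat& Mfib,
                          Rcpp::NumericVector pars, double d,
                          bool tension_only, double resid, bool degrade_vol) {
  MatPoint mp{pars[0], pars[1], pars[2], pars[3], pars[4], pars[5]};
  vec3 M[2]; int nfib = Mfib.n_rows > 2 ? 2 : (int)Mfib.n_rows;
  for (int f = 0; f < nfib; ++f) M[f] = Mfib.row(f).t();
  mat33 Fm = F;
  PointState ps;
  if (!point_eval(Fm, mp, M, nfib, d, tension_only, resid, degrade_vol, ps))
    Rcpp::stop("invalid deformation state (det F <= 0 or overflow)");
  return Rcpp::List::create(Rcpp::Named("tau") = arma::mat(ps.tau),
                            Rcpp::Named("psi_iso") = ps.psi_iso,
                            Rcpp::Named("psi_ani") = ps.psi_ani,
                            Rcpp::Named("J") = ps.J);
}

// ---------------------------------------------------------------------------
// Mechanics residual + consistent tangent.
//
// nodes: N x dim reference coordinates; elems: E x nen 0-based connectivity;
// u: N x dim displacements; d_nodal: N phase-field values (frozen);
// mat_id: E 0-based rows into mats (mu,k1,k2,kappa,a_iso,a_ani);
// fibM/fibMp: E x 3 unit fibre vectors (all-zero row = family absent);
// etype: 0 = quad4 plane strain, 1 = tet4.
//
// Returns internal force R (N*dim), tangent triplets (Ki,Kj 1-based, Kx),
// effective energies per quadrature point, and per-element mean Cauchy stress
// (xx,yy,zz,xy,yz,xz).
// [[Rcpp::export(name = ".cpp_assemble_mechanics")]]
Rcpp::List cpp_assemble_mechanics(const arma::mat& nodes, const arma::imat& elems,
                                  const arma::mat& u, const arma::vec& d_nodal,
                                  const arma::ivec& mat_id, const arma::mat& mats,
                                  const arma::mat& fibM, const arma::mat& fibMp,
                                  bool tension_only, double resid,
                                  bool degrade_vol, int etype) {
  const int dim = nodes.n_cols;
  const int E = elems.n_rows;
  const int nen = elems.n_cols;
  const int N = nodes.n_rows;
  const int nqp = (etype == 0) ? 4 : 1;
  const int ndof = nen * dim;

  vec R(N * dim, fill::zeros);
  uvec Ki(E * (size_t)ndof * ndof), Kj(E * (size_t)ndof * ndof);
  vec Kx(E * (size_t)ndof * ndof, fill::zeros);
  vec psi_iso(E * (size_t)nqp, fill::zeros), psi_ani(E * (size_t)nqp, fill::zeros);
  mat cauchy(E, 6, fill::zeros);

  // quad gauss points
  double gp[4][2] = {{-GP,-GP},{GP,-GP},{GP,GP},{-GP,GP}};

  int bad_elem = -1;
  vec Nq; mat dNq;

  for (int e = 0; e < E; ++e) {
    MatPoint mp{mats(mat_id[e],0), mats(mat_id[e],1), mats(mat_id[e],2),
                mats(mat_id[e],3), mats(mat_id[e],4), mats(mat_id[e],5)};
    vec3 M[2]; int nfib = 0;
    if (norm(fibM.row(e)) > 0.0)  { M[nfib] = fibM.row(e).t();  ++nfib; }
    if (norm(fibMp.row(e)) > 0.0) { M[nfib] = fibMp.row(e).t(); ++nfib; }

    mat xe(nen, dim), ue(nen, dim);
    vec de(nen);
    for (int a = 0; a < nen; ++a) {
      int n = elems(e, a);
      xe.row(a) = nodes.row(n);
      ue.row(a) = u.row(n);
      de[a] = d_nodal[n];
    }

    mat Ke(ndof, ndof, fill::zeros);
    vec Re(ndof, fill::zeros);
    double vol = 0.0;
    rowvec sig(6, fill::zeros);

    for (int q = 0; q < nqp; ++q) {
      double w, dqp;
      mat gX;  // nen x dim reference gradients
      if (etype == 0) {
        quad4_shape(gp[q][0], gp[q][1], Nq, dNq);
        mat Jm = xe.t() * dNq;           // dim x dim
        double detJ = det(Jm);
        if (detJ <= 0.0) { bad_elem = e; break; }
        gX = dNq * inv(Jm);
        w = detJ;                         // gauss weight 1
        dqp = dot(Nq, de);
      } else {
        // tet4: constant gradients, one point
        mat33 Jm;
        for (int k = 0; k < 3; ++k)
          Jm.col(k) = (xe.row(k + 1) - xe.row(0)).t();
        double detJ = det(Jm);
        if (detJ <= 0.0) { bad_elem = e; break; }
        mat33 Jinv = inv(Jm);
        gX.set_size(4, 3);
        gX.row(1) = Jinv.row(0); gX.row(2) = Jinv.row(1); gX.row(3) = Jinv.row(2);
        gX.row(0) = -(gX.row(1) + gX.row(2) + gX.row(3));
        w = detJ / 6.0;
        dqp = 0.25 * accu(de);
      }

      // deformation gradient (embed in 3x3; plane strain F33 = 1)
      mat Fd = eye(dim, dim) + ue.t() * gX;
      mat33 F = eye(3, 3);
      F.submat(0, 0, dim - 1, dim - 1) = Fd;

      PointState ps;
      if (!point_eval(F, mp, M, nfib, dqp, tension_only, resid, degrade_vol, ps)) {
        bad_elem = e; break;
      }
      size_t qg = (size_t)e * nqp + q;
      psi_iso[qg] = ps.psi_iso;
      psi_ani[qg] = ps.psi_ani;

      // spatial gradients, embedded in 3 components
      mat gx = gX * inv(Fd);              // nen x dim
      mat g3(nen, 3, fill::zeros);
      g3.cols(0, dim - 1) = gx;

      // residual and tangent
      for (int a = 0; a < nen; ++a) {
        vec3 ga = g3.row(a).t();
        vec3 ta = ps.tau * ga;
        for (int i = 0; i < dim; ++i)
          Re[a * dim + i] += w * ta[i];
        for (int b = 0; b < nen; ++b) {
          vec3 gb = g3.row(b).t();
          double gagb = dot(ga, gb);
          double geo = dot(ga, ps.tau * gb);
          for (int i = 0; i < dim; ++i) {
            for (int k = 0; k < dim; ++k) {
              double v = ps.A * ga[i] * gb[k]
                       + 0.5 * ps.B * ((i == k ? gagb : 0.0) + gb[i] * ga[k])
                       + (i == k ? geo : 0.0);
              for (int f = 0; f < ps.nfib; ++f)
                v += ps.Cf[f] * dot(ps.m[f], ga) * dot(ps.m[f], gb)
                   * ps.m[f][i] * ps.m[f][k];
              Ke(a * dim + i, b * dim + k) += w * v;
            }
          }
        }
      }
      vol += w;
      mat33 sg = ps.tau / ps.J;
      sig += w * rowvec{sg(0,0), sg(1,1), sg(2,2), sg(0,1), sg(1,2), sg(0,2)};
    }
    if (bad_elem >= 0) break;

    cauchy.row(e) = sig / vol;

    // scatter
    size_t base = (size_t)e * ndof * ndof;
    for (int a = 0; a < nen; ++a)
      for (int i = 0; i < dim; ++i) {
        int ga_ = elems(e, a) * dim + i;
        R[ga_] += Re[a * dim + i];
        for (int b = 0; b < nen; ++b)
          for (int k = 0; k < dim; ++k) {
            size_t idx = base + (size_t)(a * dim + i) * ndof + (b * dim + k);
            Ki[idx] = ga_ + 1;
            Kj[idx] = elems(e, b) * dim + k + 1;
            Kx[idx] = Ke(a * dim + i, b * dim + k);
          }
      }
  }

  return Rcpp::List::create(
      Rcpp::Named("ok") = (bad_elem < 0),
      Rcpp::Named("bad_elem") = bad_elem + 1,
      Rcpp::Named("R") = R,
      Rcpp::Named("Ki") = Rcpp::IntegerVector(Ki.begin(), Ki.end()),
      Rcpp::Named("Kj") = Rcpp::IntegerVector(Kj.begin(), Kj.end()),
      Rcpp::Named("Kx") = Kx,
      Rcpp::Named("psi_iso") = psi_iso,
      Rcpp::Named("psi_ani") = psi_ani,
      Rcpp::Named("cauchy") = cauchy);
}

// ---------------------------------------------------------------------------
// Phase-field linear system.
//
// Backward-Euler weak form of  eta*(d - d_n)/dt = (1-d) H - d + gf*Div(L grad d):
//   [ (eta/dt + 1 + H) M + gf K_L ] d = (eta/dt) M d_n + m_H
// gf = 1/2 for the evolution equation (superposed iso/ani criteria); gf = 1
// recovers the geometric Euler-Lagrange crack equation when H = 0.
// pf_mats rows: l, omega_M, omega_Mp.
// [[Rcpp::export(name = ".cpp_assemble_phasefield")]]
Rcpp::List cpp_assemble_phasefield(const arma::mat& nodes, const arma::imat& elems,
                                   const arma::vec& H_qp, const arma::vec& d_n,
                                   const arma::ivec& mat_id, const arma::mat& pf_mats,
                                   const arma::mat& fibM, const arma::mat& fibMp,
                                   double eta_over_dt, double grad_factor, int etype) {
  const int dim = nodes.n_cols;
  const int E = elems.n_rows;
  const int nen = elems.n_cols;
  const int N = nodes.n_rows;
  const int nqp = (etype == 0) ? 4 : 1;

  vec bvec(N, fill::zeros);
  uvec Ai(E * (size_t)nen * nen), Aj(E * (size_t)nen * nen);
  vec Ax(E * (size_t)nen * nen, fill::zeros);

  double gp[4][2] = {{-GP,-GP},{GP,-GP},{GP,GP},{-GP,GP}};
  vec Nq; mat dNq;

  for (int e = 0; e < E; ++e) {
    double l = pf_mats(mat_id[e], 0);
    double wM = pf_mats(mat_id[e], 1), wMp = pf_mats(mat_id[e], 2);
    mat33 L = l * l * eye(3, 3);
    if (norm(fibM.row(e)) > 0.0) {
      vec3 M = fibM.row(e).t();
      L += l * l * wM * (M * M.t());
    }
    if (norm(fibMp.row(e)) > 0.0) {
      vec3 Mp = fibMp.row(e).t();
      L += l * l * wMp * (Mp * Mp.t());
    }

    mat xe(nen, dim);
    vec dne(nen);
    for (int a = 0; a < nen; ++a) {
      xe.row(a) = nodes.row(elems(e, a));
      dne[a] = d_n[elems(e, a)];
    }

    mat Ae(nen, nen, fill::zeros);
    vec be(nen, fill::zeros);

    for (int q = 0; q < nqp; ++q) {
      double w, Hq = H_qp[(size_t)e * nqp + q];
      mat gX;
      vec Nv;
      if (etype == 0) {
        quad4_shape(gp[q][0], gp[q][1], Nq, dNq);
        mat Jm = xe.t() * dNq;
        double detJ = det(Jm);
        gX = dNq * inv(Jm);
        w = detJ;
        Nv = Nq;
      } else {
        mat33 Jm;
        for (int k = 0; k < 3; ++k)
          Jm.col(k) = (xe.row(k + 1) - xe.row(0)).t();
        double detJ = det(Jm);
        mat33 Jinv = inv(Jm);
        gX.set_size(4, 3);
        gX.row(1) = Jinv.row(0); gX.row(2) = Jinv.row(1); gX.row(3) = Jinv.row(2);
        gX.row(0) = -(gX.row(1) + gX.row(2) + gX.row(3));
        w = detJ / 6.0;
        Nv = vec(4, fill::value(0.25));
      }
      mat g3(nen, 3, fill::zeros);
      g3.cols(0, dim - 1) = gX.cols(0, dim - 1);

      double coef = eta_over_dt + 1.0 + Hq;
      double dnq = dot(Nv, dne);
      for (int a = 0; a < nen; ++a) {
        be[a] += w * Nv[a] * (eta_over_dt * dnq + Hq);
        vec3 ga = g3.row(a).t();
        vec3 Lga = L * ga;
        for (int b = 0; b < nen; ++b) {
          vec3 gb = g3.row(b).t();
          Ae(a, b) += w * (coef * Nv[a] * Nv[b] + grad_factor * dot(Lga, gb));
        }
      }
    }

    size_t base = (size_t)e * nen * nen;
    for (int a = 0; a < nen; ++a) {
      bvec[elems(e, a)] += be[a];
      for (int b = 0; b < nen; ++b) {
        Ai[base + a * nen + b] = elems(e, a) + 1;
        Aj[base + a * nen + b] = elems(e, b) + 1;
        Ax[base + a * nen + b] = Ae(a, b);
      }
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("Ai") = Rcpp::IntegerVector(Ai.begin(), Ai.end()),
      Rcpp::Named("Aj") = Rcpp::IntegerVector(Aj.begin(), Aj.end()),
      Rcpp::Named("Ax") = Ax,
      Rcpp::Named("b") = bvec);
}

// ---------------------------------------------------------------------------
// Follower pressure load on triangular facets of the current surface.
// Nodal force f_a = (p/6) (x2-x1) x (x3-x1) for each facet node; the facet
// orientation (node order) must point along the load direction.  Also returns
// the load-stiffness triplets dF/dx so the Newton tangent is consistent.
// [[Rcpp::export(name = ".cpp_pressure_load")]]
Rcpp::List cpp_pressure_load(const arma::mat& xcur, const arma::imat& tris, double p) {
  const int Fn = tris.n_rows;
  const int N = xcur.n_rows;
  vec f(N * 3, fill::zeros);
  uvec Ki(Fn * 81), Kj(Fn * 81);
  vec Kx(Fn * 81, fill::zeros);

  for (int t = 0; t < Fn; ++t) {
    int n1 = tris(t, 0), n2 = tris(t, 1), n3 = tris(t, 2);
    vec3 x1 = xcur.row(n1).t(), x2 = xcur.row(n2).t(), x3 = xcur.row(n3).t();
    vec3 e21 = x2 - x1, e31 = x3 - x1;
    vec3 fa = (p / 6.0) * cross(e21, e31);
    int nd[3] = {n1, n2, n3};
    for (int a = 0; a < 3; ++a)
      for (int i = 0; i < 3; ++i)
        f[nd[a] * 3 + i] += fa[i];

    auto skew = [](const vec3& v) {
      mat33 s = {{0, -v[2], v[1]}, {v[2], 0, -v[0]}, {-v[1], v[0], 0}};
      return s;
    };
    mat33 D[3];
    D[0] = (p / 6.0) * (skew(e31) - skew(e21));
    D[1] = (-p / 6.0) * skew(e31);
    D[2] = (p / 6.0) * skew(e21);

    size_t base = (size_t)t * 81;
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b)
        for (int i = 0; i < 3; ++i)
          for (int k = 0; k < 3; ++k) {
            size_t idx = base + ((size_t)(a * 3 + i)) * 9 + (b * 3 + k);
            Ki[idx] = nd[a] * 3 + i + 1;
            Kj[idx] = nd[b] * 3 + k + 1;
            Kx[idx] = D[b](i, k);
          }
  }
  return Rcpp::List::create(
      Rcpp::Named("f") = f,
      Rcpp::Named("Ki") = Rcpp::IntegerVector(Ki.begin(), Ki.end()),
      Rcpp::Named("Kj") = Rcpp::IntegerVector(Kj.begin(), Kj.end()),
      Rcpp::Named("Kx") = Kx);
}
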