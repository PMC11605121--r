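// Planar constrained rigid-body engine for the eight-segment walker, the
// spring-damper ground contact with Coulomb friction cap, and the 14-neuron
// oscillator network.  Coordinates are redundant: each segment carries
// (x, y, theta) and pin joints are enforced as algebraic constraints solved
// together with the accelerations (KKT system, Schur complement on the
// diagonal mass matrix), with Baumgarte stabilization plus a post-step
// position/velocity projection that keeps joint residuals at solver accuracy.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;
using Rcpp::stop;

static inline double relu(double x) { return x > 0.0 ? x : 0.0; }

// smooth contact indicator: 0 below zero, linear ramp over 1 cm, 1 beyond
static inline double indic(double x) {
  if (x < 0.0) return 0.0;
  if (x <= 0.01) return 100.0 * x;
  return 1.0;
}

static inline vec2 rotc(double th, double c1, double c2) {
  return vec2{c1 * std::cos(th) - c2 * std::sin(th),
              c1 * std::sin(th) + c2 * std::cos(th)};
}
// d/dtheta of rotc
static inline vec2 drotc(double th, double c1, double c2) {
  return vec2{-c1 * std::sin(th) - c2 * std::cos(th),
              c1 * std::cos(th) - c2 * std::sin(th)};
}

// ---------------------------------------------------------------------------
// mechanism description (generic planar linkage tree)
struct Mech {
  vec mass, inertia;        // length n
  ivec jsegA, jsegB;        // length m; A may be -1 (world pin, cA = world point)
  mat jcA, jcB;             // m x 2 local attachment offsets (segment frame)
  int n, m;
};

static Mech parse_mech(const List& mech) {
  Mech M;
  M.mass = Rcpp::as<vec>(mech["mass"]);
  M.inertia = Rcpp::as<vec>(mech["inertia"]);
  mat joints = Rcpp::as<mat>(mech["joints"]); // cols: segA segB cAx cAy cBx cBy
  M.n = (int)M.mass.n_elem;
  M.m = (int)joints.n_rows;
  M.jsegA = conv_to<ivec>::from(joints.col(0));
  M.jsegB = conv_to<ivec>::from(joints.col(1));
  M.jcA = joints.cols(2, 3);
  M.jcB = joints.cols(4, 5);
  return M;
}

// constraint residual C(q) (2m), world-point differences at each joint
static vec constraint_residual(const Mech& M, const vec& q) {
  int n = M.n;
  vec C(2 * M.m);
  for (int j = 0; j < M.m; ++j) {
    int a = M.jsegA(j), b = M.jsegB(j);
    vec2 pB = vec2{q(b), q(n + b)} + rotc(q(2 * n + b), M.jcB(j, 0), M.jcB(j, 1));
    vec2 pA;
    if (a < 0) pA = vec2{M.jcA(j, 0), M.jcA(j, 1)};
    else pA = vec2{q(a), q(n + a)} + rotc(q(2 * n + a), M.jcA(j, 0), M.jcA(j, 1));
    C(2 * j) = pA(0) - pB(0);
    C(2 * j + 1) = pA(1) - pB(1);
  }
  return C;
}

// constraint Jacobian J (2m x 3n) and centripetal term c2 with
// J qdd = c2 (+ stabilization) at the acceleration level
static void constraint_jacobian(const Mech& M, const vec& q, const vec& v,
                                sp_mat* unused, mat& J, vec& c2) {
  int n = M.n;
  J.zeros(2 * M.m, 3 * n);
  c2.zeros(2 * M.m);
  for (int j = 0; j < M.m; ++j) {
    int a = M.jsegA(j), b = M.jsegB(j);
    if (a >= 0) {
      double th = q(2 * n + a), om = v(2 * n + a);
      vec2 d = drotc(th, M.jcA(j, 0), M.jcA(j, 1));
      vec2 r = rotc(th, M.jcA(j, 0), M.jcA(j, 1));
      J(2 * j, a) = 1.0;        J(2 * j, 2 * n + a) = d(0);
      J(2 * j + 1, n + a) = 1.0; J(2 * j + 1, 2 * n + a) = d(1);
      c2(2 * j) += om * om * r(0);
      c2(2 * j + 1) += om * om * r(1);
    }
    double th = q(2 * n + b), om = v(2 * n + b);
    vec2 d = drotc(th, M.jcB(j, 0), M.jcB(j, 1));
    vec2 r = rotc(th, M.jcB(j, 0), M.jcB(j, 1));
    J(2 * j, b) = -1.0;         J(2 * j, 2 * n + b) = -d(0);
    J(2 * j + 1, n + b) = -1.0; J(2 * j + 1, 2 * n + b) = -d(1);
    c2(2 * j) -= om * om * r(0);
    c2(2 * j + 1) -= om * om * r(1);
  }
}

// Solve [M -J^t; J 0] [qdd; -lambda] = [f; gamma] via Schur complement.
// lambda(2j:2j+1) is the constraint force applied to segment A (world side for
// pins); the opposite force acts on B, so action equals reaction by
// construction.
static bool solve_constrained(const Mech& M, const vec& q, const vec& v,
                              const vec& f, double alpha, double beta2,
                              vec& qdd, vec& lambda, double* rcond_out) {
  int n = M.n;
  vec minv(3 * n);
  for (int i = 0; i < n; ++i) {
    minv(i) = 1.0 / M.mass(i);
    minv(n + i) = 1.0 / M.mass(i);
    minv(2 * n + i) = 1.0 / M.inertia(i);
  }
  if (M.m == 0) { qdd = minv % f; lambda.reset(); if (rcond_out) *rcond_out = 1.0; return true; }
  mat J; vec c2;
  constraint_jacobian(M, q, v, nullptr, J, c2);
  vec C = constraint_residual(M, q);
  vec Cdot = J * v;
  vec gamma = c2 - alpha * Cdot - beta2 * C;
  mat Jm = J.each_row() % minv.t();
  mat S = J * Jm.t(); // J Minv J^t
  if (rcond_out) *rcond_out = rcond(S);
  vec rhs = gamma - J * (minv % f);
  vec lam;
  bool ok = solve(lam, S, rhs, solve_opts::likely_sympd + solve_opts::no_approx);
  if (!ok) return false;
  // qdd = Minv (f + J^t lam)
  qdd = minv % (f + J.t() * lam);
  lambda = lam;
  return true;
}

// Newton projection of q onto the constraint manifold, plus velocity
// projection onto its tangent.  Displacements are taken along Minv J^t so
// heavy segments move less (standard mass-weighted least squares).
static void project_constraints(const Mech& M, vec& q, vec& v,
                                double tol, int maxit) {
  if (M.m == 0) return;
  int n = M.n;
  vec minv(3 * n);
  for (int i = 0; i < n; ++i) {
    minv(i) = 1.0 / M.mass(i);
    minv(n + i) = 1.0 / M.mass(i);
    minv(2 * n + i) = 1.0 / M.inertia(i);
  }
  mat J; vec c2;
  for (int it = 0; it < maxit; ++it) {
    vec C = constraint_residual(M, q);
    if (norm(C, "inf") < tol && it > 0) break;
    constraint_jacobian(M, q, v, nullptr, J, c2);
    mat Jm = J.each_row() % minv.t();
    mat S = J * Jm.t();
    vec dl;
    if (!solve(dl, S, -C, solve_opts::likely_sympd + solve_opts::no_approx)) return;
    q += minv % (J.t() * dl);
    if (norm(C, "inf") < tol) break;
  }
  constraint_jacobian(M, q, v, nullptr, J, c2);
  mat Jm2 = J.each_row() % minv.t();
  mat S = J * Jm2.t();
  vec dv;
  if (solve(dv, S, -(J * v), solve_opts::likely_sympd + solve_opts::no_approx))
    v += minv % (J.t() * dv);
}

// ---------------------------------------------------------------------------
// ground contact
struct Ground {
  double kgx, kgy, bgx, bgy;
  vec mu_x;   // segment start positions of the friction schedule
  vec mu_val; // NA = unset (no cap)
};

static Ground parse_ground(const List& g) {
  Ground G;
  G.kgx = Rcpp::as<double>(g["k_gx"]);
  G.kgy = Rcpp::as<double>(g["k_gy"]);
  G.bgx = Rcpp::as<double>(g["b_gx"]);
  G.bgy = Rcpp::as<double>(g["b_gy"]);
  G.mu_x = Rcpp::as<vec>(g["mu_x"]);
  G.mu_val = Rcpp::as<vec>(g["mu_val"]);
  return G;
}

static double mu_at(const Ground& G, double x) {
  double val = datum::nan; // unset
  for (uword i = 0; i < G.mu_x.n_elem; ++i)
    if (x >= G.mu_x(i)) val = G.mu_val(i);
  return val; // may be NaN (unset)
}

static inline double cap_shear(double fgx, double fgy, double mu) {
  if (std::isnan(mu)) return fgx;
  double lim = mu * fgy;
  if (std::fabs(fgx) > lim) return (fgx > 0 ? lim : -lim);
  return fgx;
}

struct ContactPts {
  ivec seg;  // np
  mat c;     // np x 2 local offsets
  int np;
};

static ContactPts parse_pts(const List& p) {
  ContactPts P;
  mat tab = Rcpp::as<mat>(p["points"]); // cols: seg cx cy
  P.np = (int)tab.n_rows;
  P.seg = conv_to<ivec>::from(tab.col(0));
  P.c = tab.cols(1, 2);
  return P;
}

// forces (np x 2), given anchors and contact flags; flat ground y = 0
static mat contact_forces(const ContactPts& P, const Ground& G, int n,
                          const vec& q, const vec& v,
                          const vec& anchor_x, const ivec& flag) {
  mat F(P.np, 2, fill::zeros);
  for (int k = 0; k < P.np; ++k) {
    if (!flag(k)) continue;
    int s = P.seg(k);
    double th = q(2 * n + s), om = v(2 * n + s);
    vec2 r = rotc(th, P.c(k, 0), P.c(k, 1));
    vec2 dr = drotc(th, P.c(k, 0), P.c(k, 1));
    double py = q(n + s) + r(1);
    double px = q(s) + r(0);
    double vx = v(s) + om * dr(0);
    double vy = v(n + s) + om * dr(1);
    double ind = indic(0.0 - py); // flat ground
    if (ind <= 0.0) continue;
    double fgy = (-G.kgy * (py - 0.0) + G.bgy * relu(-vy)) * ind;
    if (fgy < 0.0) fgy = 0.0;
    double fgx = (-G.kgx * (px - anchor_x(k)) - G.bgx * vx) * ind;
    fgx = cap_shear(fgx, fgy, mu_at(G, anchor_x(k)));
    F(k, 0) = fgx;
    F(k, 1) = fgy;
  }
  return F;
}

// ---------------------------------------------------------------------------
// neural network (14 Matsuoka-type neurons, 7 flexor/extensor pairs)
struct Cpg {
  vec tau, taup;   // 14
  double beta;
  mat W;           // 14 x 14
  bool literal;    // literal printed self-indexed coupling (comparison switch)
  vec p;           // 18 transfer coefficients
  vec kT;          // torque unit constants per joint, N m per (p * output)
  vec fbg;         // feedback gains
  double fb_scale; // feedback scaled with the tonic drive (u0 / u0_young)
  double Fref;     // load normalisation for contact indicators, N
};

static Cpg parse_cpg(const List& cp) {
  Cpg C;
  C.tau = Rcpp::as<vec>(cp["tau"]);
  C.taup = Rcpp::as<vec>(cp["tau_prime"]);
  C.beta = Rcpp::as<double>(cp["beta"]);
  C.W = Rcpp::as<mat>(cp["W"]);
  C.literal = Rcpp::as<bool>(cp["literal_coupling"]);
  C.p = Rcpp::as<vec>(cp["p"]);
  vec kt = Rcpp::as<vec>(cp["torque_gain"]);
  C.kT = (kt.n_elem == 1) ? vec(7, fill::value(kt(0))) : kt;
  C.fbg = Rcpp::as<vec>(cp["fb_gains"]);
  C.fb_scale = cp.containsElementNamed("fb_scale") ?
      Rcpp::as<double>(cp["fb_scale"]) : 1.0;
  C.Fref = Rcpp::as<double>(cp["load_ref"]);
  return C;
}

// neuron order: 1 hipF_R, 2 hipE_R, 3 hipF_L, 4 hipE_L, 5 kneeF_R, 6 kneeE_R,
// 7 kneeF_L, 8 kneeE_L, 9 ankF_R, 10 ankE_R, 11 ankF_L, 12 ankE_L,
// 13 trunkF, 14 trunkE (0-based in code)
static vec cpg_feedback(const Cpg& C, int n, const vec& q, const vec& v,
                        double hR, double hL, double vxcom) {
  // segment angles: 0 HAT, 1 pelvis, 2 thighR, 3 thighL, 4 shankR, 5 shankL
  double thH = q(2 * n + 0), omH = v(2 * n + 0);
  double thP = q(2 * n + 1), omP = v(2 * n + 1);
  double thTR = q(2 * n + 2), thTL = q(2 * n + 3);
  double omTR = v(2 * n + 2), omTL = v(2 * n + 3);
  double thSR = q(2 * n + 4), thSL = q(2 * n + 5);
  const vec& a = C.fbg;
  vec S(14, fill::zeros);
  // hips: signed thigh-angle stretch reflex (push-pull, so the antagonist
  // terminates an overlong swing burst), contact gating, pelvis posture
  // posture references: drive the pelvis/trunk toward a slight forward lean
  double upright = a(3) * (thP + a(13)) + a(12) * omP; // + = backward lean
  // the extensor stretch response acts mainly in stance, so the swing leg is
  // not retracted past its landing position once the flexor burst ends;
  // the velocity lead term damps the swing so the thigh settles instead of
  // overshooting
  double gR = 0.15 + 0.85 * hR, gL = 0.15 + 0.85 * hL;
  // speed-dependent swing target (capture-point foot placement): the thigh
  // stretch reflex drives the swing leg toward an angle that grows with the
  // forward CoM velocity, so faster gait lands the foot farther ahead
  double eTR = thTR + a(16) * omTR - a(17) * vxcom * (1.0 - hR);
  double eTL = thTL + a(16) * omTL - a(17) * vxcom * (1.0 - hL);
  S(0) = -a(0) * eTR + a(1) * hL - a(2) * hR + upright * hR;
  S(1) = a(0) * eTR * gR + a(2) * hR - a(1) * hL - upright * hR;
  S(2) = -a(0) * eTL + a(1) * hR - a(2) * hL + upright * hL;
  S(3) = a(0) * eTL * gL + a(2) * hL - a(1) * hR - upright * hL;
  // knees: swing flexion follows thigh swing, pre-swing flexion unloads the
  // trailing leg, the knee extends through late swing for foot placement,
  // and in stance the extensor is an angle servo that resists knee yield
  // under load (low duty, so it does not accrue adaptation tonically)
  double kneeR = thSR - thTR, kneeL = thSL - thTL; // relative knee angle
  S(4) = a(4) * (1.0 - hR) * relu(omTR) + a(15) * hL * relu(-thTR);
  S(5) = a(5) * hR * relu(-kneeR) + a(6) * (1.0 - hR) * relu(thTR);
  S(6) = a(4) * (1.0 - hL) * relu(omTL) + a(15) * hR * relu(-thTL);
  S(7) = a(5) * hL * relu(-kneeL) + a(6) * (1.0 - hL) * relu(thTL);
  // ankles: swing dorsiflexion; stance push-off once the shank has passed
  // forward over the ankle (knee ahead of ankle means negative shank angle);
  // and an ankle postural strategy: forward body pitch recruits the stance
  // plantarflexors (moving the centre of pressure toward the toes), backward
  // pitch recruits the dorsiflexors
  double pitch = thP + a(13) + 0.25 * omP; // + = backward of the target lean
  S(8) = a(7) * (1.0 - hR) + a(18) * hR * relu(pitch);
  S(9) = a(8) * hR * relu(-thSR) + a(9) * hR + a(18) * hR * relu(-pitch);
  S(10) = a(7) * (1.0 - hL) + a(18) * hL * relu(pitch);
  S(11) = a(8) * hL * relu(-thSL) + a(9) * hL + a(18) * hL * relu(-pitch);
  // trunk: keep HAT upright (forward lean is negative theta); signed
  double lean = a(10) * (thH + a(14)) + a(11) * omH;
  S(12) = lean;
  S(13) = -lean;
  return C.fb_scale * S;
}

// joint torques from rectified outputs through the 18 transfer channels;
// joints: 0 trunk, 1 hipR, 2 hipL, 3 kneeR, 4 kneeL, 5 ankR, 6 ankL
static inline double fwd_gate(double th) {
  double g = th / 0.3;
  if (g < 0.0) return 0.0;
  if (g > 1.0) return 1.0;
  return g;
}

// Channel map of the 18 torque transfer coefficients (mirrored left/right,
// several gated by the stance/swing state):
//   hip:   flexor p1 (+ p14 in swing); extensor p2 (stance-weighted),
//          p8 early-stance boost (thigh forward), p17 swing retraction
//   knee:  flexor p3 (+ p4 in swing); extensor p9 in stance,
//          p11 + p18 terminal-swing extension
//   ankle: dorsiflexor p6 (+ p15 in swing, + p12 in stance);
//          plantarflexor p7 (+ p13 in swing), p5 stance push-off gated by
//          the shank passing forward over the ankle
//   trunk: extensor p16, flexor p10
static vec active_torques_cpp(const Cpg& C, const vec& y, double hR, double hL,
                              const vec& th) {
  const vec& p = C.p;
  double thTR = th(2), thTL = th(3), thSR = th(4), thSL = th(5);
  vec Ta(7, fill::zeros);
  double swR = 1.0 - hR, swL = 1.0 - hL;
  double eR = 0.45 + 0.55 * hR, eL = 0.45 + 0.55 * hL;
  double poR = 0.3 + 0.7 * fwd_gate(-thSR), poL = 0.3 + 0.7 * fwd_gate(-thSL);
  Ta(0) = p(15) * y(13) - p(9) * y(12);
  Ta(1) = (p(0) + p(13) * swR) * y(0)
          - (p(1) * eR + p(7) * hR * fwd_gate(thTR) + p(16) * swR) * y(1);
  Ta(2) = (p(0) + p(13) * swL) * y(2)
          - (p(1) * eL + p(7) * hL * fwd_gate(thTL) + p(16) * swL) * y(3);
  Ta(3) = -(p(2) + p(3) * swR) * y(4)
          + (p(8) * hR + (p(10) + p(17)) * swR) * y(5);
  Ta(4) = -(p(2) + p(3) * swL) * y(6)
          + (p(8) * hL + (p(10) + p(17)) * swL) * y(7);
  Ta(5) = (p(5) + p(14) * swR + p(11) * hR) * y(8)
          - (p(4) * hR * poR + p(6) + p(12) * swR) * y(9);
  Ta(6) = (p(5) + p(14) * swL + p(11) * hL) * y(10)
          - (p(4) * hL * poL + p(6) + p(12) * swL) * y(11);
  return C.kT % Ta;
}

struct PassiveSpec {
  mat limits;     // 7 x 2 (lo, hi) relative joint angle, rad
  double k_stop, b_stop;
};

static PassiveSpec parse_passive(const List& ps) {
  PassiveSpec P;
  P.limits = Rcpp::as<mat>(ps["limits"]);
  P.k_stop = Rcpp::as<double>(ps["k_stop"]);
  P.b_stop = Rcpp::as<double>(ps["b_stop"]);
  return P;
}

// viscoelastic joint-limit torques; zero inside the neutral range
static vec passive_torques_cpp(const PassiveSpec& P, int n, const vec& q,
                               const vec& v, const imat& jpair) {
  vec Tp(7, fill::zeros);
  for (int j = 0; j < 7; ++j) {
    int a = jpair(j, 0), b = jpair(j, 1);
    double phi = q(2 * n + b) - q(2 * n + a);
    double phid = v(2 * n + b) - v(2 * n + a);
    double lo = P.limits(j, 0), hi = P.limits(j, 1);
    if (phi > hi) Tp(j) = -P.k_stop * (phi - hi) - P.b_stop * phid;
    else if (phi < lo) Tp(j) = -P.k_stop * (phi - lo) - P.b_stop * phid;
  }
  return Tp;
}

// ---------------------------------------------------------------------------
// full model derivative
struct Walker {
  Mech mech;
  ContactPts pts;
  Ground ground;
  Cpg cpg;
  PassiveSpec passive;
  imat jpair;  // 7 x 2 (A,B) segment ids per torque joint
  double g;
  int hip_seg; vec2 hip_local; // pelvis bottom (hip joint centre)
};

static void generalized_forces(const Walker& Wk, const vec& q, const vec& v,
                               const vec& Ta, const vec& Tp, const mat& Fg,
                               vec& f) {
  int n = Wk.mech.n;
  f.zeros(3 * n);
  for (int i = 0; i < n; ++i) f(n + i) = -Wk.mech.mass(i) * Wk.g;
  for (int k = 0; k < Wk.pts.np; ++k) {
    int s = Wk.pts.seg(k);
    vec2 r = rotc(q(2 * n + s), Wk.pts.c(k, 0), Wk.pts.c(k, 1));
    f(s) += Fg(k, 0);
    f(n + s) += Fg(k, 1);
    f(2 * n + s) += r(0) * Fg(k, 1) - r(1) * Fg(k, 0);
  }
  for (int j = 0; j < 7; ++j) {
    double T = Ta(j) + Tp(j);
    f(2 * n + Wk.jpair(j, 0)) -= T;
    f(2 * n + Wk.jpair(j, 1)) += T;
  }
}

struct Deriv {
  vec qdd, du, dv_ad;
  mat Fg;
  double hR, hL;
  bool ok;
};

static Deriv walker_deriv(const Walker& Wk, const vec& q, const vec& v,
                          const vec& u, const vec& vad, double u0,
                          const vec& anchor_x, const ivec& flag,
                          double alpha, double beta2) {
  Deriv D;
  int n = Wk.mech.n;
  D.Fg = contact_forces(Wk.pts, Wk.ground, n, q, v, anchor_x, flag);
  D.hR = std::min(1.0, (D.Fg(0, 1) + D.Fg(1, 1)) / Wk.cpg.Fref);
  D.hL = std::min(1.0, (D.Fg(2, 1) + D.Fg(3, 1)) / Wk.cpg.Fref);
  vec y = u; y.transform([](double x) { return relu(x); });
  double vxcom = dot(Wk.mech.mass, v.subvec(0, n - 1)) / accu(Wk.mech.mass);
  vec S = cpg_feedback(Wk.cpg, n, q, v, D.hR, D.hL, vxcom);
  vec Ta = active_torques_cpp(Wk.cpg, y, D.hR, D.hL,
                              q.subvec(2 * n, 3 * n - 1));
  vec Tp = passive_torques_cpp(Wk.passive, n, q, v, Wk.jpair);
  vec f;
  generalized_forces(Wk, q, v, Ta, Tp, D.Fg, f);
  vec lambda;
  D.ok = solve_constrained(Wk.mech, q, v, f, alpha, beta2, D.qdd, lambda, nullptr);
  if (!D.ok) return D;
  vec coup(14);
  if (Wk.cpg.literal) {
    vec rs = sum(Wk.cpg.W, 1);
    coup = rs % y;
  } else {
    coup = Wk.cpg.W * y;
  }
  vec vady = vad; vady.transform([](double x) { return relu(x); });
  D.du = (-u - Wk.cpg.beta * vady + coup + u0 + S) / Wk.cpg.tau;
  D.dv_ad = (-vad + y) / Wk.cpg.taup;
  return D;
}

static Walker parse_walker(const List& model) {
  Walker Wk;
  Wk.mech = parse_mech(model["mech"]);
  Wk.pts = parse_pts(model["contacts"]);
  Wk.ground = parse_ground(model["ground"]);
  Wk.cpg = parse_cpg(model["cpg"]);
  Wk.passive = parse_passive(model["passive"]);
  Wk.jpair = Rcpp::as<imat>(model["joint_pairs"]);
  Wk.g = Rcpp::as<double>(model["g"]);
  Wk.hip_seg = Rcpp::as<int>(model["hip_seg"]);
  vec hl = Rcpp::as<vec>(model["hip_local"]);
  Wk.hip_local = vec2{hl(0), hl(1)};
  return Wk;
}

// ---------------------------------------------------------------------------
// exported unit-layer functions

// [[Rcpp::export]]
Rcpp::NumericVector sg_indicator(Rcpp::NumericVector x) {
  Rcpp::NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = indic(x[i]);
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericVector sg_rectify(Rcpp::NumericVector x) {
  Rcpp::NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = relu(x[i]);
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericVector sg_friction_cap(Rcpp::NumericVector fgx,
                                    Rcpp::NumericVector fgy,
                                    Rcpp::NumericVector mu) {
  R_xlen_t n = fgx.size();
  Rcpp::NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double m = mu[i % mu.size()];
    out[i] = cap_shear(fgx[i], fgy[i % fgy.size()],
                       Rcpp::NumericVector::is_na(m) ? datum::nan : m);
  }
  return out;
}

// [[Rcpp::export]]
List sg_ground_reaction(double px, double py, double vx, double vy,
                        double anchor_x, List ground, bool in_contact,
                        bool apply_cap) {
  Ground G = parse_ground(ground);
  double fgx = 0.0, fgy = 0.0, ind = 0.0;
  if (in_contact) {
    ind = indic(0.0 - py);
    if (ind > 0.0) {
      fgy = (-G.kgy * py + G.bgy * relu(-vy)) * ind;
      if (fgy < 0.0) fgy = 0.0;
      fgx = (-G.kgx * (px - anchor_x) - G.bgx * vx) * ind;
      if (apply_cap) fgx = cap_shear(fgx, fgy, mu_at(G, anchor_x));
    }
  }
  return List::create(Named("F_gx") = fgx, Named("F_gy") = fgy,
                      Named("indicator") = ind);
}

// [[Rcpp::export]]
List sg_compute_accelerations(List mech, Rcpp::NumericVector q,
                              Rcpp::NumericVector v, Rcpp::NumericVector f,
                              double alpha, double beta2) {
  Mech M = parse_mech(mech);
  vec qv = Rcpp::as<vec>(q), vv = Rcpp::as<vec>(v), fv = Rcpp::as<vec>(f);
  vec qdd, lambda;
  double rc = 0.0;
  bool ok = solve_constrained(M, qv, vv, fv, alpha, beta2, qdd, lambda, &rc);
  if (!ok || rc < 1e-12)
    stop("constraint system is singular or ill-conditioned (rcond = %g)", rc);
  return List::create(Named("qdd") = qdd, Named("lambda") = lambda,
                      Named("rcond") = rc,
                      Named("residual") = constraint_residual(M, qv));
}

// [[Rcpp::export]]
Rcpp::NumericVector sg_constraint_residual(List mech, Rcpp::NumericVector q) {
  Mech M = parse_mech(mech);
  return Rcpp::wrap(constraint_residual(M, Rcpp::as<vec>(q)));
}

// [[Rcpp::export]]
List sg_neuron_derivatives(Rcpp::NumericVector u, Rcpp::NumericVector vad,
                           List cpg, Rcpp::NumericVector feedback,
                           double u0_noisy) {
  Cpg C = parse_cpg(cpg);
  vec uv = Rcpp::as<vec>(u), vv = Rcpp::as<vec>(vad);
  vec S = Rcpp::as<vec>(feedback);
  vec y = uv; y.transform([](double x) { return relu(x); });
  vec coup;
  if (C.literal) coup = sum(C.W, 1) % y; else coup = C.W * y;
  vec vady = vv; vady.transform([](double x) { return relu(x); });
  vec du = (-uv - C.beta * vady + coup + u0_noisy + S) / C.tau;
  vec dv = (-vv + y) / C.taup;
  return List::create(Named("du") = du, Named("dv") = dv);
}

// [[Rcpp::export]]
Rcpp::NumericVector sg_active_torques(Rcpp::NumericVector y, List cpg,
                                      double hR, double hL,
                                      Rcpp::NumericVector theta) {
  Cpg C = parse_cpg(cpg);
  return Rcpp::wrap(active_torques_cpp(C, Rcpp::as<vec>(y), hR, hL,
                                       Rcpp::as<vec>(theta)));
}

// [[Rcpp::export]]
Rcpp::NumericVector sg_passive_torques(Rcpp::NumericVector theta,
                                       Rcpp::NumericVector omega,
                                       List passive,
                                       Rcpp::IntegerMatrix joint_pairs) {
  PassiveSpec P = parse_passive(passive);
  imat jp(joint_pairs.nrow(), joint_pairs.ncol());
  for (int i = 0; i < joint_pairs.nrow(); ++i)
    for (int j = 0; j < joint_pairs.ncol(); ++j) jp(i, j) = joint_pairs(i, j);
  int n = theta.size();
  vec q(3 * n, fill::zeros), v(3 * n, fill::zeros);
  for (int i = 0; i < n; ++i) {
    q(2 * n + i) = theta[i];
    v(2 * n + i) = omega[i];
  }
  return Rcpp::wrap(passive_torques_cpp(P, n, q, v, jp));
}

// [[Rcpp::export]]
Rcpp::NumericVector sg_sensory_feedback(List model, Rcpp::NumericVector q,
                                        Rcpp::NumericVector v,
                                        double hR, double hL) {
  Walker Wk = parse_walker(model);
  vec vv = Rcpp::as<vec>(v);
  int n = Wk.mech.n;
  double vxcom = dot(Wk.mech.mass, vv.subvec(0, n - 1)) / accu(Wk.mech.mass);
  return Rcpp::wrap(cpg_feedback(Wk.cpg, n, Rcpp::as<vec>(q), vv, hR, hL,
                                 vxcom));
}

// [[Rcpp::export]]
Rcpp::NumericMatrix sg_contact_forces(List model, Rcpp::NumericVector q,
                                      Rcpp::NumericVector v,
                                      Rcpp::NumericVector anchor_x,
                                      Rcpp::IntegerVector flag) {
  Walker Wk = parse_walker(model);
  ivec fl = Rcpp::as<ivec>(flag);
  mat F = contact_forces(Wk.pts, Wk.ground, Wk.mech.n, Rcpp::as<vec>(q),
                         Rcpp::as<vec>(v), Rcpp::as<vec>(anchor_x), fl);
  return Rcpp::wrap(F);
}

// ---------------------------------------------------------------------------
// main run loop

// [[Rcpp::export]]
List sg_run_walker(List model, Rcpp::NumericVector q0, Rcpp::NumericVector v0,
                   Rcpp::NumericVector u0state, Rcpp::NumericVector vad0,
                   Rcpp::NumericVector anchor0, Rcpp::IntegerVector flag0,
                   Rcpp::NumericVector u0_per_step, double t0, double dt,
                   int n_steps, int record_every, double x_stop,
                   double hip_stop, double t_max,
                   double baumgarte_alpha, double baumgarte_beta2,
                   double proj_tol) {
  Walker Wk = parse_walker(model);
  int n = Wk.mech.n;
  vec q = Rcpp::as<vec>(q0), v = Rcpp::as<vec>(v0);
  vec u = Rcpp::as<vec>(u0state), vad = Rcpp::as<vec>(vad0);
  vec anchor_x = Rcpp::as<vec>(anchor0);
  ivec flag = Rcpp::as<ivec>(flag0);
  double t = t0;
  double mtot = accu(Wk.mech.mass);

  int ncol = 1 + 3 * n * 2 + Wk.pts.np * 2 + Wk.pts.np * 2 + 14;
  int nrec_max = n_steps / std::max(1, record_every) + 3;
  mat rec(nrec_max, ncol);
  int nrec = 0;
  int status = 2; // t_max reached unless another condition fires
  double com_x = 0.0, hip_y = 0.0;

  auto record_row = [&](void) {
    if (nrec >= nrec_max) return;
    mat Fg = contact_forces(Wk.pts, Wk.ground, n, q, v, anchor_x, flag);
    int c = 0;
    rec(nrec, c++) = t;
    for (int i = 0; i < 3 * n; ++i) rec(nrec, c++) = q(i);
    for (int i = 0; i < 3 * n; ++i) rec(nrec, c++) = v(i);
    for (int k = 0; k < Wk.pts.np; ++k) { rec(nrec, c++) = Fg(k, 0); rec(nrec, c++) = Fg(k, 1); }
    for (int k = 0; k < Wk.pts.np; ++k) { rec(nrec, c++) = (double)flag(k); rec(nrec, c++) = anchor_x(k); }
    for (int i = 0; i < 14; ++i) rec(nrec, c++) = relu(u(i));
    nrec++;
  };

  record_row();
  int step;
  bool recorded_last = true;
  for (step = 0; step < n_steps; ++step) {
    if (t >= t_max) { status = 2; break; }
    double u0n = u0_per_step[step % u0_per_step.size()];

    Deriv k1 = walker_deriv(Wk, q, v, u, vad, u0n, anchor_x, flag, baumgarte_alpha, baumgarte_beta2);
    if (!k1.ok) { status = 3; break; }
    vec q2 = q + 0.5 * dt * v, v2 = v + 0.5 * dt * k1.qdd;
    vec uu2 = u + 0.5 * dt * k1.du, vv2 = vad + 0.5 * dt * k1.dv_ad;
    Deriv k2 = walker_deriv(Wk, q2, v2, uu2, vv2, u0n, anchor_x, flag, baumgarte_alpha, baumgarte_beta2);
    if (!k2.ok) { status = 3; break; }
    vec q3 = q + 0.5 * dt * v2, v3 = v + 0.5 * dt * k2.qdd;
    vec uu3 = u + 0.5 * dt * k2.du, vv3 = vad + 0.5 * dt * k2.dv_ad;
    Deriv k3 = walker_deriv(Wk, q3, v3, uu3, vv3, u0n, anchor_x, flag, baumgarte_alpha, baumgarte_beta2);
    if (!k3.ok) { status = 3; break; }
    vec q4 = q + dt * v3, v4 = v + dt * k3.qdd;
    vec uu4 = u + dt * k3.du, vv4 = vad + dt * k3.dv_ad;
    Deriv k4 = walker_deriv(Wk, q4, v4, uu4, vv4, u0n, anchor_x, flag, baumgarte_alpha, baumgarte_beta2);
    if (!k4.ok) { status = 3; break; }

    q += (dt / 6.0) * (v + 2.0 * v2 + 2.0 * v3 + v4);
    v += (dt / 6.0) * (k1.qdd + 2.0 * k2.qdd + 2.0 * k3.qdd + k4.qdd);
    u += (dt / 6.0) * (k1.du + 2.0 * k2.du + 2.0 * k3.du + k4.du);
    vad += (dt / 6.0) * (k1.dv_ad + 2.0 * k2.dv_ad + 2.0 * k3.dv_ad + k4.dv_ad);
    t = t0 + (step + 1) * dt;

    if (!q.is_finite() || !v.is_finite() || !u.is_finite()) { status = 3; break; }

    project_constraints(Wk.mech, q, v, proj_tol, 3);

    // anchor bookkeeping: touchdown seeds a new rest position, lift-off clears
    for (int k = 0; k < Wk.pts.np; ++k) {
      int s = Wk.pts.seg(k);
      vec2 r = rotc(q(2 * n + s), Wk.pts.c(k, 0), Wk.pts.c(k, 1));
      double py = q(n + s) + r(1), px = q(s) + r(0);
      if (!flag(k) && py < 0.0) { flag(k) = 1; anchor_x(k) = px; }
      else if (flag(k) && py >= 0.0) { flag(k) = 0; }
    }

    recorded_last = false;
    if ((step + 1) % record_every == 0) { record_row(); recorded_last = true; }

    com_x = dot(Wk.mech.mass, q.subvec(0, n - 1)) / mtot;
    vec2 hip = vec2{q(Wk.hip_seg), q(n + Wk.hip_seg)} +
               rotc(q(2 * n + Wk.hip_seg), Wk.hip_local(0), Wk.hip_local(1));
    hip_y = hip(1);
    if (com_x >= x_stop) { status = 0; break; }
    if (hip_y < hip_stop) { status = 1; break; }
    if (std::fabs(q(0)) > 1e3 || std::fabs(q(n)) > 1e3) { status = 3; break; }
  }
  if (step >= n_steps) status = (status == 2 ? 2 : status);
  if (!recorded_last) record_row();

  return List::create(
      Named("trajectory") = rec.rows(0, std::max(0, nrec - 1)),
      Named("status") = status, Named("steps") = std::min(step + 1, n_steps),
      Named("state") = List::create(
          Named("t") = t, Named("q") = q, Named("v") = v, Named("u") = u,
          Named("v_adapt") = vad, Named("anchor_x") = anchor_x,
          Named("in_contact") = flag));
}
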