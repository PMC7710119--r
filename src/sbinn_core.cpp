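// Core numerics: surrogate network forward/backward with a coupled
// time-derivative channel, benchmark model right-hand sides with analytic
// Jacobians, and the composite loss (data + ODE residual + auxiliary) with
// gradients w.r.t. network weights and (transformed) kinetic parameters.
//
// Orientation convention: internally activations are stored as (units x
// batch) matrices; exported functions return (batch x states).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;

static const double S6_CLAMP = 1e-12;
static const double II_CLAMP = 1e-9;

// ---------------------------------------------------------------------------
// activations

static inline double sigmoidd(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// swish(z) = z * sigmoid(z); first and second derivatives
static inline void swish3(double z, double& f, double& d1, double& d2) {
  double s = sigmoidd(z);
  double sp = s * (1.0 - s);
  f  = z * s;
  d1 = s + z * sp;
  d2 = 2.0 * sp + z * sp * (1.0 - 2.0 * s);
}

// ---------------------------------------------------------------------------
// feature layer: codes 0 -> t~, j>0 -> sin(j t~), -1 -> exp(-t~)

// omega rescales the argument of the periodic/decay features (f(omega*t~)),
// so their frequencies can be matched to the period of the observed
// dynamics; the identity feature stays t~.
static void feature_eval(const vec& tt, const IntegerVector& codes,
                         double omega, mat& A, mat& Ad, bool deriv,
                         double Tscale) {
  int L = codes.size(), n = tt.n_elem;
  A.set_size(L, n);
  if (deriv) Ad.set_size(L, n);
  for (int l = 0; l < L; ++l) {
    int c = codes[l];
    for (int i = 0; i < n; ++i) {
      double x = tt(i);
      double f, d;
      if (c == 0)      { f = x;                 d = 1.0; }
      else if (c > 0)  { double w = c * omega;
                         f = std::sin(w * x);   d = w * std::cos(w * x); }
      else             { f = std::exp(-omega * x); d = -omega * f; }
      A(l, i) = f;
      if (deriv) Ad(l, i) = d / Tscale;  // d/dt = d/dt~ * (1/T)
    }
  }
}

// ---------------------------------------------------------------------------
// model right-hand sides and Jacobians (natural parameter scale)
// model_id: 1 glycolysis (S=7,K=14), 2 apoptosis (S=8,K=9),
//           3 ultradian (S=6,K=20, exogenous meal forcing)

static void glyc_f(const double* x, double /*t*/, const double* p, double* f) {
  const double J0=p[0],k1=p[1],k2=p[2],k3=p[3],k4=p[4],k5=p[5],k6=p[6],
               kk=p[7],kap=p[8],q=p[9],K1=p[10],psi=p[11],N=p[12],A=p[13];
  const double S1=x[0],S2=x[1],S3=x[2],S4=x[3],S5=x[4],S6=x[5],S7=x[6];
  double S6c = (S6 > S6_CLAMP) ? S6 : S6_CLAMP;
  double u = std::pow(S6c / K1, q);
  double D = 1.0 + u;
  double v  = k1 * S1 * S6c / D;
  double a2 = k2 * S2 * (N - S5);
  double a3 = k3 * S3 * (A - S6);
  double a4 = k4 * S4 * S5;
  double a6 = k6 * S2 * S5;
  double ac = kap * (S4 - S7);
  f[0] = J0 - v;
  f[1] = 2.0 * v - a2 - a6;
  f[2] = a2 - a3;
  f[3] = a3 - a4 - ac;
  f[4] = a2 - a4 - a6;
  f[5] = -2.0 * v + 2.0 * a3 - k5 * S6;
  f[6] = psi * ac - kk * S7;
}

static void glyc_jac(const double* x, double /*t*/, const double* p,
                     mat& Jx, mat& Jp) {
  const double J0=p[0],k1=p[1],k2=p[2],k3=p[3],k4=p[4],k5=p[5],k6=p[6],
               kk=p[7],kap=p[8],q=p[9],K1=p[10],psi=p[11],N=p[12],A=p[13];
  (void)J0;
  const double S1=x[0],S2=x[1],S3=x[2],S4=x[3],S5=x[4],S6=x[5],S7=x[6];
  double S6c = (S6 > S6_CLAMP) ? S6 : S6_CLAMP;
  bool clamped = (S6 <= S6_CLAMP);
  double u = std::pow(S6c / K1, q);
  double D = 1.0 + u;
  double v = k1 * S1 * S6c / D;
  double dvdS1 = k1 * S6c / D;
  double dvdS6 = clamped ? 0.0 : (k1 * S1 / D) * (1.0 - q * u / D);
  double dvdk1 = S1 * S6c / D;
  double dvdq  = -v * u * std::log(S6c / K1) / D;
  double dvdK1 = v * q * u / (K1 * D);

  Jx.zeros(7, 7); Jp.zeros(7, 14);
  // f1 = J0 - v
  Jx(0,0) = -dvdS1; Jx(0,5) = -dvdS6;
  Jp(0,0) = 1.0; Jp(0,1) = -dvdk1; Jp(0,9) = -dvdq; Jp(0,10) = -dvdK1;
  // f2 = 2v - k2 S2 (N-S5) - k6 S2 S5
  Jx(1,0) = 2.0*dvdS1; Jx(1,1) = -k2*(N-S5) - k6*S5;
  Jx(1,4) = k2*S2 - k6*S2; Jx(1,5) = 2.0*dvdS6;
  Jp(1,1) = 2.0*dvdk1; Jp(1,2) = -S2*(N-S5); Jp(1,6) = -S2*S5;
  Jp(1,9) = 2.0*dvdq; Jp(1,10) = 2.0*dvdK1; Jp(1,12) = -k2*S2;
  // f3 = k2 S2 (N-S5) - k3 S3 (A-S6)
  Jx(2,1) = k2*(N-S5); Jx(2,2) = -k3*(A-S6); Jx(2,4) = -k2*S2; Jx(2,5) = k3*S3;
  Jp(2,2) = S2*(N-S5); Jp(2,3) = -S3*(A-S6); Jp(2,12) = k2*S2; Jp(2,13) = -k3*S3;
  // f4 = k3 S3 (A-S6) - k4 S4 S5 - kap (S4-S7)
  Jx(3,2) = k3*(A-S6); Jx(3,3) = -k4*S5 - kap; Jx(3,4) = -k4*S4;
  Jx(3,5) = -k3*S3; Jx(3,6) = kap;
  Jp(3,3) = S3*(A-S6); Jp(3,4) = -S4*S5; Jp(3,8) = -(S4-S7); Jp(3,13) = k3*S3;
  // f5 = k2 S2 (N-S5) - k4 S4 S5 - k6 S2 S5
  Jx(4,1) = k2*(N-S5) - k6*S5; Jx(4,3) = -k4*S5;
  Jx(4,4) = -k2*S2 - k4*S4 - k6*S2;
  Jp(4,2) = S2*(N-S5); Jp(4,4) = -S4*S5; Jp(4,6) = -S2*S5; Jp(4,12) = k2*S2;
  // f6 = -2v + 2 k3 S3 (A-S6) - k5 S6
  Jx(5,0) = -2.0*dvdS1; Jx(5,2) = 2.0*k3*(A-S6);
  Jx(5,5) = -2.0*dvdS6 - 2.0*k3*S3 - k5;
  Jp(5,1) = -2.0*dvdk1; Jp(5,3) = 2.0*S3*(A-S6); Jp(5,5) = -S6;
  Jp(5,9) = -2.0*dvdq; Jp(5,10) = -2.0*dvdK1; Jp(5,13) = 2.0*k3*S3;
  // f7 = psi kap (S4-S7) - k S7
  Jx(6,3) = psi*kap; Jx(6,6) = -psi*kap - kk;
  Jp(6,7) = -S7; Jp(6,8) = psi*(S4-S7); Jp(6,11) = kap*(S4-S7);
}

// apoptosis: stoichiometry * mass-action fluxes; flux j carries parameter j
// r = (k1 x1 x4, kd1 x5, kd2 x5, k3 x2 x3, kd3 x6, kd4 x6,
//      k5 x4 x7, kd5 x8, kd6 x8)
static const int APO_NR = 9;
static const double APO_ST[8][9] = {
  // r1  r2  r3  r4  r5  r6  r7  r8  r9
  { -1,  1,  0,  0,  0,  0,  0,  0,  0 },  // x1
  {  0,  0,  1, -1,  1,  1,  0,  0,  0 },  // x2
  {  0,  0,  0, -1,  1,  0,  0,  0,  0 },  // x3
  { -1,  1,  1,  0,  0,  1, -1,  1,  0 },  // x4
  {  1, -1, -1,  0,  0,  0,  0,  0,  0 },  // x5
  {  0,  0,  0,  1, -1, -1,  0,  0,  0 },  // x6
  {  0,  0,  0,  0,  0,  0, -1,  1,  1 },  // x7
  {  0,  0,  0,  0,  0,  0,  1, -1, -1 },  // x8
};

static void apo_fluxmono(const double* x, double* m) {
  m[0] = x[0]*x[3]; m[1] = x[4]; m[2] = x[4];
  m[3] = x[1]*x[2]; m[4] = x[5]; m[5] = x[5];
  m[6] = x[3]*x[6]; m[7] = x[7]; m[8] = x[7];
}

// rate constants are quoted per second (bimolecular: per molecule per
// second); the model's native time unit is hours, hence the 3600 factor.
static const double APO_TSCALE = 3600.0;

static void apo_f(const double* x, double /*t*/, const double* p, double* f) {
  double m[APO_NR];
  apo_fluxmono(x, m);
  for (int s = 0; s < 8; ++s) {
    double acc = 0.0;
    for (int j = 0; j < APO_NR; ++j) acc += APO_ST[s][j] * p[j] * m[j];
    f[s] = APO_TSCALE * acc;
  }
}

static void apo_jac(const double* x, double /*t*/, const double* p,
                    mat& Jx, mat& Jp) {
  double m[APO_NR];
  apo_fluxmono(x, m);
  // drdx: 9 x 8 flux derivatives
  mat drdx(APO_NR, 8, arma::fill::zeros);
  drdx(0,0) = p[0]*x[3]; drdx(0,3) = p[0]*x[0];
  drdx(1,4) = p[1];      drdx(2,4) = p[2];
  drdx(3,1) = p[3]*x[2]; drdx(3,2) = p[3]*x[1];
  drdx(4,5) = p[4];      drdx(5,5) = p[5];
  drdx(6,3) = p[6]*x[6]; drdx(6,6) = p[6]*x[3];
  drdx(7,7) = p[7];      drdx(8,7) = p[8];
  Jx.zeros(8, 8); Jp.zeros(8, 9);
  for (int s = 0; s < 8; ++s)
    for (int j = 0; j < APO_NR; ++j) {
      double st = APO_ST[s][j] * APO_TSCALE;
      if (st == 0.0) continue;
      Jp(s, j) += st * m[j];
      for (int i = 0; i < 8; ++i) Jx(s, i) += st * drdx(j, i);
    }
}

// ultradian: parameter order
// 0 Vp, 1 Vi, 2 Vg, 3 E, 4 tp, 5 ti, 6 td, 7 k, 8 Rm, 9 a1, 10 C1, 11 C2,
// 12 C4, 13 C5, 14 Ub, 15 U0/C3, 16 Um/C3, 17 Rg, 18 alpha, 19 beta
// meal masses are stored in grams; the glucose compartment is in mg, hence
// the 1000 mg/g factor in the forcing term.
static const double MG_PER_G = 1000.0;

static double ult_ig(double t, const double* p, const vec& ev_t,
                     const vec& ev_m) {
  double k = p[7], acc = 0.0;
  for (arma::uword j = 0; j < ev_t.n_elem; ++j)
    if (t >= ev_t(j))
      acc += MG_PER_G * ev_m(j) * k * std::exp(k * (ev_t(j) - t));
  return acc;
}

struct UltCommon {
  double e1, f1, g1, e2, f2, kap, z, w, f3, e4, f4, g4, Iic;
  bool ii_clamped;
};

static void ult_common(const double* x, const double* p, UltCommon& c) {
  const double Vp=p[0],Vi=p[1],Vg=p[2],E=p[3],ti=p[5],
               Rm=p[8],a1=p[9],C1=p[10],C2=p[11],C4=p[12],C5=p[13],Ub=p[14],
               u0=p[15],um=p[16],Rg=p[17],al=p[18],be=p[19];
  const double G=x[2], Ii=x[1], h3=x[5];
  c.e1 = std::exp(a1 - G / (Vg * C1));
  c.f1 = Rm / (1.0 + c.e1);
  c.g1 = Rm * c.e1 / ((1.0 + c.e1) * (1.0 + c.e1));
  c.e2 = std::exp(-G / (Vg * C2));
  c.f2 = Ub * (1.0 - c.e2);
  c.kap = (1.0 / Vi + 1.0 / (E * ti)) / C4;
  c.ii_clamped = (Ii <= II_CLAMP);
  c.Iic = c.ii_clamped ? II_CLAMP : Ii;
  c.z = c.kap * c.Iic;
  c.w = 1.0 / (1.0 + std::pow(c.z, -be));
  c.f3 = (u0 + (um - u0) * c.w) / Vg;
  c.e4 = std::exp(al * (h3 / (Vp * C5) - 1.0));
  c.f4 = Rg / (1.0 + c.e4);
  c.g4 = Rg * c.e4 / ((1.0 + c.e4) * (1.0 + c.e4));
}

static void ult_f(const double* x, double t, const double* p,
                  const vec& ev_t, const vec& ev_m, double* f) {
  const double Vp=p[0],Vi=p[1],E=p[3],tp=p[4],ti=p[5],td=p[6];
  const double Ip=x[0],Ii=x[1],G=x[2],h1=x[3],h2=x[4],h3=x[5];
  UltCommon c; ult_common(x, p, c);
  double ex = E * (Ip / Vp - Ii / Vi);
  f[0] = c.f1 - ex - Ip / tp;
  f[1] = ex - Ii / ti;
  f[2] = c.f4 + ult_ig(t, p, ev_t, ev_m) - c.f2 - c.f3 * G;
  f[3] = (Ip - h1) / td;
  f[4] = (h1 - h2) / td;
  f[5] = (h2 - h3) / td;
}

static void ult_jac(const double* x, double t, const double* p,
                    const vec& ev_t, const vec& ev_m,
                    mat& Jx, mat& Jp, mat& Jev) {
  const double Vp=p[0],Vi=p[1],Vg=p[2],E=p[3],tp=p[4],ti=p[5],td=p[6],
               k=p[7],Rm=p[8],C1=p[10],C2=p[11],C4=p[12],C5=p[13],Ub=p[14],
               u0=p[15],um=p[16],Rg=p[17],al=p[18],be=p[19];
  const double Ip=x[0],Ii=x[1],G=x[2],h1=x[3],h2=x[4],h3=x[5];
  UltCommon c; ult_common(x, p, c);

  double df1dG  = c.g1 / (Vg * C1);
  double df1dVg = -c.g1 * G / (Vg * Vg * C1);
  double df1dC1 = -c.g1 * G / (Vg * C1 * C1);
  double df1da1 = -c.g1;
  double df1dRm = c.f1 / Rm;

  double df2dG  = Ub * c.e2 / (Vg * C2);
  double df2dUb = 1.0 - c.e2;
  double df2dVg = -Ub * c.e2 * G / (Vg * Vg * C2);
  double df2dC2 = -Ub * c.e2 * G / (Vg * C2 * C2);

  double dwdz   = be * c.w * (1.0 - c.w) / c.z;
  double df3dIi = c.ii_clamped ? 0.0 : (um - u0) / Vg * dwdz * c.kap;
  double df3dkap = (um - u0) / Vg * dwdz * c.Iic;
  double dkapdVi = -1.0 / (Vi * Vi * C4);
  double dkapdE  = -1.0 / (E * E * ti * C4);
  double dkapdti = -1.0 / (E * ti * ti * C4);
  double dkapdC4 = -c.kap / C4;
  double df3dbe  = (um - u0) / Vg * c.w * (1.0 - c.w) * std::log(c.z);
  double df3du0  = (1.0 - c.w) / Vg;
  double df3dum  = c.w / Vg;
  double df3dVg  = -c.f3 / Vg;

  double df4dh3 = -c.g4 * al / (Vp * C5);
  double df4dRg = c.f4 / Rg;
  double df4dal = -c.g4 * (h3 / (Vp * C5) - 1.0);
  double df4dVp = c.g4 * al * h3 / (Vp * Vp * C5);
  double df4dC5 = c.g4 * al * h3 / (Vp * C5 * C5);

  Jx.zeros(6, 6); Jp.zeros(6, 20); Jev.zeros(6, 2 * ev_t.n_elem);

  // dIp/dt
  Jx(0,0) = -E / Vp - 1.0 / tp;
  Jx(0,1) =  E / Vi;
  Jx(0,2) =  df1dG;
  Jp(0,0) = E * Ip / (Vp * Vp);
  Jp(0,1) = -E * Ii / (Vi * Vi);
  Jp(0,2) = df1dVg;
  Jp(0,3) = -(Ip / Vp - Ii / Vi);
  Jp(0,4) = Ip / (tp * tp);
  Jp(0,8) = df1dRm; Jp(0,9) = df1da1; Jp(0,10) = df1dC1;

  // dIi/dt
  Jx(1,0) =  E / Vp;
  Jx(1,1) = -E / Vi - 1.0 / ti;
  Jp(1,0) = -E * Ip / (Vp * Vp);
  Jp(1,1) =  E * Ii / (Vi * Vi);
  Jp(1,3) =  (Ip / Vp - Ii / Vi);
  Jp(1,5) =  Ii / (ti * ti);

  // dG/dt
  Jx(2,1) = -df3dIi * G;
  Jx(2,2) = -df2dG - c.f3;
  Jx(2,5) =  df4dh3;
  Jp(2,0) = df4dVp;
  Jp(2,1) = -df3dkap * dkapdVi * G;
  Jp(2,2) = -df2dVg - df3dVg * G;
  Jp(2,3) = -df3dkap * dkapdE * G;
  Jp(2,5) = -df3dkap * dkapdti * G;
  Jp(2,11) = -df2dC2;
  Jp(2,12) = -df3dkap * dkapdC4 * G;
  Jp(2,13) = df4dC5;
  Jp(2,14) = -df2dUb;
  Jp(2,15) = -df3du0 * G;
  Jp(2,16) = -df3dum * G;
  Jp(2,17) = df4dRg;
  Jp(2,18) = df4dal;
  Jp(2,19) = -df3dbe * G;
  // forcing derivatives
  double digdk = 0.0;
  for (arma::uword j = 0; j < ev_t.n_elem; ++j) {
    if (t >= ev_t(j)) {
      double dt = ev_t(j) - t;
      double ee = std::exp(k * dt);
      digdk += MG_PER_G * ev_m(j) * ee * (1.0 + k * dt);
      Jev(2, j) = MG_PER_G * k * ee;                       // d/dm_j
      Jev(2, ev_t.n_elem + j) = MG_PER_G * ev_m(j) * k * k * ee;  // d/dt_j
    }
  }
  Jp(2,7) = digdk;

  // filter chain
  Jx(3,0) = 1.0 / td; Jx(3,3) = -1.0 / td;
  Jx(4,3) = 1.0 / td; Jx(4,4) = -1.0 / td;
  Jx(5,4) = 1.0 / td; Jx(5,5) = -1.0 / td;
  Jp(3,6) = -(Ip - h1) / (td * td);
  Jp(4,6) = -(h1 - h2) / (td * td);
  Jp(5,6) = -(h2 - h3) / (td * td);
}

// dispatchers ---------------------------------------------------------------

static int model_dim_S(int id) { return id == 1 ? 7 : (id == 2 ? 8 : 6); }
static int model_dim_K(int id) { return id == 1 ? 14 : (id == 2 ? 9 : 20); }

static void model_f1(int id, const double* x, double t, const double* p,
                     const vec& ev_t, const vec& ev_m, double* f) {
  if (id == 1) glyc_f(x, t, p, f);
  else if (id == 2) apo_f(x, t, p, f);
  else ult_f(x, t, p, ev_t, ev_m, f);
}

static void model_jac1(int id, const double* x, double t, const double* p,
                       const vec& ev_t, const vec& ev_m,
                       mat& Jx, mat& Jp, mat& Jev) {
  if (id == 1) { glyc_jac(x, t, p, Jx, Jp); Jev.zeros(7, 0); }
  else if (id == 2) { apo_jac(x, t, p, Jx, Jp); Jev.zeros(8, 0); }
  else ult_jac(x, t, p, ev_t, ev_m, Jx, Jp, Jev);
}

// [[Rcpp::export]]
arma::mat cpp_model_f(int model_id, const arma::mat& X, const arma::vec& t,
                      const arma::vec& p, const arma::vec& ev_t,
                      const arma::vec& ev_m) {
  int S = model_dim_S(model_id);
  int n = X.n_rows;
  mat F(n, S);
  std::vector<double> fx(S);
  for (int i = 0; i < n; ++i) {
    arma::rowvec xr = X.row(i);
    model_f1(model_id, xr.memptr(), t(i), p.memptr(), ev_t, ev_m, fx.data());
    for (int s = 0; s < S; ++s) F(i, s) = fx[s];
  }
  return F;
}

// [[Rcpp::export]]
Rcpp::List cpp_model_jac(int model_id, const arma::vec& x, double t,
                         const arma::vec& p, const arma::vec& ev_t,
                         const arma::vec& ev_m) {
  mat Jx, Jp, Jev;
  model_jac1(model_id, x.memptr(), t, p.memptr(), ev_t, ev_m, Jx, Jp, Jev);
  return List::create(_["Jx"] = Jx, _["Jp"] = Jp, _["Jev"] = Jev);
}

// ---------------------------------------------------------------------------
// MLP with flattened weights
// dims: (L_in, w1, ..., wD, S); layer i: W_i (dims[i+1] x dims[i]) then b_i

struct MLPViews {
  std::vector<mat> W;
  std::vector<vec> b;
};

static int mlp_nweights(const IntegerVector& dims) {
  int n = 0;
  for (int i = 0; i + 1 < dims.size(); ++i)
    n += dims[i + 1] * dims[i] + dims[i + 1];
  return n;
}

static void mlp_views(const vec& theta, const IntegerVector& dims,
                      MLPViews& v) {
  v.W.clear(); v.b.clear();
  const double* ptr = theta.memptr();
  size_t off = 0;
  for (int i = 0; i + 1 < dims.size(); ++i) {
    int r = dims[i + 1], c = dims[i];
    v.W.emplace_back(const_cast<double*>(ptr + off), r, c, false, true);
    off += (size_t)r * c;
    v.b.emplace_back(const_cast<double*>(ptr + off), r, false, true);
    off += r;
  }
}

struct FwdCache {
  std::vector<mat> A, Ad;   // per layer activations (incl. feature layer 0)
  std::vector<mat> Z, Zd;   // pre-activations of hidden layers
  mat X, Xd;                // outputs S x n (scaled)
};

// forward; if deriv, also propagate dA/dt
static void mlp_forward(const MLPViews& v, const IntegerVector& dims,
                        const IntegerVector& feats, double omega,
                        double Tscale, const vec& kout, const vec& t,
                        bool deriv, FwdCache& fc) {
  int nl = dims.size() - 1;      // number of dense layers
  vec tt = t / Tscale;
  fc.A.assign(nl, mat()); fc.Ad.assign(nl, mat());
  fc.Z.assign(nl, mat()); fc.Zd.assign(nl, mat());
  mat A0, A0d;
  feature_eval(tt, feats, omega, A0, A0d, deriv, Tscale);
  fc.A[0] = A0; if (deriv) fc.Ad[0] = A0d;
  mat A = A0, Adot = A0d;
  for (int i = 0; i < nl; ++i) {
    mat Z = v.W[i] * A;
    Z.each_col() += v.b[i];
    mat Zd;
    if (deriv) Zd = v.W[i] * Adot;
    if (i == nl - 1) {
      // linear output + output scaling
      fc.X = Z.each_col() % kout;
      if (deriv) fc.Xd = Zd.each_col() % kout;
    } else {
      fc.Z[i] = Z;
      mat Anew(Z.n_rows, Z.n_cols), Adnew;
      if (deriv) Adnew.set_size(Z.n_rows, Z.n_cols);
      for (arma::uword j = 0; j < Z.n_elem; ++j) {
        double f, d1, d2;
        swish3(Z(j), f, d1, d2);
        Anew(j) = f;
        if (deriv) Adnew(j) = d1 * Zd(j);
      }
      if (deriv) { fc.Zd[i] = Zd; fc.Ad[i + 1] = Adnew; Adot = Adnew; }
      A = Anew;
      fc.A[i + 1] = A;
    }
  }
}

// backward: G = dL/dX (S x n), H = dL/dXd (S x n, may be empty); accumulates
// into gtheta (flattened layout)
static void mlp_backward(const MLPViews& v, const IntegerVector& dims,
                         const vec& kout, const FwdCache& fc,
                         mat G, mat H, vec& gtheta) {
  int nl = dims.size() - 1;
  bool deriv = (H.n_elem > 0);
  // through output scaling
  G.each_col() %= kout;
  if (deriv) H.each_col() %= kout;
  // offsets of layers in theta
  std::vector<size_t> off(nl);
  size_t o = 0;
  for (int i = 0; i < nl; ++i) {
    off[i] = o;
    o += (size_t)dims[i + 1] * dims[i] + dims[i + 1];
  }
  mat dZ = G, dZd = H;   // output layer is linear
  for (int i = nl - 1; i >= 0; --i) {
    const mat& Aprev = fc.A[i];
    mat gW = dZ * Aprev.t();
    if (deriv) gW += dZd * fc.Ad[i].t();
    vec gb = arma::sum(dZ, 1);
    // accumulate into gtheta (called once per loss component)
    double* gp = gtheta.memptr() + off[i];
    const double* gwp = gW.memptr();
    for (arma::uword j = 0; j < gW.n_elem; ++j) gp[j] += gwp[j];
    double* gbp = gp + gW.n_elem;
    for (arma::uword j = 0; j < gb.n_elem; ++j) gbp[j] += gb(j);
    if (i == 0) break;
    mat Gprev = v.W[i].t() * dZ;
    mat Hprev;
    if (deriv) Hprev = v.W[i].t() * dZd;
    // through activation of layer i-1 (hidden)
    const mat& Z = fc.Z[i - 1];
    mat ndZ(Z.n_rows, Z.n_cols), ndZd;
    if (deriv) ndZd.set_size(Z.n_rows, Z.n_cols);
    for (arma::uword j = 0; j < Z.n_elem; ++j) {
      double f, d1, d2;
      swish3(Z(j), f, d1, d2);
      double h = deriv ? Hprev(j) : 0.0;
      double zd = deriv ? fc.Zd[i - 1](j) : 0.0;
      ndZ(j) = Gprev(j) * d1 + h * d2 * zd;
      if (deriv) ndZd(j) = h * d1;
    }
    dZ = ndZ;
    if (deriv) dZd = ndZd; else dZd.reset();
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_mlp_forward(const arma::vec& theta, IntegerVector dims,
                           IntegerVector feats, double omega, double Tscale,
                           const arma::vec& kout, const arma::vec& t,
                           bool deriv) {
  MLPViews v; mlp_views(theta, dims, v);
  FwdCache fc;
  mlp_forward(v, dims, feats, omega, Tscale, kout, t, deriv, fc);
  List out = List::create(_["x"] = mat(fc.X.t()));
  if (deriv) out["dxdt"] = mat(fc.Xd.t());
  return out;
}

// [[Rcpp::export]]
int cpp_mlp_nweights(IntegerVector dims) { return mlp_nweights(dims); }

// ---------------------------------------------------------------------------
// parameter transforms: type 0 fixed, 1 log-positive, 2 box(lo,hi)

static void build_params(const vec& raw, const IntegerVector& ptype,
                         const vec& pfix, const vec& plo, const vec& phi,
                         const vec& pref, const IntegerVector& praw_idx,
                         vec& p, vec& dpdraw) {
  int K = ptype.size();
  p.set_size(K); dpdraw.set_size(K);
  for (int k = 0; k < K; ++k) {
    if (ptype[k] == 0) { p(k) = pfix(k); dpdraw(k) = 0.0; }
    else if (ptype[k] == 1) {
      double e = pref(k) * std::exp(raw(praw_idx[k]));
      p(k) = e; dpdraw(k) = e;
    } else {
      double s = sigmoidd(raw(praw_idx[k]));
      p(k) = plo(k) + (phi(k) - plo(k)) * s;
      dpdraw(k) = (phi(k) - plo(k)) * s * (1.0 - s);
    }
  }
}

// ---------------------------------------------------------------------------
// composite loss + gradients
//
// stage 1: supervised only (data + aux); stage 2: + ODE residual.
// Event masses/timings optionally trainable (ultradian hidden forcing).

// [[Rcpp::export]]
Rcpp::List cpp_loss_grad(
    const arma::vec& theta, IntegerVector dims, IntegerVector feats,
    double omega, double Tscale, const arma::vec& kout,
    int model_id,
    const arma::vec& raw, IntegerVector ptype, const arma::vec& pfix,
    const arma::vec& plo, const arma::vec& phi, const arma::vec& pref,
    IntegerVector praw_idx,
    const arma::vec& ev_t0, const arma::vec& ev_m0,
    bool ev_m_free, bool ev_t_free,
    IntegerVector evm_raw_idx, IntegerVector evt_raw_idx,
    const arma::vec& evt_lo, const arma::vec& evt_hi,
    double order_penalty_w,
    const arma::vec& t_data, const arma::mat& y_data, IntegerVector obs_idx,
    const arma::vec& tau,
    const arma::vec& t_aux, const arma::mat& x_aux,
    const arma::vec& w_data, const arma::vec& w_ode, const arma::vec& w_aux,
    int stage, bool want_grad,
    Rcpp::Nullable<Rcpp::Function> user_model = R_NilValue) {

  int S = dims[dims.size() - 1];
  int M = obs_idx.size();
  int nd = t_data.n_elem;
  int naux = t_aux.n_elem;
  int ntau = tau.n_elem;

  MLPViews v; mlp_views(theta, dims, v);
  vec gtheta(theta.n_elem, arma::fill::zeros);
  vec graw(raw.n_elem, arma::fill::zeros);

  // natural parameters and events
  vec p, dpdraw;
  build_params(raw, ptype, pfix, plo, phi, pref, praw_idx, p, dpdraw);
  int nev = ev_t0.n_elem;
  vec ev_t = ev_t0, ev_m = ev_m0, dmdraw(nev, arma::fill::zeros),
      dtdraw(nev, arma::fill::zeros);
  if (ev_m_free)
    for (int j = 0; j < nev; ++j) {
      double e = std::exp(raw(evm_raw_idx[j]));
      ev_m(j) = e; dmdraw(j) = e;
    }
  if (ev_t_free)
    for (int j = 0; j < nev; ++j) {
      double s = sigmoidd(raw(evt_raw_idx[j]));
      ev_t(j) = evt_lo(j) + (evt_hi(j) - evt_lo(j)) * s;
      dtdraw(j) = (evt_hi(j) - evt_lo(j)) * s * (1.0 - s);
    }

  // ---- supervised pass: data + aux times ----
  vec t_sup(nd + naux);
  if (nd) t_sup.head(nd) = t_data;
  if (naux) t_sup.tail(naux) = t_aux;
  FwdCache fs;
  mlp_forward(v, dims, feats, omega, Tscale, kout, t_sup, false, fs);

  vec data_terms(M, arma::fill::zeros);
  mat Gsup(S, nd + naux, arma::fill::zeros);
  for (int m = 0; m < M; ++m) {
    int s = obs_idx[m] - 1;
    double acc = 0.0;
    for (int i = 0; i < nd; ++i) {
      double d = fs.X(s, i) - y_data(i, m);
      acc += d * d;
      Gsup(s, i) += 2.0 * w_data(m) * d / nd;
    }
    data_terms(m) = acc / nd;
  }
  vec aux_terms(S, arma::fill::zeros);
  for (int s = 0; s < S; ++s) {
    double acc = 0.0;
    for (int i = 0; i < naux; ++i) {
      double d = fs.X(s, nd + i) - x_aux(i, s);
      acc += d * d;
      Gsup(s, nd + i) += w_aux(s) * d;   // d/dx of w * sum(d^2)/2
    }
    aux_terms(s) = acc / 2.0;
  }
  if (want_grad) mlp_backward(v, dims, kout, fs, Gsup, mat(), gtheta);

  // ---- ODE residual pass ----
  vec ode_terms(S, arma::fill::zeros);
  if (stage >= 2 && ntau > 0) {
    FwdCache fo;
    mlp_forward(v, dims, feats, omega, Tscale, kout, tau, true, fo);
    // model f at surrogate states
    mat F(S, ntau);
    std::vector<double> fx(S);
    mat Gode(S, ntau, arma::fill::zeros), Hode(S, ntau, arma::fill::zeros);
    mat Jx, Jp, Jev;
    arma::cube uJX, uJP;          // user-model jacobians, one slice per point
    vec gp(p.n_elem, arma::fill::zeros);
    vec gev_m(nev, arma::fill::zeros), gev_t(nev, arma::fill::zeros);
    if (model_id == 0) {
      if (user_model.isNull())
        stop("training a user-defined system requires a model callback");
      Function fmod(user_model.get());
      List um = fmod(mat(fo.X.t()), tau, p, want_grad);
      F = trans(as<mat>(um["F"]));
      if (want_grad) {
        uJX = as<arma::cube>(um["Jx"]);
        uJP = as<arma::cube>(um["Jp"]);
      }
    } else {
      for (int i = 0; i < ntau; ++i) {
        vec xi = fo.X.col(i);
        model_f1(model_id, xi.memptr(), tau(i), p.memptr(), ev_t, ev_m,
                 fx.data());
        for (int s = 0; s < S; ++s) F(s, i) = fx[s];
      }
    }
    mat Rres = fo.Xd - F;
    for (int s = 0; s < S; ++s) {
      double acc = 0.0;
      for (int i = 0; i < ntau; ++i) acc += Rres(s, i) * Rres(s, i);
      ode_terms(s) = acc / ntau;
    }
    if (want_grad) {
      for (int i = 0; i < ntau; ++i) {
        if (model_id == 0) {
          Jx = uJX.slice(i); Jp = uJP.slice(i); Jev.zeros(S, 0);
        } else {
          vec xi = fo.X.col(i);
          model_jac1(model_id, xi.memptr(), tau(i), p.memptr(), ev_t, ev_m,
                     Jx, Jp, Jev);
        }
        vec wr(S);
        for (int s = 0; s < S; ++s)
          wr(s) = 2.0 * w_ode(s) * Rres(s, i) / ntau;
        Hode.col(i) = wr;
        Gode.col(i) = -(Jx.t() * wr);
        gp -= Jp.t() * wr;
        if (nev && (ev_m_free || ev_t_free)) {
          vec ge = Jev.t() * wr;  // length 2*nev
          for (int j = 0; j < nev; ++j) {
            gev_m(j) -= ge(j);
            gev_t(j) -= ge(nev + j);
          }
        }
      }
      mlp_backward(v, dims, kout, fo, Gode, Hode, gtheta);
      for (int k = 0; k < (int)p.n_elem; ++k)
        if (ptype[k] != 0) graw(praw_idx[k]) += gp(k) * dpdraw(k);
      if (ev_m_free)
        for (int j = 0; j < nev; ++j)
          graw(evm_raw_idx[j]) += gev_m(j) * dmdraw(j);
      if (ev_t_free)
        for (int j = 0; j < nev; ++j)
          graw(evt_raw_idx[j]) += gev_t(j) * dtdraw(j);
    }
  }

  // soft ordering penalty on trainable event timings
  double penalty = 0.0;
  if (ev_t_free && nev > 1) {
    for (int j = 0; j + 1 < nev; ++j) {
      double gap = ev_t(j) - ev_t(j + 1);
      if (gap > 0.0) {
        penalty += order_penalty_w * gap * gap;
        if (want_grad) {
          graw(evt_raw_idx[j]) += 2.0 * order_penalty_w * gap * dtdraw(j);
          graw(evt_raw_idx[j + 1]) -= 2.0 * order_penalty_w * gap *
                                      dtdraw(j + 1);
        }
      }
    }
  }

  double total = arma::dot(w_data, data_terms) + arma::dot(w_aux, aux_terms) +
                 penalty;
  if (stage >= 2) total += arma::dot(w_ode, ode_terms);

  return List::create(
      _["total"] = total,
      _["data_terms"] = data_terms,
      _["ode_terms"] = ode_terms,
      _["aux_terms"] = aux_terms,
      _["penalty"] = penalty,
      _["grad_theta"] = gtheta,
      _["grad_raw"] = graw,
      _["p"] = p,
      _["ev_t"] = ev_t,
      _["ev_m"] = ev_m);
}
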