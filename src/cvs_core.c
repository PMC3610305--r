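/* Compiled core of the multi-scale cardiovascular model.
 *
 * One set of static model equations serves four deSolve compiled models:
 *   - full closed loop (6 chamber volumes + 4 sarcomere states)
 *   - systemic subsystem (LV + aorta, constant venous pressures)
 *   - pulmonary subsystem (elastance RV + pulmonary artery, constant venous pressures)
 *   - isolated LV with prescribed volume (forcing): isovolumic beats and flow clamps
 * plus .Call helpers so the R-level operations exercise the same code paths.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

/* parameter slots, shared layout for every compiled model */
enum {
  iT1 = 0, iT2, iCamax, iPeriod,
  iY1, iZ1, iY2, iZ2, iY3, iZ3, iY4, iYd, iTt, iB, ihc, iLa, iRcurv,
  iA, iK, iL0, iAlpha, iBeta,
  iKv, iLr, iVw, iF,
  iEpa, iEpu, iEao, iEvc, iErv,
  iRpul, iRsys, iRav, iRmt, iRpv, iRtc,
  iVtot,
  iA1, iA2, iA3, iB1, iB2, iB3, iC1, iC2, iC3,
  iQout,               /* external pulmonary-vein outflow, ml/s            */
  iPpuC, iPvcC,        /* constant venous pressures (split subsystems)     */
  NPARMAX
};

#define NPAR_FULL  48   /* through iQout */
#define NPAR_SUB   50   /* through iPvcC */

static double parms[NPARMAX];
static double vforc[1]; /* prescribed LV volume (isolated-ventricle model) */

static double ramp(double x) { return x > 0.0 ? x : 0.0; }

static double cycle_time(double t, double period)
{
  double tc = fmod(t, period);
  if (tc < 0.0) tc += period;
  return tc;
}

/* two-cosine-branch intracellular calcium transient */
static double ca_driver(double t, const double *p)
{
  double tc = cycle_time(t, p[iPeriod]);
  if (tc < p[iT1])
    return 0.5 * p[iCamax] * (1.0 - cos(M_PI * tc / p[iT1]));
  if (tc < p[iT2])
    return 0.5 * p[iCamax] * (1.0 + cos(M_PI * (tc - p[iT1]) / (p[iT2] - p[iT1])));
  return 0.0;
}

/* three-Gaussian right-ventricular activation, evaluated on cycle time */
static double rv_activation(double t, const double *p)
{
  double tc = cycle_time(t, p[iPeriod]);
  double d1 = tc - p[iC1], d2 = tc - p[iC2], d3 = tc - p[iC3];
  return p[iA1] * exp(-p[iB1] * d1 * d1) +
         p[iA2] * exp(-p[iB2] * d2 * d2) +
         p[iA3] * exp(-p[iB3] * d3 * d3);
}

static double pow5(double x) { double x2 = x * x; return x2 * x2 * x; }
static double pow4(double x) { double x2 = x * x; return x2 * x2; }

/* Series/parallel/active force balance at fixed total muscle-unit length:
 * find half-sarcomere length L with
 *   A*ct*(L - X) + K*(L - L0)^5 = alpha*(exp(beta*(Lt - L)) - 1)
 * The left side is strictly increasing in L (ct >= 0), the right side strictly
 * decreasing, so the root is unique. Safeguarded Newton with bisection
 * fallback inside the bracket [0.5*L0, 1.5*Lt]; absolute force tolerance 1e-10.
 */
static double solve_partition(double Lt, double ct, double X,
                              double A, double K, double L0,
                              double alpha, double beta, int *err)
{
  double lo = 0.5 * L0, hi = 1.5 * Lt;
  double glo, ghi, L, g, dg, Ln;
  int it;

  *err = 0;
  glo = A * ct * (lo - X) + K * pow5(lo - L0) - alpha * expm1(beta * (Lt - lo));
  ghi = A * ct * (hi - X) + K * pow5(hi - L0) - alpha * expm1(beta * (Lt - hi));
  if (glo > 0.0 || ghi < 0.0 || !R_FINITE(glo) || !R_FINITE(ghi)) {
    *err = 1;
    return NA_REAL;
  }

  L = Lt - 0.02;                       /* series element is short in practice */
  if (L <= lo || L >= hi) L = 0.5 * (lo + hi);
  for (it = 0; it < 200; it++) {
    g = A * ct * (L - X) + K * pow5(L - L0) - alpha * expm1(beta * (Lt - L));
    if (fabs(g) < 1e-10) break;
    if (g > 0.0) hi = L; else lo = L;
    dg = A * ct + 5.0 * K * pow4(L - L0) + alpha * beta * exp(beta * (Lt - L));
    Ln = L - g / dg;
    if (!R_FINITE(Ln) || Ln <= lo || Ln >= hi) Ln = 0.5 * (lo + hi);
    if (fabs(Ln - L) < 1e-15) { L = Ln; break; }
    L = Ln;
  }
  return L;
}

/* four-state troponin/cross-bridge kinetics; d = (dTCa, dTCa*, dT*, dX) */
static void sarcomere_rates(double TCa, double TCs, double Ts, double X,
                            double L, double Ca, const double *p, double *d)
{
  double dX  = p[iB] * (L - X - p[ihc]);
  double T   = p[iTt] - TCa - TCs - Ts;
  double dLa = L - p[iLa];
  double TCaeff = TCa * exp(-p[iRcurv] * dLa * dLa);
  double Qa  = p[iY2] * TCaeff - p[iZ2] * TCs;
  double Qb  = p[iY1] * Ca * T - p[iZ1] * TCa;
  double Qr  = p[iY3] * TCs - p[iZ3] * Ts * Ca;
  double Qd  = p[iY4] * Ts;
  double Qd1 = p[iYd] * dX * dX * TCs;
  double Qd2 = p[iYd] * dX * dX * Ts;
  d[0] = Qb - Qa;
  d[1] = Qa - Qr - Qd1;
  d[2] = Qr - Qd - Qd2;
  d[3] = dX;
}

/* LV pressure from chamber volume and sarcomere state.
 * Returns Plv; optionally reports Lt, L, total force F. */
static double lv_pressure_core(double Vlv, double TCs, double Ts, double X,
                               const double *p, double *Lt_out, double *L_out,
                               double *F_out, int *err)
{
  double Lt = cbrt((p[iVw] * p[iF] + Vlv) / p[iKv]);
  double ct = TCs + Ts;
  double L = solve_partition(Lt, ct, X, p[iA], p[iK], p[iL0],
                             p[iAlpha], p[iBeta], err);
  double F, Plv;
  if (*err) return NA_REAL;
  F = p[iA] * ct * (L - X) + p[iK] * pow5(L - p[iL0]);
  Plv = 5.0 * F * p[iVw] / (p[iLr] * p[iKv] * Lt * Lt);
  if (Lt_out) *Lt_out = Lt;
  if (L_out)  *L_out = L;
  if (F_out)  *F_out = F;
  return Plv;
}

/* full closed loop.
 * y    = (Vlv, Vrv, Vao, Vvc, Vpa, Vpu, TCa, TCa*, T*, X)
 * yout = (Plv, Prv, Pao, Pvc, Ppa, Ppu, Qmt, Qav, Qsys, Qtc, Qpv, Qpul, L, F)
 */
#define NOUT_FULL 14
static void full_core(double t, const double *y, double *ydot, double *g,
                      const double *p)
{
  double Vlv = y[0], Vrv = y[1], Vao = y[2], Vvc = y[3], Vpa = y[4], Vpu = y[5];
  double TCa = y[6], TCs = y[7], Ts = y[8], X = y[9];
  int err = 0;
  double Lt, L, F;
  double Plv = lv_pressure_core(Vlv, TCs, Ts, X, p, &Lt, &L, &F, &err);
  double e, Prv, Pao, Pvc, Ppa, Ppu;
  double Qmt, Qav, Qsys, Qtc, Qpv, Qpul, Ca;

  if (err)
    Rf_error("muscle force balance not bracketed (Vlv = %g ml, Lt = %g um)",
             Vlv, Lt);

  e   = rv_activation(t, p);
  Prv = e * p[iErv] * Vrv;
  Pao = p[iEao] * Vao;
  Pvc = p[iEvc] * Vvc;
  Ppa = p[iEpa] * Vpa;
  Ppu = p[iEpu] * Vpu;

  Qmt  = ramp((Ppu - Plv) / p[iRmt]);
  Qav  = ramp((Plv - Pao) / p[iRav]);
  Qsys = (Pao - Pvc) / p[iRsys];
  Qtc  = ramp((Pvc - Prv) / p[iRtc]);
  Qpv  = ramp((Prv - Ppa) / p[iRpv]);
  Qpul = (Ppa - Ppu) / p[iRpul];

  ydot[0] = Qmt - Qav;
  ydot[1] = Qtc - Qpv;
  ydot[2] = Qav - Qsys;
  ydot[3] = Qsys - Qtc;
  ydot[4] = Qpv - Qpul;
  ydot[5] = Qpul - Qmt - p[iQout];

  Ca = ca_driver(t, p);
  sarcomere_rates(TCa, TCs, Ts, X, L, Ca, p, ydot + 6);

  if (g) {
    g[0] = Plv; g[1] = Prv; g[2] = Pao; g[3] = Pvc; g[4] = Ppa; g[5] = Ppu;
    g[6] = Qmt; g[7] = Qav; g[8] = Qsys; g[9] = Qtc; g[10] = Qpv; g[11] = Qpul;
    g[12] = L; g[13] = F;
  }
}

/* systemic subsystem: y = (Vlv, Vao, TCa, TCa*, T*, X);
 * yout = (Plv, Pao, Qmt, Qav, Qsys, L, F) */
#define NOUT_SYS 7
static void sys_core(double t, const double *y, double *ydot, double *g,
                     const double *p)
{
  double Vlv = y[0], Vao = y[1], TCa = y[2], TCs = y[3], Ts = y[4], X = y[5];
  int err = 0;
  double Lt, L, F;
  double Plv = lv_pressure_core(Vlv, TCs, Ts, X, p, &Lt, &L, &F, &err);
  double Pao, Qmt, Qav, Qsys, Ca;

  if (err)
    Rf_error("muscle force balance not bracketed (Vlv = %g ml)", Vlv);

  Pao  = p[iEao] * Vao;
  Qmt  = ramp((p[iPpuC] - Plv) / p[iRmt]);
  Qav  = ramp((Plv - Pao) / p[iRav]);
  Qsys = (Pao - p[iPvcC]) / p[iRsys];

  ydot[0] = Qmt - Qav;
  ydot[1] = Qav - Qsys;
  Ca = ca_driver(t, p);
  sarcomere_rates(TCa, TCs, Ts, X, L, Ca, p, ydot + 2);

  if (g) {
    g[0] = Plv; g[1] = Pao; g[2] = Qmt; g[3] = Qav; g[4] = Qsys;
    g[5] = L; g[6] = F;
  }
}

/* pulmonary subsystem: y = (Vrv, Vpa); yout = (Prv, Ppa, Qtc, Qpv, Qpul) */
#define NOUT_PULM 5
static void pulm_core(double t, const double *y, double *ydot, double *g,
                      const double *p)
{
  double Vrv = y[0], Vpa = y[1];
  double e   = rv_activation(t, p);
  double Prv = e * p[iErv] * Vrv;
  double Ppa = p[iEpa] * Vpa;
  double Qtc  = ramp((p[iPvcC] - Prv) / p[iRtc]);
  double Qpv  = ramp((Prv - Ppa) / p[iRpv]);
  double Qpul = (Ppa - p[iPpuC]) / p[iRpul];

  ydot[0] = Qtc - Qpv;
  ydot[1] = Qpv - Qpul;
  if (g) { g[0] = Prv; g[1] = Ppa; g[2] = Qtc; g[3] = Qpv; g[4] = Qpul; }
}

/* isolated LV with prescribed volume (forcing vforc[0]):
 * y = (TCa, TCa*, T*, X); yout = (Plv, L, F, Vlv) */
#define NOUT_LVISO 4
static void lviso_core(double t, const double *y, double *ydot, double *g,
                       const double *p, double Vlv)
{
  double TCa = y[0], TCs = y[1], Ts = y[2], X = y[3];
  int err = 0;
  double Lt, L, F;
  double Plv = lv_pressure_core(Vlv, TCs, Ts, X, p, &Lt, &L, &F, &err);
  double Ca;

  if (err)
    Rf_error("muscle force balance not bracketed (Vlv = %g ml)", Vlv);
  Ca = ca_driver(t, p);
  sarcomere_rates(TCa, TCs, Ts, X, L, Ca, p, ydot);
  if (g) { g[0] = Plv; g[1] = L; g[2] = F; g[3] = Vlv; }
}

/* ------------------------- deSolve entry points ------------------------- */

void cv_init(void (*odeparms)(int *, double *))
{
  int n = NPAR_SUB;
  odeparms(&n, parms);
}

void cv_forc_lviso(void (*odeforcs)(int *, double *))
{
  int n = 1;
  odeforcs(&n, vforc);
}

void cv_derivs_full(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
  if (ip[0] < NOUT_FULL) Rf_error("nout must be >= %d", NOUT_FULL);
  full_core(*t, y, ydot, yout, parms);
}

void cv_derivs_sys(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
  if (ip[0] < NOUT_SYS) Rf_error("nout must be >= %d", NOUT_SYS);
  sys_core(*t, y, ydot, yout, parms);
}

void cv_derivs_pulm(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
  if (ip[0] < NOUT_PULM) Rf_error("nout must be >= %d", NOUT_PULM);
  pulm_core(*t, y, ydot, yout, parms);
}

void cv_derivs_lviso(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
  if (ip[0] < NOUT_LVISO) Rf_error("nout must be >= %d", NOUT_LVISO);
  lviso_core(*t, y, ydot, yout, parms, vforc[0]);
}

/* ----------------------------- .Call helpers ---------------------------- */

static const double *check_parms(SEXP p, int nmin)
{
  if (!Rf_isReal(p) || Rf_length(p) < nmin)
    Rf_error("parameter vector must be numeric of length >= %d", nmin);
  return REAL(p);
}

SEXP cv_ca_conc(SEXP t, SEXP p)
{
  const double *pp = check_parms(p, 4);
  R_xlen_t i, n = Rf_xlength(t);
  SEXP out = PROTECT(Rf_allocVector(REALSXP, n));
  const double *tt = REAL(t);
  for (i = 0; i < n; i++) REAL(out)[i] = ca_driver(tt[i], pp);
  UNPROTECT(1);
  return out;
}

SEXP cv_rv_act(SEXP t, SEXP p)
{
  const double *pp = check_parms(p, iC3 + 1);
  R_xlen_t i, n = Rf_xlength(t);
  SEXP out = PROTECT(Rf_allocVector(REALSXP, n));
  const double *tt = REAL(t);
  for (i = 0; i < n; i++) REAL(out)[i] = rv_activation(tt[i], pp);
  UNPROTECT(1);
  return out;
}

SEXP cv_solve_partition(SEXP Lt, SEXP ct, SEXP X, SEXP p)
{
  const double *pp = check_parms(p, iBeta + 1);
  int err = 0;
  double L = solve_partition(Rf_asReal(Lt), Rf_asReal(ct), Rf_asReal(X),
                             pp[iA], pp[iK], pp[iL0], pp[iAlpha], pp[iBeta],
                             &err);
  if (err)
    Rf_error("force-balance root not bracketed in [0.5*L0, 1.5*Lt]: state or parameters are unphysical");
  return Rf_ScalarReal(L);
}

/* full-model right-hand side at one (t, y): derivatives then the 14 globals */
SEXP cv_full_rhs(SEXP t, SEXP y, SEXP p)
{
  const double *pp = check_parms(p, NPAR_FULL);
  SEXP out;
  double g[NOUT_FULL];
  if (Rf_length(y) != 10) Rf_error("state must have length 10");
  out = PROTECT(Rf_allocVector(REALSXP, 10 + NOUT_FULL));
  full_core(Rf_asReal(t), REAL(y), REAL(out), g, pp);
  memcpy(REAL(out) + 10, g, NOUT_FULL * sizeof(double));
  UNPROTECT(1);
  return out;
}
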