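#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* .Call helpers */
extern SEXP cv_ca_conc(SEXP, SEXP);
extern SEXP cv_rv_act(SEXP, SEXP);
extern SEXP cv_solve_partition(SEXP, SEXP, SEXP, SEXP);
extern SEXP cv_full_rhs(SEXP, SEXP, SEXP);

/* deSolve compiled-model entry points (looked up by name) */
extern void cv_init(void (*)(int *, double *));
extern void cv_forc_lviso(void (*)(int *, double *));
extern void cv_derivs_full(int *, double *, double *, double *, double *, int *);
extern void cv_derivs_sys(int *, double *, double *, double *, double *, int *);
extern void cv_derivs_pulm(int *, double *, double *, double *, double *, int *);
extern void cv_derivs_lviso(int *, double *, double *, double *, double *, int *);

static const R_CallMethodDef CallEntries[] = {
  {"cv_ca_conc",         (DL_FUNC) &cv_ca_conc,         2},
  {"cv_rv_act",          (DL_FUNC) &cv_rv_act,          2},
  {"cv_solve_partition", (DL_FUNC) &cv_solve_partition, 4},
  {"cv_full_rhs",        (DL_FUNC) &cv_full_rhs,        3},
  {NULL, NULL, 0}
};

static const R_CMethodDef CEntries[] = {
  {"cv_init",         (DL_FUNC) &cv_init,         1},
  {"cv_forc_lviso",   (DL_FUNC) &cv_forc_lviso,   1},
  {"cv_derivs_full",  (DL_FUNC) &cv_derivs_full,  6},
  {"cv_derivs_sys",   (DL_FUNC) &cv_derivs_sys,   6},
  {"cv_derivs_pulm",  (DL_FUNC) &cv_derivs_pulm,  6},
  {"cv_derivs_lviso", (DL_FUNC) &cv_derivs_lviso, 6},
  {NULL, NULL, 0}
};

void R_init_cvloop(DllInfo *dll)
{
  R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
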