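#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void lr91_rhs(double t, const double *y, double *dy, const double *p);
void tt06_rhs(double t, const double *y, double *dy, const double *p);
void lr91_derivs(int *, double *, double *, double *, double *, int *);
void tt06_derivs(int *, double *, double *, double *, double *, int *);
void lr91_initparms(void (*odeparms)(int *, double *));
void tt06_initparms(void (*odeparms)(int *, double *));

/* one-shot RHS evaluation, for derivative-level tests from R */
static SEXP eval_rhs(SEXP y, SEXP p, int n, int npar,
                     void (*rhs)(double, const double *, double *,
                                 const double *))
{
    if (LENGTH(y) != n) error("state vector must have length %d", n);
    if (LENGTH(p) != npar) error("parameter vector must have length %d", npar);
    SEXP dy = PROTECT(allocVector(REALSXP, n));
    rhs(0.0, REAL(y), REAL(dy), REAL(p));
    UNPROTECT(1);
    return dy;
}

SEXP C_lr91_deriv(SEXP y, SEXP p) { return eval_rhs(y, p, 8, 9, lr91_rhs); }
SEXP C_tt06_deriv(SEXP y, SEXP p) { return eval_rhs(y, p, 19, 8, tt06_rhs); }

static const R_CallMethodDef callMethods[] = {
    {"C_lr91_deriv", (DL_FUNC) &C_lr91_deriv, 2},
    {"C_tt06_deriv", (DL_FUNC) &C_tt06_deriv, 2},
    {NULL, NULL, 0}
};

static const R_CMethodDef cMethods[] = {
    {"lr91_derivs", (DL_FUNC) &lr91_derivs, 6},
    {"tt06_derivs", (DL_FUNC) &tt06_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_apdecon(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, callMethods, NULL, NULL);
    /* keep dynamic lookup on: deSolve resolves initparms/derivs by name */
    R_useDynamicSymbols(dll, TRUE);
}
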