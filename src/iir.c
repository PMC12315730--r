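/* Direct-form-II-transposed IIR filtering with zero initial state. */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_iir_filter(SEXP b_, SEXP a_, SEXP x_)
{
    const int nb = LENGTH(b_), na = LENGTH(a_);
    const R_xlen_t n = XLENGTH(x_);
    const int nw = (nb > na ? nb : na);
    const double *b = REAL(b_), *a = REAL(a_), *x = REAL(x_);
    SEXP y_ = PROTECT(allocVector(REALSXP, n));
    double *y = REAL(y_);
    double *w = (double *) R_alloc(nw, sizeof(double));
    for (int i = 0; i < nw; i++) w[i] = 0.0;

    for (R_xlen_t t = 0; t < n; t++) {
        const double xn = x[t];
        const double yn = b[0] * xn + w[0];
        for (int i = 0; i < nw - 1; i++) {
            const double bi = (i + 1 < nb) ? b[i + 1] : 0.0;
            const double ai = (i + 1 < na) ? a[i + 1] : 0.0;
            w[i] = bi * xn - ai * yn + w[i + 1];   /* w[nw-1] is always 0 */
        }
        y[t] = yn;
    }
    UNPROTECT(1);
    return y_;
}

static const R_CallMethodDef CallEntries[] = {
    {"C_iir_filter", (DL_FUNC) &C_iir_filter, 3},
    {NULL, NULL, 0}
};

void R_init_smrloop(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
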