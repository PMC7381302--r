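/* Generic mass-action derivative for deSolve compiled models.
 *
 * The model (reactant index pairs, stoichiometry triplets grouped per
 * reaction) is staged from R via .Call before each solve; the derivative
 * itself is looked up by name from deSolve.  State may include trailing
 * accumulator components: they are ordinary rows of the stoichiometry.
 * Global staging implies one model at a time (the package solves serially).
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

static SEXP ma_keep_model = NULL;
static SEXP ma_keep_k = NULL;

static int ma_nstate = 0;
static int ma_nrxn = 0;
static int *ma_r1 = NULL;     /* first reactant index, 0-based, -1 = none   */
static int *ma_r2 = NULL;     /* second reactant index, 0-based, -1 = none  */
static int *ma_off = NULL;    /* per-reaction offsets into triplet arrays   */
static int *ma_idx = NULL;    /* state index of each stoichiometry entry    */
static double *ma_val = NULL; /* stoichiometric coefficient                 */
static double *ma_k = NULL;   /* rate constants, one per reaction           */

SEXP ma_set_model(SEXP model)
{
    /* model: list(nstate, r1, r2, off, idx, val) with integer vectors
       r1/r2/off/idx already 0-based where applicable */
    if (ma_keep_model != NULL) R_ReleaseObject(ma_keep_model);
    R_PreserveObject(model);
    ma_keep_model = model;

    ma_nstate = INTEGER(VECTOR_ELT(model, 0))[0];
    ma_r1 = INTEGER(VECTOR_ELT(model, 1));
    ma_r2 = INTEGER(VECTOR_ELT(model, 2));
    ma_off = INTEGER(VECTOR_ELT(model, 3));
    ma_idx = INTEGER(VECTOR_ELT(model, 4));
    ma_val = REAL(VECTOR_ELT(model, 5));
    ma_nrxn = LENGTH(VECTOR_ELT(model, 1));
    return R_NilValue;
}

SEXP ma_set_k(SEXP k)
{
    if (ma_keep_k != NULL) R_ReleaseObject(ma_keep_k);
    R_PreserveObject(k);
    ma_keep_k = k;
    ma_k = REAL(k);
    return R_NilValue;
}

void ma_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    int i, j;
    for (i = 0; i < *neq; i++) ydot[i] = 0.0;
    for (j = 0; j < ma_nrxn; j++) {
        double rate = ma_k[j];
        if (ma_r1[j] >= 0) rate *= y[ma_r1[j]];
        if (ma_r2[j] >= 0) rate *= y[ma_r2[j]];
        for (i = ma_off[j]; i < ma_off[j + 1]; i++)
            ydot[ma_idx[i]] += ma_val[i] * rate;
    }
}

static const R_CallMethodDef call_entries[] = {
    {"ma_set_model", (DL_FUNC) &ma_set_model, 1},
    {"ma_set_k",     (DL_FUNC) &ma_set_k,     1},
    {NULL, NULL, 0}
};

static const R_CMethodDef c_entries[] = {
    {"ma_derivs", (DL_FUNC) &ma_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_evnest(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
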