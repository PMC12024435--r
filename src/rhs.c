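/* Compiled right-hand side of the metabolic mass balances dC/dt = S v(C).
 *
 * The model layout (stoichiometric matrix, per-term substrate indices and
 * Km values, per-law vmax) is packed into a double vector by the R side
 * (pack_model()) and installed with .Call("aavmet_set_model", ...) before
 * each integration; deSolve then calls aavmet_rhs() directly.
 *
 * Layout of the packed vector:
 *   [0] n_state  [1] n_laws  [2] n_fw_terms  [3] n_rv_terms
 *   S (n_state * n_laws, column-major by law)
 *   fw_vmax (n_laws)   rv_vmax (n_laws; 0 for irreversible laws)
 *   fw_sp, fw_law, fw_km (n_fw_terms each; indices 1-based)
 *   rv_sp, rv_law, rv_km (n_rv_terms each)
 *
 * Concentrations are floored at zero before the saturation terms are
 * formed, so integrator overshoot below zero cannot drive negative flux.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <stdlib.h>
#include <string.h>

static double *model_pack = NULL;
static R_xlen_t model_len = 0;

SEXP aavmet_set_model(SEXP pack)
{
    R_xlen_t n = XLENGTH(pack);
    double *src = REAL(pack);
    double *buf = (double *) realloc(model_pack, n * sizeof(double));
    if (buf == NULL)
        error("aavmet: could not allocate model buffer");
    memcpy(buf, src, n * sizeof(double));
    model_pack = buf;
    model_len = n;
    return R_NilValue;
}

void aavmet_rhs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    if (model_pack == NULL)
        error("aavmet: model layout not installed");
    const double *p = model_pack;
    int n_state = (int) p[0];
    int n_laws  = (int) p[1];
    int n_fw    = (int) p[2];
    int n_rv    = (int) p[3];
    const double *S       = p + 4;
    const double *fw_vmax = S + (size_t) n_state * n_laws;
    const double *rv_vmax = fw_vmax + n_laws;
    const double *fw_sp   = rv_vmax + n_laws;
    const double *fw_law  = fw_sp + n_fw;
    const double *fw_km   = fw_law + n_fw;
    const double *rv_sp   = fw_km + n_fw;
    const double *rv_law  = rv_sp + n_rv;
    const double *rv_km   = rv_law + n_rv;

    double v[128], vr[128];
    if (n_laws > 128)
        error("aavmet: too many flux laws for the compiled kernel");

    for (int l = 0; l < n_laws; l++) {
        v[l] = fw_vmax[l];
        vr[l] = rv_vmax[l];
    }
    for (int k = 0; k < n_fw; k++) {
        double c = y[(int) fw_sp[k] - 1];
        if (c < 0) c = 0;
        v[(int) fw_law[k] - 1] *= c / (fw_km[k] + c);
    }
    for (int k = 0; k < n_rv; k++) {
        double c = y[(int) rv_sp[k] - 1];
        if (c < 0) c = 0;
        vr[(int) rv_law[k] - 1] *= c / (rv_km[k] + c);
    }
    for (int l = 0; l < n_laws; l++)
        v[l] -= vr[l];

    for (int s = 0; s < n_state; s++)
        ydot[s] = 0.0;
    for (int l = 0; l < n_laws; l++) {
        const double *col = S + (size_t) l * n_state;
        double vl = v[l];
        for (int s = 0; s < n_state; s++)
            ydot[s] += col[s] * vl;
    }
}

static const R_CallMethodDef call_entries[] = {
    {"aavmet_set_model", (DL_FUNC) &aavmet_set_model, 1},
    {NULL, NULL, 0}
};

static const R_CMethodDef c_entries[] = {
    {"aavmet_rhs", (DL_FUNC) &aavmet_rhs, 6},
    {NULL, NULL, 0}
};

void R_init_aavmet(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
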