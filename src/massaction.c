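/* Compiled right-hand sides for mass-action reaction networks and their
 * forward sensitivity systems, driven through deSolve's compiled-function
 * interface. The active network is staged into module globals from R
 * (integrations are strictly sequential) before each lsoda call:
 *   ma_set_network(): topology (net stoichiometry, reactant indices,
 *                     rate-parameter indices, input-modulation flags)
 *   ma_set_run():     rate-constant values and the current input value
 * Rates are r_j = k_j * u^[mod_j] * x[i1_j] * (i2_j >= 0 ? x[i2_j] : 1),
 * i.e. mass action of total order one or two.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

static int g_nx = 0, g_nr = 0, g_np = 0;
static double *g_N = NULL;     /* nx x nr net stoichiometry, column-major */
static int *g_i1 = NULL;       /* first reactant index, 0-based */
static int *g_i2 = NULL;       /* second reactant index or -1 */
static int *g_rate = NULL;     /* rate-parameter index, 0-based */
static int *g_mod = NULL;      /* input-modulated flag */
static double *g_k = NULL;     /* rate-constant values, length np */
static double g_u = 0.0;       /* current input value */
static double *g_r = NULL;     /* scratch: rates, length nr */
static double *g_T = NULL;     /* scratch: nr x np, column-major */

static void ma_free_all(void)
{
    R_Free(g_N); R_Free(g_i1); R_Free(g_i2); R_Free(g_rate); R_Free(g_mod);
    R_Free(g_k); R_Free(g_r); R_Free(g_T);
    g_N = NULL; g_i1 = g_i2 = g_rate = g_mod = NULL;
    g_k = g_r = g_T = NULL;
}

SEXP ma_set_network(SEXP nx, SEXP nr, SEXP np, SEXP Nmat, SEXP i1, SEXP i2,
                    SEXP rateIdx, SEXP mod)
{
    int j;
    ma_free_all();
    g_nx = INTEGER(nx)[0];
    g_nr = INTEGER(nr)[0];
    g_np = INTEGER(np)[0];
    g_N = R_Calloc((size_t) g_nx * g_nr, double);
    g_i1 = R_Calloc(g_nr, int);
    g_i2 = R_Calloc(g_nr, int);
    g_rate = R_Calloc(g_nr, int);
    g_mod = R_Calloc(g_nr, int);
    g_k = R_Calloc(g_np, double);
    g_r = R_Calloc(g_nr, double);
    g_T = R_Calloc((size_t) g_nr * g_np, double);
    memcpy(g_N, REAL(Nmat), sizeof(double) * (size_t) g_nx * g_nr);
    for (j = 0; j < g_nr; j++) {
        g_i1[j] = INTEGER(i1)[j];
        g_i2[j] = INTEGER(i2)[j];
        g_rate[j] = INTEGER(rateIdx)[j];
        g_mod[j] = INTEGER(mod)[j];
    }
    return R_NilValue;
}

SEXP ma_set_run(SEXP k, SEXP u)
{
    memcpy(g_k, REAL(k), sizeof(double) * g_np);
    g_u = REAL(u)[0];
    return R_NilValue;
}

/* deSolve initializer: the network is staged via .Call, parms are unused */
void ma_init(void (*odeparms)(int *, double *))
{
    int n = 0;
    (void) odeparms; (void) n;
}

static void ma_rates(const double *x)
{
    int j;
    for (j = 0; j < g_nr; j++) {
        double r = g_k[g_rate[j]] * x[g_i1[j]];
        if (g_i2[j] >= 0) r *= x[g_i2[j]];
        if (g_mod[j]) r *= g_u;
        g_r[j] = r;
    }
}

/* dx/dt = N r(x) */
void ma_derivs(int *neq, double *t, double *y, double *ydot, double *yout,
               int *ip)
{
    int i, j;
    (void) neq; (void) t; (void) yout; (void) ip;
    ma_rates(y);
    for (i = 0; i < g_nx; i++) ydot[i] = 0.0;
    for (j = 0; j < g_nr; j++) {
        const double *Nj = g_N + (size_t) j * g_nx;
        double r = g_r[j];
        if (r == 0.0) continue;
        for (i = 0; i < g_nx; i++) ydot[i] += Nj[i] * r;
    }
}

/* State + forward sensitivity system:
 *   y = (x, vec S), S is nx x np column-major,
 *   dS = Jx S + Jp with Jx = N D (D the rate Jacobian, two nonzeros per
 *   row) and Jp = N E, E[j, rate_j] = r_j / k_{rate_j}.
 *   Computed as dS = N T with T[j, p] = D_j1 S[i1, p] + D_j2 S[i2, p]
 *   (+ r_j / k on the reaction's own rate column).
 */
void ma_derivs_sens(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    int i, j, p;
    const double *S = y + g_nx;
    double *dS = ydot + g_nx;
    (void) neq; (void) t; (void) yout; (void) ip;

    ma_rates(y);
    for (i = 0; i < g_nx; i++) ydot[i] = 0.0;
    for (j = 0; j < g_nr; j++) {
        const double *Nj = g_N + (size_t) j * g_nx;
        double r = g_r[j];
        for (i = 0; i < g_nx; i++) ydot[i] += Nj[i] * r;
    }

    for (j = 0; j < g_nr; j++) {
        double ku = g_k[g_rate[j]];
        double d1, d2 = 0.0;
        double rk;
        int a = g_i1[j], b = g_i2[j];
        if (g_mod[j]) ku *= g_u;
        d1 = ku * (b >= 0 ? y[b] : 1.0);
        if (b >= 0) d2 = ku * y[a];
        rk = (g_k[g_rate[j]] > 0.0) ? g_r[j] / g_k[g_rate[j]] : 0.0;
        for (p = 0; p < g_np; p++) {
            const double *Sp = S + (size_t) p * g_nx;
            double tv = d1 * Sp[a];
            if (b >= 0) tv += d2 * Sp[b];
            if (p == g_rate[j]) tv += rk;
            g_T[j + (size_t) p * g_nr] = tv;
        }
    }
    for (p = 0; p < g_np; p++) {
        double *dSp = dS + (size_t) p * g_nx;
        for (i = 0; i < g_nx; i++) dSp[i] = 0.0;
        for (j = 0; j < g_nr; j++) {
            double tv = g_T[j + (size_t) p * g_nr];
            const double *Nj = g_N + (size_t) j * g_nx;
            if (tv == 0.0) continue;
            for (i = 0; i < g_nx; i++) dSp[i] += Nj[i] * tv;
        }
    }
}

static const R_CallMethodDef callMethods[] = {
    {"ma_set_network", (DL_FUNC) &ma_set_network, 8},
    {"ma_set_run", (DL_FUNC) &ma_set_run, 2},
    {NULL, NULL, 0}
};

void R_init_kinetred(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, TRUE);
}
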