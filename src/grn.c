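/* Data-driven kinetic right-hand side for the CSF1R GRN model.
 *
 * The model is fully described by a flat double vector ("pack") built on the
 * R side from a network definition, a named parameter set and the current
 * inputs (LPS level, per-component synthesis scale).  Layout:
 *
 *   [0] n_comp   number of components (mRNA variables)
 *   [1] n_prot   number of components with an inactive/active protein pair
 *   [2] ratio    protein/mRNA scale for components without an active form
 *   [3] lps      dimensionless stimulus level (input)
 *   [4 .. 4+n_prot-1]                comp_of_prot (0-based component index)
 *   then contiguous blocks:
 *     v0[n_comp], kdm[n_comp], ksp[n_prot], kdp[n_prot], kin[n_prot],
 *     scale[n_comp]
 *   [.] n_tedges, then per transcriptional edge 6 doubles:
 *       target, src, sign(+1/-1), v, K, n      (src: component index or
 *                                               n_comp for the LPS input)
 *   [.] n_pedges, then per post-translational edge 5 doubles:
 *       prot, src, ka, Ka, n                   (Ka == 0 -> linear in source)
 *
 * State layout: y[0..n_comp-1] mRNA; y[n_comp..n_comp+n_prot-1] inactive
 * protein; y[n_comp+n_prot ..] active protein.
 *
 * Kinetics: transcription of component i is
 *   scale_i * (v0_i + sum_act v_e * H(A_src; K_e, n_e))
 *           * prod_inh K_e^n / (K_e^n + A_src^n)  -  kdm_i * M_i
 * with H(A;K,n) = A^n / (K^n + A^n); regulator activity A is the active
 * protein for components with an active form, ratio * mRNA otherwise, and
 * the raw LPS level for input edges.  Protein pools follow
 *   dPI = ksp*M - act*PI + kin*PA - kdp*PI
 *   dPA =         act*PI - kin*PA - kdp*PA
 * with act = sum_e ka_e * H(A_src; Ka_e, n_e).
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define MAX_PACK 2048
static double pack_static[MAX_PACK];
static int pack_len_static = 0;

static double hillpos(double a, double k, double n)
{
    double an, kn;
    if (a <= 0.0) return 0.0;
    if (k <= 0.0) return 1.0;
    an = pow(a, n);
    kn = pow(k, n);
    return an / (kn + an);
}

static void grn_core(const double *p, const double *y, double *dy)
{
    int n_comp = (int) p[0];
    int n_prot = (int) p[1];
    double ratio = p[2];
    double lps = p[3];
    const double *comp_of_prot = p + 4;
    const double *v0   = comp_of_prot + n_prot;
    const double *kdm  = v0 + n_comp;
    const double *ksp  = kdm + n_comp;
    const double *kdp  = ksp + n_prot;
    const double *kin  = kdp + n_prot;
    const double *scale = kin + n_prot;
    const double *q = scale + n_comp;
    int n_tedges, n_pedges, i, k, e;
    double act_of_comp[64];   /* regulator activity per component */
    double prod[64], inh[64]; /* transcription accumulation */
    double actflux[16];

    /* regulator activities */
    for (i = 0; i < n_comp; i++) act_of_comp[i] = ratio * y[i];
    for (k = 0; k < n_prot; k++) {
        int c = (int) comp_of_prot[k];
        act_of_comp[c] = y[n_comp + n_prot + k]; /* active protein */
    }

    for (i = 0; i < n_comp; i++) { prod[i] = v0[i]; inh[i] = 1.0; }
    for (k = 0; k < n_prot; k++) actflux[k] = 0.0;

    n_tedges = (int) q[0]; q++;
    for (e = 0; e < n_tedges; e++, q += 6) {
        int tgt = (int) q[0];
        int src = (int) q[1];
        double a = (src == n_comp) ? lps : act_of_comp[src];
        if (q[2] > 0.0) {            /* activation */
            prod[tgt] += q[3] * hillpos(a, q[4], q[5]);
        } else {                     /* inhibition: K^n/(K^n + A^n) */
            inh[tgt] *= 1.0 - hillpos(a, q[4], q[5]);
        }
    }
    n_pedges = (int) q[0]; q++;
    for (e = 0; e < n_pedges; e++, q += 5) {
        int pk = (int) q[0];
        int src = (int) q[1];
        double a = (src == n_comp) ? lps : act_of_comp[src];
        /* Ka <= 0 encodes a rate linear in the source activity; the value is
           deliberately left unclamped so that continuation to negative LPS
           can trace the (non-physical) connection of the middle and upper
           branches through their saddle-node. */
        if (q[3] <= 0.0) actflux[pk] += q[2] * a;
        else             actflux[pk] += q[2] * hillpos(a, q[3], q[4]);
    }

    for (i = 0; i < n_comp; i++)
        dy[i] = scale[i] * prod[i] * inh[i] - kdm[i] * y[i];
    for (k = 0; k < n_prot; k++) {
        int c = (int) comp_of_prot[k];
        double pi = y[n_comp + k];
        double pa = y[n_comp + n_prot + k];
        double af = actflux[k];
        dy[n_comp + k] = ksp[k] * y[c] - af * pi + kin[k] * pa - kdp[k] * pi;
        dy[n_comp + n_prot + k] = af * pi - kin[k] * pa - kdp[k] * pa;
    }
}

/* .Call interface: C_grn_rhs(pack, y) -> dy */
SEXP C_grn_rhs(SEXP pack, SEXP y)
{
    int ny = LENGTH(y);
    SEXP dy = PROTECT(allocVector(REALSXP, ny));
    grn_core(REAL(pack), REAL(y), REAL(dy));
    UNPROTECT(1);
    return dy;
}

/* deSolve compiled-code interface; the R side pads parms to MAX_PACK so the
   requested length always matches. */
void grn_initmod(void (*odeparms)(int *, double *))
{
    int n = MAX_PACK;
    odeparms(&n, pack_static);
    pack_len_static = n;
}

void grn_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    (void) t; (void) yout; (void) ip;
    grn_core(pack_static, y, ydot);
    (void) neq;
}

static const R_CallMethodDef call_entries[] = {
    {"C_grn_rhs", (DL_FUNC) &C_grn_rhs, 2},
    {NULL, NULL, 0}
};

void R_init_csfgrn(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_forceSymbols(dll, FALSE);
}
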