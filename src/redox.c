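/* Compiled right-hand side of the reduced erythrocyte redox network.
 *
 * State vector (dynamic species, micromolar):
 *   y[0] h2o2   intracellular hydrogen peroxide
 *   y[1] o2minus superoxide
 *   y[2] gsh    reduced glutathione
 *   y[3] gssg   oxidised glutathione
 *   y[4] nadph
 *   y[5] nadp
 *   y[6] g6p    glucose-6-phosphate
 *   y[7] gl6p   6-phosphogluconolactone (lumped with 6PG)
 *
 * Parameter vector (24 slots, see model_parms_vector() on the R side):
 *   p[0]  h2o2_ext (clamped, uM)      p[1]  atp (clamped, uM)
 *   p[2]  bpg23 (clamped, uM)         p[3]  k_diff (1/s)
 *   p[4]  v_gen (uM/s)                p[5]  k_sod (1/s)
 *   p[6]  k_cat (1/s)                 p[7]  vmax_gshpx (uM/s)
 *   p[8]  km_gshpx_h2o2 (uM)          p[9]  km_gshpx_gsh (uM)
 *   p[10] vmax_gr (uM/s)              p[11] km_gr_gssg (uM)
 *   p[12] km_gr_nadph (uM)            p[13] k_ppp2 (1/s)
 *   p[14] km_ppp2_nadp (uM)           p[15] v_g6p_supply (uM/s)
 *   p[16] k_g6p_drain (1/s)           p[17] k_nadph_drain (1/s)
 *   p[18] vmax_g6pd (model velocity units, used as uM/s)
 *   p[19] km_g6p (uM)                 p[20] km_nadp (uM)
 *   p[21] ki_nadph (uM)               p[22] ki_atp (uM)
 *   p[23] ki_23bpg (uM)
 *
 * Flux outputs (11, reaction order of the model definition file):
 *   h2o2_influx, o2minus_generation, SOD, CAT, GSHpx, GR, G6PD,
 *   ppp_second_step, g6p_supply, g6p_drain, nadph_drain
 */

#include <R.h>
#include <Rinternals.h>

#define N_PARMS 24
#define N_SPEC 8
#define N_FLUX 11

static double parms[N_PARMS];

void redox_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

static void redox_fluxes(const double *y, const double *p, double *v)
{
    double h = y[0], o2 = y[1], gsh = y[2], gssg = y[3];
    double nadph = y[4], nadp = y[5], g6p = y[6], gl6p = y[7];

    v[0] = p[3] * (p[0] - h);                              /* h2o2_influx   */
    v[1] = p[4];                                           /* o2- generation */
    v[2] = p[5] * o2;                                      /* SOD            */
    v[3] = p[6] * h;                                       /* CAT            */
    v[4] = p[7] * h / (p[8] + h) * gsh / (p[9] + gsh);     /* GSHpx          */
    v[5] = p[10] * gssg / (p[11] + gssg)
                 * nadph / (p[12] + nadph);                /* GR             */
    /* G6PD, product-inhibited ordered rate law */
    {
        double den = p[20] * p[19] *
            (1.0 + (nadp / p[20]) * (1.0 + g6p / p[19]) +
             nadph / p[21] + p[1] / p[22] + p[2] / p[23]);
        v[6] = p[18] * nadp * g6p / den;
    }
    v[7] = p[13] * gl6p * nadp / (p[14] + nadp);           /* ppp 2nd step  */
    v[8] = p[15];                                          /* g6p supply    */
    v[9] = p[16] * g6p;                                    /* g6p drain     */
    v[10] = p[17] * nadph;                                 /* nadph drain   */
}

static void redox_accumulate(const double *v, double *ydot)
{
    ydot[0] = v[0] + v[2] - 2.0 * v[3] - v[4];             /* h2o2   */
    ydot[1] = v[1] - 2.0 * v[2];                           /* o2-    */
    ydot[2] = -2.0 * v[4] + 2.0 * v[5];                    /* gsh    */
    ydot[3] = v[4] - v[5];                                 /* gssg   */
    ydot[4] = v[6] + v[7] - v[5] - v[10];                  /* nadph  */
    ydot[5] = -v[6] - v[7] + v[5] + v[10];                 /* nadp   */
    ydot[6] = v[8] - v[9] - v[6];                          /* g6p    */
    ydot[7] = v[6] - v[7];                                 /* gl6p   */
}

void redox_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double v[N_FLUX];
    if (ip[0] < N_FLUX)
        error("insufficient output slots for reaction fluxes");
    redox_fluxes(y, parms, v);
    redox_accumulate(v, ydot);
    for (int i = 0; i < N_FLUX; i++)
        yout[i] = v[i];
}

/* .Call entry: derivative + fluxes at a single state, used by the
 * steady-state Newton polish and by cross-checks against the R evaluator. */
SEXP C_redox_rhs(SEXP sy, SEXP sp)
{
    if (LENGTH(sy) != N_SPEC || LENGTH(sp) != N_PARMS)
        error("bad state or parameter length");
    double v[N_FLUX];
    SEXP dy = PROTECT(allocVector(REALSXP, N_SPEC));
    SEXP fl = PROTECT(allocVector(REALSXP, N_FLUX));
    redox_fluxes(REAL(sy), REAL(sp), v);
    redox_accumulate(v, REAL(dy));
    for (int i = 0; i < N_FLUX; i++)
        REAL(fl)[i] = v[i];
    SEXP out = PROTECT(allocVector(VECSXP, 2));
    SET_VECTOR_ELT(out, 0, dy);
    SET_VECTOR_ELT(out, 1, fl);
    SEXP nms = PROTECT(allocVector(STRSXP, 2));
    SET_STRING_ELT(nms, 0, mkChar("deriv"));
    SET_STRING_ELT(nms, 1, mkChar("flux"));
    setAttrib(out, R_NamesSymbol, nms);
    UNPROTECT(4);
    return out;
}
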