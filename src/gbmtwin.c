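/* Compiled right-hand side of the GSC hierarchy / BMP4 delivery ODE system,
 * in the deSolve compiled-code interface (initfunc + derivs looked up by name).
 *
 * State layout: y[0] = s (GSCs), y[1..n] = v_1..v_n (progenitors, v_n = TDCs),
 * y[n+1] = B (BMP4, ng/mL), y[n+2] = m (AMSCs).  All rates are per day.
 */

#include <R.h>

#define NPARMS 18
#define NMAX   64

static double parms[NPARMS];

#define P_N      parms[0]   /* proliferative capacity n (integer valued)   */
#define P_MS     parms[1]   /* GSC proliferation rate (per day)            */
#define P_MIS    parms[2]   /* PC-to-GSC proliferation ratio               */
#define P_DS     parms[3]   /* GSC death rate (per day)                    */
#define P_DIS    parms[4]   /* PC death multiplier (delta_i = dis*ds)      */
#define P_DNS    parms[5]   /* TDC death multiplier (delta_n = dns*delta_i)*/
#define P_K      parms[6]   /* carrying capacity                           */
#define P_PSMAX  parms[7]   /* max self-renewal probability                */
#define P_PSMIN  parms[8]   /* min self-renewal probability                */
#define P_PSI    parms[9]   /* self-renewal sensitivity (per ng/mL)        */
#define P_PHI    parms[10]  /* compartment sensitivity (per ng/mL)         */
#define P_DM     parms[11]  /* AMSC decay rate (per day)                   */
#define P_DB     parms[12]  /* BMP4 decay rate (per day)                   */
#define P_CREL   parms[13]  /* BMP4 release rate per AMSC (per day)        */
#define P_UB     parms[14]  /* BMP4 uptake rate by GSCs (per day per unit) */
#define P_INF    parms[15]  /* AMSC infusion rate (units per day)          */
#define P_PSFIX  parms[16]  /* >= 0: hold Ps at this value (assay CTRL)    */
#define P_HOLDB  parms[17]  /* 1: freeze B and m (assay bath conditions)   */

void gbmtwin_init(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

/* unit triangle: 1+x on [-1,0), 1-x on [0,1), else 0 */
static double tri(double x)
{
    if (x >= -1.0 && x < 0.0) return 1.0 + x;
    if (x >= 0.0 && x < 1.0)  return 1.0 - x;
    return 0.0;
}

void gbmtwin_rhs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    int n = (int) (P_N + 0.5);
    double s = y[0];
    double *v = y + 1;               /* v[i-1] is compartment i */
    double B = y[n + 1];
    double m = y[n + 2];
    double r[NMAX];
    int i, j;

    double N = s;
    for (i = 0; i < n; i++) N += v[i];
    double crowd = 1.0 - N / P_K;

    double Ps = (P_PSFIX >= 0.0)
        ? P_PSFIX
        : P_PSMIN + (P_PSMAX - P_PSMIN) / (1.0 + P_PSI * B);

    /* differentiation distribution: triangle centred at theta = 1 + phi*B,
     * mass past compartment n lumped into the TDC compartment */
    double theta = 1.0 + P_PHI * B;
    double sum = 0.0, tail = 0.0;
    for (i = 1; i <= n; i++) {
        r[i - 1] = tri((double) i - theta);
        sum += r[i - 1];
    }
    for (j = n + 1; (double) j < theta + 1.0; j++)
        tail += tri((double) j - theta);
    r[n - 1] += tail;
    sum += tail;
    if (sum <= 0.0) {                /* theta beyond n+1: straight to TDCs */
        for (i = 0; i < n; i++) r[i] = 0.0;
        r[n - 1] = 1.0;
        sum = 1.0;
    }
    for (i = 0; i < n; i++) r[i] /= sum;

    double mi  = P_MIS * P_MS;
    double di  = P_DIS * P_DS;
    double dn  = P_DNS * di;
    double grow = P_MS * s * crowd;            /* ms * s * (1 - N/K) */
    double diff = 2.0 * (1.0 - Ps) * grow;     /* GSC differentiation flux */

    ydot[0] = (2.0 * Ps - 1.0) * grow - P_DS * s;
    ydot[1] = r[0] * diff - mi * v[0] * crowd - di * v[0];
    for (i = 2; i <= n - 1; i++)
        ydot[i] = r[i - 1] * diff
                + 2.0 * mi * v[i - 2] * crowd
                - mi * v[i - 1] * crowd
                - di * v[i - 1];
    ydot[n] = r[n - 1] * diff + 2.0 * mi * v[n - 2] * crowd - dn * v[n - 1];

    if (P_HOLDB >= 0.5) {
        ydot[n + 1] = 0.0;
        ydot[n + 2] = 0.0;
    } else {
        ydot[n + 1] = P_CREL * m - P_UB * B * s - P_DB * B;
        ydot[n + 2] = P_INF - P_DM * m;
    }
}
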