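/* Right-hand side of the logic ODE system.
 *
 * Every non-stimulus node x follows dx/dt = tau_x * (Phi_x(inputs) - x).
 * Each incoming plain edge or AND gate contributes one OR group; a group's
 * value is the product of its members' transfers, and groups combine as
 * OR: Phi = 1 - prod_g (1 - group_g).  The activating transfer is the
 * normalised Hill function f(u) = u^n (1 + k^n) / (u^n + k^n) (f(0) = 0,
 * f(1) = 1); an inhibiting member contributes 1 - f(u).
 *
 * The network structure is passed as a flat integer vector and the
 * parameters (tau, per-member n and k, stimulus clamp values) as a flat
 * double vector, so one compiled routine serves every model.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>
#include <string.h>

static double hill_transfer(double u, double n, double k)
{
    double un, kn;
    if (u < 0.0) u = 0.0;
    if (u == 0.0) return 0.0;
    un = pow(u, n);
    kn = pow(k, n);
    return un * (1.0 + kn) / (un + kn);
}

/* Static model buffers for the direct deSolve entry point: the R side
 * stores the current structure/parameters once per integration via
 * costim_set_model(), and the integrator calls costim_derivs() without
 * any per-step R callback. */
static int *g_sint = NULL;
static int g_sint_len = 0;
static double *g_par = NULL;
static int g_par_len = 0;

SEXP costim_set_model(SEXP sint_, SEXP par_)
{
    int ns = LENGTH(sint_), np = LENGTH(par_);
    if (ns > g_sint_len) {
        g_sint = (int *) R_Realloc(g_sint, ns, int);
        g_sint_len = ns;
    }
    if (np > g_par_len) {
        g_par = (double *) R_Realloc(g_par, np, double);
        g_par_len = np;
    }
    memcpy(g_sint, INTEGER(sint_), ns * sizeof(int));
    memcpy(g_par, REAL(par_), np * sizeof(double));
    return R_NilValue;
}

static void rhs_core(const int *s, const double *par, const double *y,
                     double *dy)
{
    const int n_states = s[0];
    const int n_groups = s[2], n_members = s[3];
    const int *gcount = s + 4;
    const int *mcount = gcount + n_states;
    const int *msrc = mcount + n_groups;
    const int *msign = msrc + n_members;
    const double *tau = par;
    const double *hn = par + n_states;
    const double *hk = hn + n_members;
    const double *stim = hk + n_members;

    int g = 0, m = 0;
    for (int i = 0; i < n_states; i++) {
        if (gcount[i] == 0) {
            dy[i] = 0.0;
            continue;
        }
        double not_or = 1.0;
        for (int gi = 0; gi < gcount[i]; gi++, g++) {
            double grp = 1.0;
            for (int mi = 0; mi < mcount[g]; mi++, m++) {
                int src = msrc[m];
                double u = src > 0 ? y[src - 1] : stim[-src - 1];
                double f = hill_transfer(u, hn[m], hk[m]);
                grp *= msign[m] > 0 ? f : 1.0 - f;
            }
            not_or *= 1.0 - grp;
        }
        dy[i] = tau[i] * ((1.0 - not_or) - y[i]);
    }
}

/* deSolve native derivative entry point (model set via costim_set_model) */
void costim_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    rhs_core(g_sint, g_par, y, ydot);
}

/* layout of sint:
 *   [0] n_states  [1] n_stim  [2] n_groups  [3] n_members
 *   [4 .. 4+n_states)              groups per state
 *   [.. + n_groups)                members per group
 *   [.. + n_members)               member source (1-based state index,
 *                                  or -j for stimulus j)
 *   [.. + n_members)               member sign (+1 / -1)
 * layout of par: tau[n_states], n[n_members], k[n_members], stim[n_stim]
 */
SEXP costim_logic_rhs(SEXP y_, SEXP sint_, SEXP par_)
{
    const int n_states = INTEGER(sint_)[0];
    SEXP dy_ = PROTECT(allocVector(REALSXP, n_states));
    rhs_core(INTEGER(sint_), REAL(par_), REAL(y_), REAL(dy_));
    UNPROTECT(1);
    return dy_;
}
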