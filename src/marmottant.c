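#include <R.h>
#include <math.h>

/* Marmottant radial dynamics: modified Rayleigh-Plesset equation for a
 * lipid-shelled microbubble with piecewise surface tension (buckled /
 * elastic / ruptured), shell surface viscosity and first-order acoustic
 * radiation damping.  Compiled right-hand side for deSolve::lsodar.
 *
 * Parameter slots (filled by marm_init via deSolve's initfunc):
 *  0  R0     resting radius                      [m]
 *  1  poly   polytropic exponent of the gas      [-]
 *  2  Pv     vapor pressure                      [Pa]
 *  3  rho    medium density                      [kg/m^3]
 *  4  mu     medium dynamic viscosity            [Pa s]
 *  5  cs     medium sound speed                  [m/s]
 *  6  P0     ambient pressure                    [Pa]
 *  7  sigw   surface tension of clean interface  [N/m]
 *  8  chi    shell elastic modulus               [N/m]
 *  9  ks     shell surface viscosity             [kg/s]
 * 10  Rb     buckling radius                     [m]
 * 11  Rr     rupture radius                      [m]
 * 12  pnp    peak negative pressure of the drive [Pa]
 * 13  freq   drive center frequency              [Hz]
 * 14  ncyc   number of drive cycles              [-]
 * 15  ramp   ramp length in cycles (0 = rectangular envelope)
 * 16  floor  collapse floor as fraction of R0    [-]
 */
static double mp[17];

void marm_init(void (*odeparms)(int *, double *))
{
    int n = 17;
    odeparms(&n, mp);
}

static double sigma_R(double R)
{
    double Rb = mp[10], Rr = mp[11];
    if (R <= Rb)
        return 0.0;
    if (R < Rr) {
        double x = R / Rb;
        return mp[8] * (x * x - 1.0);
    }
    return mp[7];
}

static double p_drive(double t)
{
    double f = mp[13], ncyc = mp[14], ramp = mp[15];
    double a;
    if (t < 0.0 || t >= ncyc / f)
        return 0.0;
    a = mp[12];
    if (ramp > 0.0) {
        double tc = t * f;
        if (tc < ramp)
            a *= tc / ramp;
    }
    /* rarefaction-first convention: negative half-cycle first */
    return -a * sin(2.0 * M_PI * f * t);
}

void marm_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double R = y[0], Rd = y[1];
    double R0 = mp[0], poly = mp[1], Pv = mp[2], rho = mp[3],
           mu = mp[4], cs = mp[5], P0 = mp[6], ks = mp[9];
    double Pg0, Pg, pbal;

    /* equilibrium gas partial pressure from mechanical balance at R0 */
    Pg0 = P0 + 2.0 * sigma_R(R0) / R0 - Pv;
    Pg = Pg0 * pow(R0 / R, 3.0 * poly);

    pbal = Pg * (1.0 - 3.0 * poly * Rd / cs) + Pv
        - 2.0 * sigma_R(R) / R
        - 4.0 * mu * Rd / R
        - 4.0 * ks * Rd / (R * R)
        - P0 - p_drive(*t);

    ydot[0] = Rd;
    ydot[1] = (pbal / rho - 1.5 * Rd * Rd) / R;
}

/* terminal event: radius reaches the collapse floor */
void marm_root(int *neq, double *t, double *y, int *ng, double *gout,
               double *out, int *ip)
{
    gout[0] = y[0] - mp[16] * mp[0];
}
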