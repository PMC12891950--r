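/* Luo-Rudy 1991 guinea-pig ventricular action potential model.
 *
 * Eight states: V, m, h, j, d, f, X, Cai.  Units: mV, ms, mM, uA/uF.
 * Ischemia hooks: extracellular K+ (Ko) enters every K+ reversal
 * potential; acidosis scales gNa and gsi multiplicatively; an
 * ATP-sensitive K+ current GKATP*(Ko/5.4)^n*(V-EK) is added to the
 * total membrane current.
 *
 * Parameter vector (shared with R side, see lr91_params()):
 *   p[0] Ko (mM)        p[1] sNa scale      p[2] sCa scale
 *   p[3] GKATP (mS/uF)  p[4] KATP Ko-exponent
 *   p[5] Istim (uA/uF)  p[6] Ki (mM)        p[7] gNa (mS/uF)
 *   p[8] gsi (mS/uF)
 */
#include <R.h>
#include <math.h>

#define LR91_NPAR 9
static double lr91_p[LR91_NPAR];

void lr91_initparms(void (*odeparms)(int *, double *))
{
    int n = LR91_NPAR;
    odeparms(&n, lr91_p);
}

/* RT/F at 310 K, mV */
static const double RTF = 8314.472 * 310.0 / 96485.3415;

void lr91_rhs(double t, const double *y, double *dy, const double *p)
{
    const double Ko = p[0], sNa = p[1], sCa = p[2], gkatp = p[3],
                 katp_exp = p[4], Istim = p[5], Ki = p[6];
    const double gNa = p[7] * sNa, gsi = p[8] * sCa;
    const double Nao = 140.0, Nai = 18.0, PRNaK = 0.01833;

    const double V = y[0], m = y[1], h = y[2], j = y[3],
                 d = y[4], f = y[5], X = y[6], Cai = y[7];

    /* --- fast sodium current --- */
    const double ENa = RTF * log(Nao / Nai);
    const double INa = gNa * m * m * m * h * j * (V - ENa);

    double am;
    if (fabs(V + 47.13) < 1e-9)
        am = 3.2; /* limit of 0.32 x /(1-exp(-0.1 x)) at x -> 0 */
    else
        am = 0.32 * (V + 47.13) / (1.0 - exp(-0.1 * (V + 47.13)));
    const double bm = 0.08 * exp(-V / 11.0);

    double ah, bh, aj, bj;
    if (V < -40.0) {
        ah = 0.135 * exp((80.0 + V) / -6.8);
        bh = 3.56 * exp(0.079 * V) + 3.1e5 * exp(0.35 * V);
        aj = (-1.2714e5 * exp(0.2444 * V) - 3.474e-5 * exp(-0.04391 * V)) *
             (V + 37.78) / (1.0 + exp(0.311 * (V + 79.23)));
        bj = 0.1212 * exp(-0.01052 * V) / (1.0 + exp(-0.1378 * (V + 40.14)));
    } else {
        ah = 0.0;
        bh = 1.0 / (0.13 * (1.0 + exp((V + 10.66) / -11.1)));
        aj = 0.0;
        bj = 0.3 * exp(-2.535e-7 * V) / (1.0 + exp(-0.1 * (V + 32.0)));
    }

    /* --- slow inward (L-type-like) calcium current --- */
    const double Esi = 7.7 - 13.0287 * log(Cai);
    const double Isi = gsi * d * f * (V - Esi);
    const double ad = 0.095 * exp(-0.01 * (V - 5.0)) /
                      (1.0 + exp(-0.072 * (V - 5.0)));
    const double bd = 0.07 * exp(-0.017 * (V + 44.0)) /
                      (1.0 + exp(0.05 * (V + 44.0)));
    const double af = 0.012 * exp(-0.008 * (V + 28.0)) /
                      (1.0 + exp(0.15 * (V + 28.0)));
    const double bf = 0.0065 * exp(-0.02 * (V + 30.0)) /
                      (1.0 + exp(-0.2 * (V + 30.0)));

    /* --- time-dependent potassium current --- */
    const double EK = RTF * log((Ko + PRNaK * Nao) / (Ki + PRNaK * Nai));
    const double GK = 0.282 * sqrt(Ko / 5.4);
    double Xi;
    if (V > -100.0) {
        if (fabs(V + 77.0) < 1e-9)
            Xi = 2.837 * 0.04 / exp(0.04 * (V + 35.0));
        else
            Xi = 2.837 * expm1(0.04 * (V + 77.0)) /
                 ((V + 77.0) * exp(0.04 * (V + 35.0)));
    } else {
        Xi = 1.0;
    }
    const double IK = GK * X * Xi * (V - EK);
    const double aX = 0.0005 * exp(0.083 * (V + 50.0)) /
                      (1.0 + exp(0.057 * (V + 50.0)));
    const double bX = 0.0013 * exp(-0.06 * (V + 20.0)) /
                      (1.0 + exp(-0.04 * (V + 20.0)));

    /* --- time-independent potassium current --- */
    const double EK1 = RTF * log(Ko / Ki);
    const double GK1 = 0.6047 * sqrt(Ko / 5.4);
    const double aK1 = 1.02 / (1.0 + exp(0.2385 * (V - EK1 - 59.215)));
    const double bK1 = (0.49124 * exp(0.08032 * (V - EK1 + 5.476)) +
                        exp(0.06175 * (V - EK1 - 594.31))) /
                       (1.0 + exp(-0.5143 * (V - EK1 + 4.753)));
    const double IK1 = GK1 * (aK1 / (aK1 + bK1)) * (V - EK1);

    /* --- plateau potassium and background currents --- */
    const double Kp = 1.0 / (1.0 + exp((7.488 - V) / 5.98));
    const double IKp = 0.0183 * Kp * (V - EK1);
    const double Ib = 0.03921 * (V + 59.87);

    /* --- ATP-sensitive potassium current (ischemia) --- */
    const double IKatp = gkatp * pow(Ko / 5.4, katp_exp) * (V - EK1);

    dy[0] = -(INa + Isi + IK + IK1 + IKp + Ib + IKatp + Istim);
    dy[1] = am * (1.0 - m) - bm * m;
    dy[2] = ah * (1.0 - h) - bh * h;
    dy[3] = aj * (1.0 - j) - bj * j;
    dy[4] = ad * (1.0 - d) - bd * d;
    dy[5] = af * (1.0 - f) - bf * f;
    dy[6] = aX * (1.0 - X) - bX * X;
    dy[7] = -1e-4 * Isi + 0.07 * (1e-4 - Cai);
    (void)t;
}

/* deSolve entry point */
void lr91_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    lr91_rhs(*t, y, ydot, lr91_p);
    (void)neq; (void)yout; (void)ip;
}
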