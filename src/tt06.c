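/* ten Tusscher-Panfilov 2006 human ventricular model, epicardial
 * parameter set.
 *
 * Nineteen states, ordered as on the R side (see tt06_state_names()):
 *   0 V    1 Ki    2 Nai   3 Cai   4 CaSS  5 CaSR  6 Rbar
 *   7 xr1  8 xr2   9 xs   10 m    11 h    12 j    13 d
 *  14 f   15 f2   16 fCass 17 s   18 r
 * Units: mV, ms, mM, pA/pF (numerically identical to uA/uF).
 *
 * Ischemia hooks mirror the LR91 file: Ko substitution, acidosis
 * scaling of gNa and gCaL, added IK(ATP) assigned to the K+ flux in
 * the Ki balance (the model's convention for the stimulus, applied to
 * IK(ATP) too, keeps intracellular K+ from drifting).
 *
 * Parameter vector:
 *   p[0] Ko   p[1] sNa   p[2] sCa   p[3] GKATP  p[4] KATP Ko-exponent
 *   p[5] Istim (pA/pF)   p[6] gNa   p[7] gCaL
 */
#include <R.h>
#include <math.h>

#define TT06_NPAR 8
static double tt06_p[TT06_NPAR];

void tt06_initparms(void (*odeparms)(int *, double *))
{
    int n = TT06_NPAR;
    odeparms(&n, tt06_p);
}

static const double Rgas = 8314.472, Temp = 310.0, Far = 96485.3415;

void tt06_rhs(double t, const double *y, double *dy, const double *p)
{
    const double Ko = p[0], gkatp = p[3], katp_exp = p[4], Istim = p[5];
    const double GNa = p[6] * p[1];      /* acidosis-scaled */
    const double GCaL = p[7] * p[2];

    /* fixed epicardial parameters */
    const double Nao = 140.0, Cao = 2.0;
    const double Cm = 0.185, V_C = 0.016404, V_SR = 0.001094,
                 V_SS = 0.00005468;
    const double GK1 = 5.405, Gto = 0.294, GKr = 0.153, GKs = 0.392;
    const double GbNa = 0.00029, GbCa = 0.000592, GpCa = 0.1238,
                 KpCa = 0.0005, GpK = 0.0146;
    const double PNaK = 2.724, KmK = 1.0, KmNa = 40.0;
    const double kNaCa = 1000.0, gam = 0.35, KmNai = 87.5, KmCa = 1.38,
                 ksat = 0.1, alp = 2.5;
    const double pKNa = 0.03;
    const double Vmaxup = 0.006375, Kup = 0.00025, Vrel = 0.102,
                 Vleak = 0.00036, Vxfer = 0.0038;
    const double k1p = 0.15, k2p = 0.045, k3 = 0.060, k4 = 0.005,
                 EC = 1.5, maxsr = 2.5, minsr = 1.0;
    const double Bufc = 0.2, Kbufc = 0.001, BufSR = 10.0, KbufSR = 0.3,
                 BufSS = 0.4, KbufSS = 0.00025;

    const double V = y[0], Ki = y[1], Nai = y[2], Cai = y[3],
                 CaSS = y[4], CaSR = y[5], Rbar = y[6],
                 xr1 = y[7], xr2 = y[8], xs = y[9],
                 m = y[10], h = y[11], j = y[12], d = y[13],
                 f = y[14], f2 = y[15], fCass = y[16],
                 s = y[17], r = y[18];

    const double RTF = Rgas * Temp / Far;
    const double EK = RTF * log(Ko / Ki);
    const double ENa = RTF * log(Nao / Nai);
    const double EKs = RTF * log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
    const double ECa = 0.5 * RTF * log(Cao / Cai);

    /* fast sodium */
    const double INa = GNa * m * m * m * h * j * (V - ENa);
    const double minf = 1.0 / pow(1.0 + exp((-56.86 - V) / 9.03), 2.0);
    const double am = 1.0 / (1.0 + exp((-60.0 - V) / 5.0));
    const double bm = 0.1 / (1.0 + exp((V + 35.0) / 5.0)) +
                      0.1 / (1.0 + exp((V - 50.0) / 200.0));
    const double taum = am * bm;
    const double hinf = 1.0 / pow(1.0 + exp((V + 71.55) / 7.43), 2.0);
    double ah, bh, aj, bj;
    if (V < -40.0) {
        ah = 0.057 * exp(-(V + 80.0) / 6.8);
        bh = 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V);
        aj = ((-2.5428e4 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
              (V + 37.78)) / (1.0 + exp(0.311 * (V + 79.23)));
        bj = 0.02424 * exp(-0.01052 * V) /
             (1.0 + exp(-0.1378 * (V + 40.14)));
    } else {
        ah = 0.0;
        bh = 0.77 / (0.13 * (1.0 + exp(-(V + 10.66) / 11.1)));
        aj = 0.0;
        bj = 0.6 * exp(0.057 * V) / (1.0 + exp(-0.1 * (V + 32.0)));
    }
    const double tauh = 1.0 / (ah + bh);
    const double jinf = hinf;
    const double tauj = 1.0 / (aj + bj);

    /* L-type calcium, with the V = 15 mV removable singularity */
    const double u = 2.0 * (V - 15.0) * Far / (Rgas * Temp);
    double uratio; /* u / (exp(u) - 1) */
    if (fabs(u) < 1e-7)
        uratio = 1.0 - 0.5 * u;
    else
        uratio = u / expm1(u);
    const double ICaL = GCaL * d * f * f2 * fCass * 2.0 * Far *
                        (0.25 * CaSS * exp(u) - Cao) * uratio;
    const double dinf = 1.0 / (1.0 + exp((-8.0 - V) / 7.5));
    const double ad = 1.4 / (1.0 + exp((-35.0 - V) / 13.0)) + 0.25;
    const double bd = 1.4 / (1.0 + exp((V + 5.0) / 5.0));
    const double gd = 1.0 / (1.0 + exp((50.0 - V) / 20.0));
    const double taud = ad * bd + gd;
    const double finf = 1.0 / (1.0 + exp((V + 20.0) / 7.0));
    const double tauf = 1102.5 * exp(-pow(V + 27.0, 2.0) / 225.0) +
                        200.0 / (1.0 + exp((13.0 - V) / 10.0)) +
                        180.0 / (1.0 + exp((V + 30.0) / 10.0)) + 20.0;
    const double f2inf = 0.67 / (1.0 + exp((V + 35.0) / 7.0)) + 0.33;
    const double tauf2 = 562.0 * exp(-pow(V + 27.0, 2.0) / 240.0) +
                         31.0 / (1.0 + exp((25.0 - V) / 10.0)) +
                         80.0 / (1.0 + exp((V + 30.0) / 10.0));
    const double fCassinf = 0.6 / (1.0 + pow(CaSS / 0.05, 2.0)) + 0.4;
    const double taufCass = 80.0 / (1.0 + pow(CaSS / 0.05, 2.0)) + 2.0;

    /* transient outward (epicardial gating) */
    const double Ito = Gto * r * s * (V - EK);
    const double sinf = 1.0 / (1.0 + exp((V + 20.0) / 5.0));
    const double taus = 85.0 * exp(-pow(V + 45.0, 2.0) / 320.0) +
                        5.0 / (1.0 + exp((V - 20.0) / 5.0)) + 3.0;
    const double rinf = 1.0 / (1.0 + exp((20.0 - V) / 6.0));
    const double taur = 9.5 * exp(-pow(V + 40.0, 2.0) / 1800.0) + 0.8;

    /* delayed rectifiers */
    const double IKr = GKr * sqrt(Ko / 5.4) * xr1 * xr2 * (V - EK);
    const double xr1inf = 1.0 / (1.0 + exp((-26.0 - V) / 7.0));
    const double axr1 = 450.0 / (1.0 + exp((-45.0 - V) / 10.0));
    const double bxr1 = 6.0 / (1.0 + exp((V + 30.0) / 11.5));
    const double tauxr1 = axr1 * bxr1;
    const double xr2inf = 1.0 / (1.0 + exp((V + 88.0) / 24.0));
    const double axr2 = 3.0 / (1.0 + exp((-60.0 - V) / 20.0));
    const double bxr2 = 1.12 / (1.0 + exp((V - 60.0) / 20.0));
    const double tauxr2 = axr2 * bxr2;

    const double IKs = GKs * xs * xs * (V - EKs);
    const double xsinf = 1.0 / (1.0 + exp((-5.0 - V) / 14.0));
    const double axs = 1400.0 / sqrt(1.0 + exp((5.0 - V) / 6.0));
    const double bxs = 1.0 / (1.0 + exp((V - 35.0) / 15.0));
    const double tauxs = axs * bxs + 80.0;

    /* inward rectifier */
    const double aK1 = 0.1 / (1.0 + exp(0.06 * (V - EK - 200.0)));
    const double bK1 = (3.0 * exp(0.0002 * (V - EK + 100.0)) +
                        exp(0.1 * (V - EK - 10.0))) /
                       (1.0 + exp(-0.5 * (V - EK)));
    const double IK1 = GK1 * sqrt(Ko / 5.4) * (aK1 / (aK1 + bK1)) * (V - EK);

    /* pumps, exchanger, background */
    const double INaCa = kNaCa *
        (exp(gam * V * Far / (Rgas * Temp)) * Nai * Nai * Nai * Cao -
         exp((gam - 1.0) * V * Far / (Rgas * Temp)) * Nao * Nao * Nao *
         Cai * alp) /
        ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
         (1.0 + ksat * exp((gam - 1.0) * V * Far / (Rgas * Temp))));
    const double INaK = PNaK * Ko * Nai /
        ((Ko + KmK) * (Nai + KmNa) *
         (1.0 + 0.1245 * exp(-0.1 * V * Far / (Rgas * Temp)) +
          0.0353 * exp(-V * Far / (Rgas * Temp))));
    const double IpCa = GpCa * Cai / (Cai + KpCa);
    const double IpK = GpK * (V - EK) / (1.0 + exp((25.0 - V) / 5.98));
    const double IbNa = GbNa * (V - ENa);
    const double IbCa = GbCa * (V - ECa);

    /* ATP-sensitive potassium current (ischemia) */
    const double IKatp = gkatp * pow(Ko / 5.4, katp_exp) * (V - EK);

    /* calcium handling */
    const double kCaSR = maxsr - (maxsr - minsr) /
                         (1.0 + pow(EC / CaSR, 2.0));
    const double k1 = k1p / kCaSR;
    const double k2 = k2p * kCaSR;
    const double O = k1 * CaSS * CaSS * Rbar / (k3 + k1 * CaSS * CaSS);
    const double Irel = Vrel * O * (CaSR - CaSS);
    const double Ileak = Vleak * (CaSR - Cai);
    const double Iup = Vmaxup / (1.0 + pow(Kup / Cai, 2.0));
    const double Ixfer = Vxfer * (CaSS - Cai);

    const double bufc = 1.0 / (1.0 + Bufc * Kbufc / pow(Cai + Kbufc, 2.0));
    const double bufsr = 1.0 / (1.0 + BufSR * KbufSR /
                                pow(CaSR + KbufSR, 2.0));
    const double bufss = 1.0 / (1.0 + BufSS * KbufSS /
                                pow(CaSS + KbufSS, 2.0));

    const double Iion = INa + ICaL + Ito + IKr + IKs + IK1 + INaCa + INaK +
                        IpCa + IpK + IbNa + IbCa + IKatp;

    dy[0] = -(Iion + Istim);
    dy[1] = -(IK1 + Ito + IKr + IKs + IpK + IKatp + Istim - 2.0 * INaK) *
            Cm / (V_C * Far);
    dy[2] = -(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * Cm / (V_C * Far);
    dy[3] = bufc * ((Ileak - Iup) * V_SR / V_C + Ixfer -
                    (IbCa + IpCa - 2.0 * INaCa) * Cm / (2.0 * V_C * Far));
    dy[4] = bufss * (-Ixfer * V_C / V_SS + Irel * V_SR / V_SS -
                     ICaL * Cm / (2.0 * V_SS * Far));
    dy[5] = bufsr * (Iup - Irel - Ileak);
    dy[6] = -k2 * CaSS * Rbar + k4 * (1.0 - Rbar);
    dy[7] = (xr1inf - xr1) / tauxr1;
    dy[8] = (xr2inf - xr2) / tauxr2;
    dy[9] = (xsinf - xs) / tauxs;
    dy[10] = (minf - m) / taum;
    dy[11] = (hinf - h) / tauh;
    dy[12] = (jinf - j) / tauj;
    dy[13] = (dinf - d) / taud;
    dy[14] = (finf - f) / tauf;
    dy[15] = (f2inf - f2) / tauf2;
    dy[16] = (fCassinf - fCass) / taufCass;
    dy[17] = (sinf - s) / taus;
    dy[18] = (rinf - r) / taur;
    (void)t;
}

void tt06_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    tt06_rhs(*t, y, ydot, tt06_p);
    (void)neq; (void)yout; (void)ip;
}
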