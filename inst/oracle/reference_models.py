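"""Independent reference integration of the two ventricular myocyte models.

A from-scratch scipy implementation of the Luo-Rudy 1991 and ten Tusscher
2006 (epicardial) models, written directly from their published
formulations and kept deliberately separate from the R package's compiled
kernels.  Used once to compute the frozen baseline values asserted by the
package's fidelity tests (resting potential, APD90, and the derivative
vector at the published resting state).

Run:  python reference_models.py            -> JSON on stdout
"""
import json
import math

import numpy as np
from scipy.integrate import solve_ivp

RTF = 8314.472 * 310.0 / 96485.3415


# ----------------------------------------------------------------- LR91 ---
def lr91_rhs(t, y, ko=5.4, istim=0.0):
    v, m, h, j, d, f, x, cai = y
    ki, nao, nai = 145.0, 140.0, 18.0

    ena = RTF * math.log(nao / nai)
    ina = 23.0 * m ** 3 * h * j * (v - ena)
    xm = v + 47.13
    am = 3.2 if abs(xm) < 1e-9 else 0.32 * xm / (1.0 - math.exp(-0.1 * xm))
    bm = 0.08 * math.exp(-v / 11.0)
    if v < -40.0:
        ah = 0.135 * math.exp((80.0 + v) / -6.8)
        bh = 3.56 * math.exp(0.079 * v) + 3.1e5 * math.exp(0.35 * v)
        aj = ((-1.2714e5 * math.exp(0.2444 * v)
               - 3.474e-5 * math.exp(-0.04391 * v)) * (v + 37.78)
              / (1.0 + math.exp(0.311 * (v + 79.23))))
        bj = (0.1212 * math.exp(-0.01052 * v)
              / (1.0 + math.exp(-0.1378 * (v + 40.14))))
    else:
        ah = 0.0
        bh = 1.0 / (0.13 * (1.0 + math.exp((v + 10.66) / -11.1)))
        aj = 0.0
        bj = (0.3 * math.exp(-2.535e-7 * v)
              / (1.0 + math.exp(-0.1 * (v + 32.0))))

    esi = 7.7 - 13.0287 * math.log(cai)
    isi = 0.09 * d * f * (v - esi)
    ad = (0.095 * math.exp(-0.01 * (v - 5.0))
          / (1.0 + math.exp(-0.072 * (v - 5.0))))
    bd = (0.07 * math.exp(-0.017 * (v + 44.0))
          / (1.0 + math.exp(0.05 * (v + 44.0))))
    af = (0.012 * math.exp(-0.008 * (v + 28.0))
          / (1.0 + math.exp(0.15 * (v + 28.0))))
    bf = (0.0065 * math.exp(-0.02 * (v + 30.0))
          / (1.0 + math.exp(-0.2 * (v + 30.0))))

    ek = RTF * math.log((ko + 0.01833 * nao) / (ki + 0.01833 * nai))
    gk = 0.282 * math.sqrt(ko / 5.4)
    if v > -100.0:
        if abs(v + 77.0) < 1e-9:
            xi = 2.837 * 0.04 / math.exp(0.04 * (v + 35.0))
        else:
            xi = (2.837 * (math.exp(0.04 * (v + 77.0)) - 1.0)
                  / ((v + 77.0) * math.exp(0.04 * (v + 35.0))))
    else:
        xi = 1.0
    ik = gk * x * xi * (v - ek)
    ax = (0.0005 * math.exp(0.083 * (v + 50.0))
          / (1.0 + math.exp(0.057 * (v + 50.0))))
    bx = (0.0013 * math.exp(-0.06 * (v + 20.0))
          / (1.0 + math.exp(-0.04 * (v + 20.0))))

    ek1 = RTF * math.log(ko / ki)
    gk1 = 0.6047 * math.sqrt(ko / 5.4)
    ak1 = 1.02 / (1.0 + math.exp(0.2385 * (v - ek1 - 59.215)))
    bk1 = ((0.49124 * math.exp(0.08032 * (v - ek1 + 5.476))
            + math.exp(0.06175 * (v - ek1 - 594.31)))
           / (1.0 + math.exp(-0.5143 * (v - ek1 + 4.753))))
    ik1 = gk1 * ak1 / (ak1 + bk1) * (v - ek1)

    ikp = 0.0183 * (v - ek1) / (1.0 + math.exp((7.488 - v) / 5.98))
    ib = 0.03921 * (v + 59.87)

    return [
        -(ina + isi + ik + ik1 + ikp + ib + istim),
        am * (1 - m) - bm * m,
        ah * (1 - h) - bh * h,
        aj * (1 - j) - bj * j,
        ad * (1 - d) - bd * d,
        af * (1 - f) - bf * f,
        ax * (1 - x) - bx * x,
        -1e-4 * isi + 0.07 * (1e-4 - cai),
    ]


LR91_Y0 = [-84.3801107371, 0.00171338077730188, 0.982660523699656,
           0.989108212766685, 0.00302126301779861, 0.999967936476325,
           0.0417603108167287, 0.00017948816388306]


# ----------------------------------------------------------------- TT06 ---
def tt06_rhs(t, y, ko=5.4, istim=0.0):
    (v, ki, nai, cai, cass, casr, rbar, xr1, xr2, xs,
     m, h, j, d, f, f2, fcass, s, r) = y
    nao, cao = 140.0, 2.0
    cm, vc, vsr, vss = 0.185, 0.016404, 0.001094, 0.00005468
    F, R, T = 96485.3415, 8314.472, 310.0
    rtf = R * T / F

    ek = rtf * math.log(ko / ki)
    ena = rtf * math.log(nao / nai)
    eks = rtf * math.log((ko + 0.03 * nao) / (ki + 0.03 * nai))
    eca = 0.5 * rtf * math.log(cao / cai)

    ina = 14.838 * m ** 3 * h * j * (v - ena)
    minf = 1.0 / (1.0 + math.exp((-56.86 - v) / 9.03)) ** 2
    taum = (1.0 / (1.0 + math.exp((-60.0 - v) / 5.0))) * (
        0.1 / (1.0 + math.exp((v + 35.0) / 5.0))
        + 0.1 / (1.0 + math.exp((v - 50.0) / 200.0)))
    hinf = 1.0 / (1.0 + math.exp((v + 71.55) / 7.43)) ** 2
    if v < -40.0:
        ah = 0.057 * math.exp(-(v + 80.0) / 6.8)
        bh = 2.7 * math.exp(0.079 * v) + 3.1e5 * math.exp(0.3485 * v)
        aj = ((-2.5428e4 * math.exp(0.2444 * v)
               - 6.948e-6 * math.exp(-0.04391 * v)) * (v + 37.78)
              / (1.0 + math.exp(0.311 * (v + 79.23))))
        bj = (0.02424 * math.exp(-0.01052 * v)
              / (1.0 + math.exp(-0.1378 * (v + 40.14))))
    else:
        ah, aj = 0.0, 0.0
        bh = 0.77 / (0.13 * (1.0 + math.exp(-(v + 10.66) / 11.1)))
        bj = 0.6 * math.exp(0.057 * v) / (1.0 + math.exp(-0.1 * (v + 32.0)))
    tauh, tauj, jinf = 1.0 / (ah + bh), 1.0 / (aj + bj), hinf

    u = 2.0 * (v - 15.0) * F / (R * T)
    ur = 1.0 - 0.5 * u if abs(u) < 1e-7 else u / math.expm1(u)
    ical = (3.98e-5 * d * f * f2 * fcass * 2.0 * F
            * (0.25 * cass * math.exp(u) - cao) * ur)
    dinf = 1.0 / (1.0 + math.exp((-8.0 - v) / 7.5))
    taud = ((1.4 / (1.0 + math.exp((-35.0 - v) / 13.0)) + 0.25)
            * (1.4 / (1.0 + math.exp((v + 5.0) / 5.0)))
            + 1.0 / (1.0 + math.exp((50.0 - v) / 20.0)))
    finf = 1.0 / (1.0 + math.exp((v + 20.0) / 7.0))
    tauf = (1102.5 * math.exp(-(v + 27.0) ** 2 / 225.0)
            + 200.0 / (1.0 + math.exp((13.0 - v) / 10.0))
            + 180.0 / (1.0 + math.exp((v + 30.0) / 10.0)) + 20.0)
    f2inf = 0.67 / (1.0 + math.exp((v + 35.0) / 7.0)) + 0.33
    tauf2 = (562.0 * math.exp(-(v + 27.0) ** 2 / 240.0)
             + 31.0 / (1.0 + math.exp((25.0 - v) / 10.0))
             + 80.0 / (1.0 + math.exp((v + 30.0) / 10.0)))
    fcassinf = 0.6 / (1.0 + (cass / 0.05) ** 2) + 0.4
    taufcass = 80.0 / (1.0 + (cass / 0.05) ** 2) + 2.0

    ito = 0.294 * r * s * (v - ek)
    sinf = 1.0 / (1.0 + math.exp((v + 20.0) / 5.0))
    taus = (85.0 * math.exp(-(v + 45.0) ** 2 / 320.0)
            + 5.0 / (1.0 + math.exp((v - 20.0) / 5.0)) + 3.0)
    rinf = 1.0 / (1.0 + math.exp((20.0 - v) / 6.0))
    taur = 9.5 * math.exp(-(v + 40.0) ** 2 / 1800.0) + 0.8

    ikr = 0.153 * math.sqrt(ko / 5.4) * xr1 * xr2 * (v - ek)
    xr1inf = 1.0 / (1.0 + math.exp((-26.0 - v) / 7.0))
    tauxr1 = (450.0 / (1.0 + math.exp((-45.0 - v) / 10.0))
              * 6.0 / (1.0 + math.exp((v + 30.0) / 11.5)))
    xr2inf = 1.0 / (1.0 + math.exp((v + 88.0) / 24.0))
    tauxr2 = (3.0 / (1.0 + math.exp((-60.0 - v) / 20.0))
              * 1.12 / (1.0 + math.exp((v - 60.0) / 20.0)))

    iks = 0.392 * xs ** 2 * (v - eks)
    xsinf = 1.0 / (1.0 + math.exp((-5.0 - v) / 14.0))
    tauxs = (1400.0 / math.sqrt(1.0 + math.exp((5.0 - v) / 6.0))
             * 1.0 / (1.0 + math.exp((v - 35.0) / 15.0)) + 80.0)

    ak1 = 0.1 / (1.0 + math.exp(0.06 * (v - ek - 200.0)))
    bk1 = ((3.0 * math.exp(0.0002 * (v - ek + 100.0))
            + math.exp(0.1 * (v - ek - 10.0)))
           / (1.0 + math.exp(-0.5 * (v - ek))))
    ik1 = 5.405 * math.sqrt(ko / 5.4) * ak1 / (ak1 + bk1) * (v - ek)

    vfrt = v * F / (R * T)
    inaca = (1000.0 * (math.exp(0.35 * vfrt) * nai ** 3 * cao
                       - math.exp(-0.65 * vfrt) * nao ** 3 * cai * 2.5)
             / ((87.5 ** 3 + nao ** 3) * (1.38 + cao)
                * (1.0 + 0.1 * math.exp(-0.65 * vfrt))))
    inak = (2.724 * ko * nai
            / ((ko + 1.0) * (nai + 40.0)
               * (1.0 + 0.1245 * math.exp(-0.1 * vfrt)
                  + 0.0353 * math.exp(-vfrt))))
    ipca = 0.1238 * cai / (cai + 0.0005)
    ipk = 0.0146 * (v - ek) / (1.0 + math.exp((25.0 - v) / 5.98))
    ibna = 0.00029 * (v - ena)
    ibca = 0.000592 * (v - eca)

    kcasr = 2.5 - 1.5 / (1.0 + (1.5 / casr) ** 2)
    k1, k2 = 0.15 / kcasr, 0.045 * kcasr
    o = k1 * cass ** 2 * rbar / (0.06 + k1 * cass ** 2)
    irel = 0.102 * o * (casr - cass)
    ileak = 0.00036 * (casr - cai)
    iup = 0.006375 / (1.0 + (0.00025 / cai) ** 2)
    ixfer = 0.0038 * (cass - cai)

    bufc = 1.0 / (1.0 + 0.2 * 0.001 / (cai + 0.001) ** 2)
    bufsr = 1.0 / (1.0 + 10.0 * 0.3 / (casr + 0.3) ** 2)
    bufss = 1.0 / (1.0 + 0.4 * 0.00025 / (cass + 0.00025) ** 2)

    iion = (ina + ical + ito + ikr + iks + ik1 + inaca + inak + ipca + ipk
            + ibna + ibca)
    return [
        -(iion + istim),
        -(ik1 + ito + ikr + iks + ipk + istim - 2.0 * inak) * cm / (vc * F),
        -(ina + ibna + 3.0 * inak + 3.0 * inaca) * cm / (vc * F),
        bufc * ((ileak - iup) * vsr / vc + ixfer
                - (ibca + ipca - 2.0 * inaca) * cm / (2.0 * vc * F)),
        bufss * (-ixfer * vc / vss + irel * vsr / vss
                 - ical * cm / (2.0 * vss * F)),
        bufsr * (iup - irel - ileak),
        -k2 * cass * rbar + 0.005 * (1.0 - rbar),
        (xr1inf - xr1) / tauxr1,
        (xr2inf - xr2) / tauxr2,
        (xsinf - xs) / tauxs,
        (minf - m) / taum,
        (hinf - h) / tauh,
        (jinf - j) / tauj,
        (dinf - d) / taud,
        (finf - f) / tauf,
        (f2inf - f2) / tauf2,
        (fcassinf - fcass) / taufcass,
        (sinf - s) / taus,
        (rinf - r) / taur,
    ]


TT06_Y0 = [-85.23, 136.89, 8.604, 0.000126, 0.00036, 3.64, 0.9073,
           0.00621, 0.4712, 0.0095, 0.00172, 0.7444, 0.7045, 3.373e-5,
           0.7888, 0.9755, 0.9953, 0.999998, 2.42e-8]


# ------------------------------------------------------------- protocol ---
def pace(rhs, y0, ko=5.4, amp=-52.0, dur=1.0, bcl=1000.0, n_beats=10,
         delay=1.0, dt=0.05):
    """Pace n_beats; return (time, vm) of the last beat on a uniform grid."""
    y = np.array(y0, dtype=float)
    kw = dict(method="BDF", rtol=1e-6, atol=1e-6)
    for beat in range(n_beats):
        dense = beat == n_beats - 1
        tt, vv = [], []
        for (t0, t1, istim) in [(0.0, delay, 0.0),
                                (delay, delay + dur, amp),
                                (delay + dur, bcl, 0.0)]:
            tev = (np.linspace(t0, t1, round((t1 - t0) / dt) + 1)
                   if dense else [t0, t1])
            sol = solve_ivp(lambda t, yy: rhs(t, yy, ko, istim),
                            (t0, t1), y, t_eval=tev, **kw)
            y = sol.y[:, -1]
            if dense:
                tt.append(sol.t[:-1] if t1 < bcl else sol.t)
                vv.append(sol.y[0, :-1] if t1 < bcl else sol.y[0, :])
    return np.concatenate(tt), np.concatenate(vv)


def biomarkers(t, v, onset=1.0):
    pre = t < onset
    rmp = v[pre][-1]
    post = np.where(t >= onset)[0]
    pk = post[np.argmax(v[post])]
    peak = v[pk]
    apa = peak - rmp
    up = np.arange(post[0], max(post[0] + 1, pk))
    slopes = (v[up + 1] - v[up]) / (t[up + 1] - t[up])
    tact = t[up[np.argmax(slopes)]]

    def apd(x):
        thr = peak - x / 100.0 * apa
        for i in range(pk, len(v) - 1):
            if v[i] >= thr > v[i + 1]:
                tc = t[i] + (v[i] - thr) / (v[i] - v[i + 1]) * (t[i + 1] - t[i])
                return tc - tact
        return float("nan")

    return dict(rmp=rmp, peak=peak, apa=apa, dvdtmax=float(np.max(slopes)),
                apd90=apd(90), apd50=apd(50))


def quiescent_v(rhs, y0, ko=5.4, t_end=10000.0):
    sol = solve_ivp(lambda t, y: rhs(t, y, ko, 0.0), (0.0, t_end), y0,
                    method="BDF", rtol=1e-6, atol=1e-6)
    return float(sol.y[0, -1])


if __name__ == "__main__":
    out = {}
    out["lr91_deriv_at_rest"] = lr91_rhs(0.0, LR91_Y0)
    out["tt06_deriv_at_rest"] = tt06_rhs(0.0, TT06_Y0)
    out["lr91_quiescent_v"] = quiescent_v(lr91_rhs, LR91_Y0)
    out["lr91_quiescent_v_ko12.5"] = quiescent_v(lr91_rhs, LR91_Y0, ko=12.5)
    out["tt06_quiescent_v"] = quiescent_v(tt06_rhs, TT06_Y0)
    t, v = pace(lr91_rhs, LR91_Y0)
    out["lr91_baseline"] = biomarkers(t, v)
    t, v = pace(tt06_rhs, TT06_Y0)
    out["tt06_baseline"] = biomarkers(t, v)
    print(json.dumps(out, indent=1))
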