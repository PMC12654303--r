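"""Independent high-precision oracle for the test suite.

For every parameter set in tests/testthat/oracle-params.csv (emitted by the
package's seeded generator plus guard-branch variants) this script computes
reference values for the first-order coefficient functions and the
flux-difference terms, and writes tests/testthat/oracle-values.csv.

The first-order quantities are obtained by numerical quadrature of the
outer electroneutral system with the O(Q0) interior-layer jump conditions
(scratch-free reimplementation below) -- a route completely independent of
the closed forms the R package evaluates.  The zeroth-order difference
terms are direct transcriptions of the expanded flux formulas.

Run from the repository root:  python data-raw/derive-oracle.py
Requires mpmath (bundled with sympy).  Takes a few minutes.
"""
import csv
import mpmath as mp

mp.mp.dps = 30
FD_STEP = mp.mpf('1e-9')


def first_order_fluxes(z, z3, CL, CR, phiL, phiR, c1L, c1R, a, b):
    """J10, J30 and their O(Q0) corrections J11, J31 for the reduced
    (outer) system; see the methods vignette for the construction."""
    kap = CR - CL
    mu = (phiL - phiR)/mp.log(CR/CL)
    C0 = lambda x: CL + kap*x
    phi0 = lambda x: phiL - mu*mp.log(C0(x)/CL)
    dphi0 = lambda x: -mu*kap/C0(x)
    chi = lambda x: 1 if a < x < b else 0
    T1 = phi0(b) - phi0(a)
    cf = z3/(z - z3)
    jphi_a = 1/(z*(z - z3)*C0(a))
    jphi_b = -1/(z*(z - z3)*C0(b))
    jC_a = -1/(z - z3)

    def gamma(x):
        if x <= a:
            return cf*T1*x
        if x <= b:
            return cf*(T1*x - (phi0(x) - phi0(a))) + jC_a
        return cf*T1*(x - 1)

    def quad(f):
        return (mp.quad(f, [0, a]) + mp.quad(f, [a, b]) + mp.quad(f, [b, 1]))

    num = quad(lambda x: dphi0(x)*(z*(z - z3)*gamma(x) - z3*chi(x))/C0(x))
    den = quad(lambda x: 1/C0(x))
    K1 = (-num + z*(z - z3)*(jphi_a + jphi_b))/den

    def dphi1(x):
        return -(K1 + dphi0(x)*(z*(z - z3)*gamma(x) - z3*chi(x))) / \
            (z*(z - z3)*C0(x))

    # closed-form tail weight Om(x) = int_x^1 e^{zc phi0} dx' and the
    # integration-by-parts identity int w phi1 = int Om phi1' + jump terms
    def first_corr(zc):
        m = zc*mu
        pref = mp.e**(zc*phiL)*CL**m
        if abs(1 - m) < mp.mpf('1e-18'):
            Om = lambda x: pref*(mp.log(CR) - mp.log(C0(x)))/kap
        else:
            Om = lambda x: pref*(CR**(1 - m) - C0(x)**(1 - m)) / \
                (kap*(1 - m))
        W = Om(mp.mpf(0))
        I = quad(lambda x: Om(x)*dphi1(x))
        return (I + Om(a)*jphi_a + Om(b)*jphi_b)/W, W

    avg_z, Wz = first_corr(z)
    avg_z3, Wz3 = first_corr(z3)

    J10 = (c1L*mp.e**(z*phiL) - c1R*mp.e**(z*phiR))/Wz
    c3L = z*CL/(-z3)
    c3R = z*CR/(-z3)
    J30 = (c3L*mp.e**(z3*phiL) - c3R*mp.e**(z3*phiR))/Wz3
    return dict(J10=J10, J30=J30, J11=-J10*z*avg_z, J31=-J30*z3*avg_z3)


def limits(z, z3, L, R, L1, R1, sig, rho, V):
    e = z/(z - z3)
    return (L*sig**(-e), R*rho**(-e),
            V + mp.log(sig)/(z - z3), mp.log(rho)/(z - z3),
            L1*sig**(-e), R1*rho**(-e))


def coeff_functions(z, z3, t, a, b, L1, R1, R, V):
    """J110, J111(V), J310, J3dev(V) via deviation finite differences of
    the quadrature route at the neutral baseline (unit R-total scaling is
    not assumed; the cation prefactor carries R)."""
    L = t*R
    d = FD_STEP
    hi = first_order_fluxes(z, z3, *limits(z, z3, L, R, L1, R1, 1 + d,
                                           1 - d, V), a, b)
    lo = first_order_fluxes(z, z3, *limits(z, z3, L, R, L1, R1, 1 - d,
                                           1 + d, V), a, b)
    dJ1 = (hi['J11'] - lo['J11'])/(2*d)
    dJ3 = (hi['J31'] - lo['J31'])/(2*d)
    J11n = (hi['J11'] + lo['J11'])/2
    J31n = (hi['J31'] + lo['J31'])/2
    lt = mp.log(t)
    pref1 = (L1 - R1*mp.e**(-z*V))*(lt + z*V)/((z - z3)*R*(t - mp.e**(-z*V)))
    pref3 = -(lt + z3*V)/(z - z3)
    return dict(J110=J11n/pref1, J111=dJ1/(2*pref1),
                J310=J31n/pref3, J3dev=dJ3/2)


def zeroth_flux(z, z3, D, L123, R123, V, sig, rho):
    """corrected-sign expanded zeroth-order fluxes."""
    L1, L2, L3 = L123
    R1, R2, R3 = R123
    t = (L1 + L2)/(R1 + R2)
    s = L3/R3
    lt, ls = mp.log(t), mp.log(s)
    w = lt + z*V
    r = (1/t if w == 0 else w/(t - mp.e**(-z*V)))
    fb = lambda x, lx: ((x*lx - x + 1)*(sig - 1) + (x - 1 - lx)*(rho - 1))
    wt = (t - 1)/lt - z/(z - z3)*fb(t, lt)/lt**2
    ws = (s - 1)/ls - z3/(z - z3)*fb(s, ls)/ls**2
    return [D[0]*(L1 - R1*mp.e**(-z*V))*r*wt,
            D[1]*(L2 - R2*mp.e**(-z*V))*r*wt,
            D[2]*R3*(ls + z3*V)*ws]


def main():
    with open('tests/testthat/oracle-params.csv') as fh:
        rows = list(csv.DictReader(fh))
    out = []
    for r in rows:
        g = lambda k: mp.mpf(r[k])
        z, z3 = g('z'), g('z3')
        D = (g('D1'), g('D2'), g('D3'))
        L123 = (g('L1'), g('L2'), g('L3'))
        R123 = (g('R1'), g('R2'), g('R3'))
        V, sig, rho = g('V'), g('sigma'), g('rho')
        a, b = g('x1'), g('x2')
        t = g('t')
        Rtot = R123[0] + R123[1]

        co = coeff_functions(z, z3, t, a, b, L123[0], R123[0], Rtot, V)
        # Dbig/Fbig carriers from two-point evaluation of the affine J111
        co0 = coeff_functions(z, z3, t, a, b, L123[0], R123[0], Rtot,
                              mp.mpf(0))
        co1 = coeff_functions(z, z3, t, a, b, L123[0], R123[0], Rtot,
                              mp.mpf(1))
        A = co0['J111']
        B = co1['J111'] - A
        wa = t + a*(1 - t)
        wb = t + b*(1 - t)
        lt = mp.log(t)
        Dbig = B*(z - z3)*wa**2*wb**2*lt**4/(z*z3)
        Fbig = A*(z - z3)*wa**2*wb**2*lt**4/z3
        q0 = co0['J3dev']
        qm = coeff_functions(z, z3, t, a, b, L123[0], R123[0], Rtot,
                             mp.mpf(-1))['J3dev']
        qp = co1['J3dev']
        c1_ = (qp - qm)/2
        c2_ = (qp + qm)/2 - q0

        # flux differences
        J0_s = zeroth_flux(z, z3, D, L123, R123, V, sig, rho)
        L3n = z*(L123[0] + L123[1])/(-z3)
        R3n = z*Rtot/(-z3)
        J0_n = zeroth_flux(z, z3, D, (L123[0], L123[1], L3n),
                           (R123[0], R123[1], R3n), V, mp.mpf(1), mp.mpf(1))
        Jd0 = [x - y for x, y in zip(J0_s, J0_n)]
        dsr = sig - rho
        w_ = lt + z*V
        rr = (1/t if w_ == 0 else w_/(t - mp.e**(-z*V)))
        prefk = lambda Lk, Rk, Dk: Dk*(Lk - Rk*mp.e**(-z*V))*rr / \
            ((z - z3)*Rtot)
        Jd1 = [prefk(L123[0], R123[0], D[0])*co['J111']*dsr,
               prefk(L123[1], R123[1], D[1])*co['J111']*dsr,
               D[2]*co['J3dev']*dsr]

        vals = dict(id=r['id'], variant=r['variant'],
                    Dbig=Dbig, Fbig=Fbig, c0=q0, c1=c1_, c2=c2_,
                    J110=co['J110'], J111=co['J111'],
                    J310=co['J310'], J3dev=co['J3dev'],
                    J1d0=Jd0[0], J2d0=Jd0[1], J3d0=Jd0[2],
                    J1d1=Jd1[0], J2d1=Jd1[1], J3d1=Jd1[2])
        out.append({k: (v if isinstance(v, str)
                        else mp.nstr(v, 17, strip_zeros=False))
                    for k, v in vals.items()})
        print('row', r['id'], 'done', flush=True)

    with open('tests/testthat/oracle-values.csv', 'w', newline='') as fh:
        wtr = csv.DictWriter(fh, fieldnames=list(out[0].keys()))
        wtr.writeheader()
        wtr.writerows(out)
    print(f'wrote {len(out)} oracle rows')


if __name__ == '__main__':
    main()
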