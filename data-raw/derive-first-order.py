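"""Symbolic derivation of the first-order-in-Q0 flux corrections.

Solves the outer electroneutral system with the O(Q0) interior Debye-layer
jump conditions as truncated mu-series (mu = (phiL - phiR)/ln(CR/CL)) over
atomic boundary values, takes the neutrality-deviation derivative by chain
rule, and caches the resulting coefficient lists for
data-raw/derive-coeffs.py, which extracts and emits the closed forms.

Run from the repository root:  python data-raw/derive-first-order.py
Requires sympy.  The cache (scratch/series_deriv.pkl) is scratch output,
not part of the repository.
"""
import sympy as sp
import pickle
import os
import time

v, Lv = sp.symbols('v Lv', positive=True)
z, z3, mu = sp.symbols('z z3 mu')
n, q, va, vb, CR = sp.symbols('n q v_a v_b CR', positive=True)
Ln, La, Lb = sp.symbols('Ln La Lb')
c1L, c1R = sp.symbols('c1L c1R', positive=True)
t, a, b, R, L1, R1 = sp.symbols('t alpha beta R L1 R1', positive=True)

NMU = 4


def tolist(e):
    e = sp.expand(e)
    return [sp.cancel(sp.together(e.coeff(mu, k))) for k in range(NMU)]


def smul(A, B):
    # keep every coefficient in canonical rational form so tree size
    # tracks the (compact) mathematical content, not the operation count
    return [sp.cancel(sp.together(sum(A[i]*B[k-i] for i in range(k+1))))
            for k in range(NMU)]


def sadd(A, B):
    return [sp.cancel(sp.together(A[k] + B[k])) for k in range(NMU)]


def sscale(A, c):
    return [sp.cancel(sp.together(c*x)) for x in A]


def sinv(A):
    """series inverse."""
    inv = [sp.cancel(1/A[0])]
    for k in range(1, NMU):
        inv.append(sp.cancel(sp.together(
            -sum(A[i]*inv[k-i] for i in range(1, k+1))/A[0])))
    return inv


def anti(p, k):
    p = int(p)
    if p == -1:
        return Lv**(k+1)/(k+1)
    q_ = sp.Integer(p+1)
    I = v**q_/q_
    for kk in range(1, k+1):
        I = v**q_*Lv**kk/q_ - sp.Integer(kk)/q_*I
    return I


LOGMAP = {n: Ln, va: La, vb: Lb, sp.Integer(1): sp.Integer(0)}


def integ(expr, lo, hi):
    expr = sp.expand(expr)
    out = 0
    for term in expr.as_ordered_terms():
        nu, de = term.as_numer_denom()
        pn = nu.as_powers_dict().get(v, sp.Integer(0))
        pdn = sp.factor(de).as_powers_dict().get(v, sp.Integer(0))
        k = int(nu.as_powers_dict().get(Lv, 0))
        p = pn - pdn
        c = sp.cancel(term/(v**p*Lv**k))
        assert not c.has(v) and not c.has(Lv), (term, c)
        F = anti(p, k)
        Fhi = F.subs({v: hi, Lv: LOGMAP[hi]})
        Flo = F if lo == 'sym' else F.subs({v: lo, Lv: LOGMAP[lo]})
        out += c*(Fhi - Flo)
    return out


def mu_trunc(e):
    e = sp.expand(e)
    return sum(e.coeff(mu, k)*mu**k for k in range(NMU))


def build(zc_sym):
    cf = z3/(z - z3)
    T1 = -mu*(Lb - La)
    jphi_a = 1/(z*(z - z3)*CR*va)
    jphi_b = -1/(z*(z - z3)*CR*vb)
    g1 = cf*T1*(v - n)/q
    g2 = cf*(T1*(v - n)/q + mu*(Lv - La)) - 1/(z - z3)
    g3 = cf*T1*(v - 1)/q
    P1 = z*(z - z3)*g1
    P2 = z*(z - z3)*g2 - z3
    P3 = z*(z - z3)*g3

    den = -Ln/(q*CR)
    num = (-mu/CR)*(integ(P1/v**2, n, va) + integ(P2/v**2, va, vb)
                    + integ(P3/v**2, vb, 1))
    K1 = (-num + z*(z - z3)*(jphi_a + jphi_b))/den
    K1list = tolist(K1)
    K1s = sp.Symbol('K1s')

    mexp = zc_sym*mu
    wser = mu_trunc(sum((-mexp*Lv)**k/sp.factorial(k) for k in range(NMU)))
    OmF = integ(wser, 'sym', 1)

    def p1p(P):
        return -(K1s - (mu*q/v)*P)/(z*(z - z3)*CR*v)

    I_Om_expr = (integ(mu_trunc(sp.expand(OmF*p1p(P1))), n, va)
                 + integ(mu_trunc(sp.expand(OmF*p1p(P2))), va, vb)
                 + integ(mu_trunc(sp.expand(OmF*p1p(P3))), vb, 1))/q
    top_expr = (I_Om_expr + OmF.subs({v: va, Lv: La})*jphi_a
                + OmF.subs({v: vb, Lv: Lb})*jphi_b)
    t0 = sp.expand(top_expr)
    top0 = tolist(t0.coeff(K1s, 0))
    top1 = tolist(t0.coeff(K1s, 1))
    top = sadd(top0, smul(top1, K1list))

    W0 = tolist(integ(wser, n, 1))
    W0inv = sinv(W0)
    nser = tolist(sum((mexp*Ln)**k/sp.factorial(k) for k in range(NMU)))
    ninv = tolist(sum((-mexp*Ln)**k/sp.factorial(k) for k in range(NMU)))
    if zc_sym == z:
        cX = sadd([c1L, 0, 0, 0], sscale(nser, -c1R))
    else:
        cX = sadd([z*n*CR/(-z3), 0, 0, 0], sscale(nser, -z*CR/(-z3)))
    J = sscale(smul(smul(smul(smul(cX, ninv), top), W0inv), W0inv),
               -zc_sym*q)
    return J


# stay in atom form: n, va, vb etc. remain symbols; the neutral
# identification (n = t, va = omega(alpha), Ln = ln t, ...) happens at
# evaluation time.
e_ = z/(z - z3)
datoms = {n: -2*e_*n, va: -2*e_*n*(1 - a), vb: -2*e_*n*(1 - b),
          CR: e_*CR, Ln: -2*e_, La: -2*e_*n*(1 - a)/va,
          Lb: -2*e_*n*(1 - b)/vb, c1L: -e_*c1L, c1R: e_*c1R}
dmu_const = -2/((z - z3)*Ln)
dmu_lin = 2*e_/Ln

out = {}
# orders actually needed: cation dJ[0..1] (affine), anion dJ[0..2]
for fam, zc, kmax in (('cation', z, 1), ('anion', z3, 2)):
    tt = time.time()
    J = build(zc)
    print(fam, 'built', time.time() - tt,
          [sp.count_ops(x) for x in J], flush=True)
    # eliminate q via the exact relation q = 1 - n (so the n-derivative
    # carries q's variation as well)
    J = [sp.cancel(x.subs(q, 1 - n)) for x in J]
    dJ = []
    for k in range(kmax + 1):
        tt = time.time()
        d = sum(sp.diff(J[k], s_)*d_ for s_, d_ in datoms.items())
        extra = (k + 1)*J[k + 1]*dmu_const
        if k >= 1:
            extra += k*J[k]*dmu_lin
        dJ.append(sp.cancel(sp.together(d + extra)))
        print(fam, 'dJ', k, 'ops', sp.count_ops(dJ[-1]),
              time.time() - tt, flush=True)
    out[fam] = (J[:kmax + 2], dJ)
    os.makedirs('scratch', exist_ok=True)
    with open('scratch/series_deriv.pkl', 'wb') as fh:
        pickle.dump(out, fh)
print('all done', flush=True)
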