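"""Generate R/coeffs-corrected.R: closed forms of the first-order
(permanent-charge) flux coefficient functions.

The generating derivation (data-raw/derive-first-order.py) solves the
outer electroneutral system plus the O(Q0) interior-layer jump conditions
exactly, expands in the neutrality deviations, and reduces the resulting
flux corrections to

  cation:  dJk/dQ0 = pref_k(V) * (J110 + (sigma - rho) * (A + B V) + ...)
  anion :  dJ3/dQ0 = pref_3(V) * J310 + (sigma - rho)(c0 + c1 V + c2 V^2)

This script performs the series division, simplifies, numerically
cross-validates against an independent quadrature implementation of the
same reduction, and emits R source.

Run from the repository root:
    python data-raw/derive-coeffs.py   (requires sympy; slow)
"""
import pickle
import sympy as sp
import mpmath as mp
from sympy.printing.rcode import rcode

# atom symbols of the derivation: n = t, Ln = ln t, va/vb = omega values,
# La/Lb their logs, CR = R (right cation total), c1L/c1R species-1 baths
n, va, vb, CR = sp.symbols('n v_a v_b CR', positive=True)
Ln, La, Lb = sp.symbols('Ln La Lb')
c1L, c1R = sp.symbols('c1L c1R', positive=True)
a, b = sp.symbols('alpha beta', positive=True)
z, z3 = sp.symbols('z z3')
t, lt, L1, R1, R = n, Ln, c1L, c1R, CR

import os
if not os.path.exists('scratch/series_deriv.pkl'):
    # regenerate the cached derivation (slow; a few minutes)
    import subprocess
    subprocess.run(['python', 'data-raw/derive-first-order.py'], check=True)
with open('scratch/series_deriv.pkl', 'rb') as fh:
    out = pickle.load(fh)
J0c, dJc = out['cation']
J0a, dJa = out['anion']

# prefactor series in mu (V = -mu * lt)
P0 = lt*(L1 - R1)/((z - z3)*R*(t - 1))
P1 = P0*(-(R1*z*lt/(L1 - R1) + z) + z*lt/(t - 1))
Q0_ = -lt/(z - z3)
Q1_ = lt*z3/(z - z3)


def simp(e):
    return sp.cancel(sp.together(e))


forms = {}
# cation deviation coefficient: A + B V
s0 = simp(dJc[0]/(2*P0))
s1 = simp((dJc[1] - 2*P1*s0)/(2*P0))
forms['catA'] = simp(s0)
forms['catB'] = simp(-s1/lt)
# cation neutral coefficient J110
u0 = simp(J0c[0]/P0)
u1 = simp((J0c[1] - P1*u0)/P0)
forms['cat0A'] = u0
forms['cat0B'] = simp(-u1/lt)
# anion deviation quadratic
forms['an_c0'] = simp(dJa[0]/2)
forms['an_c1'] = simp(-dJa[1]/(2*lt))
forms['an_c2'] = simp(dJa[2]/(2*lt**2))
# anion neutral coefficient J310
v0 = simp(J0a[0]/Q0_)
v1 = simp((J0a[1] - Q1_*v0)/Q0_)
forms['an0A'] = v0
forms['an0B'] = simp(-v1/lt)

for k, e in forms.items():
    print(k, 'ops', sp.count_ops(e), 'syms', sorted(map(str, e.free_symbols)))

with open('scratch/forms_final.pkl', 'wb') as fh:
    pickle.dump(forms, fh)

# ---------------- numeric validation vs quadrature route ------------------
import importlib.util
spec_ = importlib.util.spec_from_file_location(
    'dfo', 'data-raw/derive-oracle.py')
dfo = importlib.util.module_from_spec(spec_)
spec_.loader.exec_module(dfo)
mp.mp.dps = 25


def validate(zv, z3v, tv, av, bv, L1v, R1v, Rv, Vv, label):
    Lv_ = tv*Rv
    d = mp.mpf('1e-9')
    A = dfo.first_order_fluxes(zv, z3v, *dfo.limits(zv, z3v, Lv_, Rv, L1v,
                                                    R1v, 1 + d, 1 - d, Vv),
                               av, bv)
    Bq = dfo.first_order_fluxes(zv, z3v, *dfo.limits(zv, z3v, Lv_, Rv, L1v,
                                                     R1v, 1 - d, 1 + d, Vv),
                                av, bv)
    dJ1 = (A['J11'] - Bq['J11'])/(2*d)
    dJ3 = (A['J31'] - Bq['J31'])/(2*d)
    J11n = (A['J11'] + Bq['J11'])/2
    J31n = (A['J31'] + Bq['J31'])/2

    wav = tv + av*(1 - tv)
    wbv = tv + bv*(1 - tv)
    vals = {t: tv, a: av, b: bv, R: Rv, L1: L1v, R1: R1v, z: zv, z3: z3v,
            va: wav, vb: wbv, La: mp.log(wav), Lb: mp.log(wbv),
            Ln: mp.log(tv)}
    ev = lambda e: sp.lambdify(list(vals), e, 'mpmath')(*vals.values())
    ltv = mp.log(tv)
    Emv = mp.e**(-zv*Vv)
    pref1 = (L1v - R1v*Emv)*(ltv + zv*Vv)/((zv - z3v)*Rv*(tv - Emv))
    pref3 = -(ltv + z3v*Vv)/(zv - z3v)

    dJ1_c = 2*pref1*(ev(forms['catA']) + ev(forms['catB'])*Vv)
    J11_c = pref1*(ev(forms['cat0A']) + ev(forms['cat0B'])*Vv)
    dJ3_c = 2*(ev(forms['an_c0']) + ev(forms['an_c1'])*Vv
               + ev(forms['an_c2'])*Vv**2)
    J31_c = pref3*(ev(forms['an0A']) + ev(forms['an0B'])*Vv)
    rel = lambda x, y: abs(x - y)/max(abs(y), mp.mpf('1e-30'))
    print(label, 'rel errs: dJ1', mp.nstr(rel(dJ1_c, dJ1), 4),
          ' J11', mp.nstr(rel(J11_c, J11n), 4),
          ' dJ3', mp.nstr(rel(dJ3_c, dJ3), 4),
          ' J31', mp.nstr(rel(J31_c, J31n), 4))


cases = [
    (1, -1, 2, sp.Rational(1, 3), sp.Rational(2, 3), 1, '0.3', 1, '0.5'),
    (2, -1, '0.45', '0.21', '0.81', '0.3', '1.1', '1.7', '-0.8'),
    (1, -2, '3.7', '0.55', '0.6', '2.2', '0.4', '0.9', '1.3'),
    (2, -2, '1.8', '0.15', '0.35', '0.6', '0.9', '2.4', '2.1'),
]
for c in cases:
    validate(*[mp.mpf(str(sp.Rational(str(x)).evalf(30))) if not isinstance(
        x, int) else mp.mpf(x) for x in c[:3]],
        *[mp.mpf(str(sp.Rational(str(x)).evalf(30))) for x in c[3:5]],
        *[mp.mpf(str(sp.Rational(str(x)).evalf(30))) for x in c[5:8]],
        mp.mpf(str(sp.Rational(str(c[8])).evalf(30))), str(c))

# ---------------- emit R code --------------------------------------------
repl, reduced = sp.cse([forms[k] for k in
                        ('catA', 'catB', 'cat0A', 'cat0B',
                         'an_c0', 'an_c1', 'an_c2', 'an0A', 'an0B')],
                       optimizations='basic')
lines = [
    '# Generated by data-raw/derive-coeffs.py -- do not edit by hand.',
    '# Closed forms of the first-order (permanent-charge) flux coefficient',
    '# functions, derived from the outer electroneutral system with O(Q0)',
    '# interior-layer jump conditions and validated against an independent',
    '# quadrature implementation and the full BVP solver.',
    '#',
    '# .coeffs_corrected(t, alpha, beta, z, z3) returns:',
    '#   catA, catB : cation deviation coefficient  A + B V',
    '#   cat0A, cat0B : cation neutral coefficient (J110 analogue)',
    '#   an_c0..an_c2 : anion deviation quadratic  c0 + c1 V + c2 V^2',
    '#   an0A, an0B : anion neutral coefficient (J310 analogue)',
    '',
    '.coeffs_corrected <- function(t, alpha, beta, z, z3) {',
    '  n <- t',
    '  Ln <- log1p(t - 1)',
    '  v_a <- t + alpha * (1 - t)',
    '  v_b <- t + beta * (1 - t)',
    '  La <- log(v_a)',
    '  Lb <- log(v_b)',
]
for sym, expr in repl:
    lines.append(f'  {sym} <- {rcode(expr)}')
names = ['catA', 'catB', 'cat0A', 'cat0B', 'an_c0', 'an_c1', 'an_c2',
         'an0A', 'an0B']
lines.append('  list(')
for i, (nm, expr) in enumerate(zip(names, reduced)):
    comma = ',' if i < len(names) - 1 else ''
    lines.append(f'    {nm} = {rcode(expr)}{comma}')
lines += ['  )', '}']
body = '\n'.join(lines) + '\n'
with open('R/coeffs-corrected.R', 'w') as fh:
    fh.write(body)
print('wrote R/coeffs-corrected.R,', len(body), 'bytes')

# ---------------- series tables about t = 1 -------------------------------
# Near t = 1 the direct closed forms cancel through four powers of ln t.
# Rather than embedding long truncated expansions, emit the numerator and
# denominator monomial tables of each coefficient function; the R runtime
# rebuilds the u-series (u = t - 1) to any order from the elementary atom
# expansions and divides formally, which is numerically stable because the
# analytically-vanishing leading orders are dropped by construction.
import mpmath as mp2

atom_order = (n, va, vb, Ln, La, Lb)


def monomial_table(expr):
    nu, de = sp.fraction(sp.cancel(sp.together(expr)))
    out = {}
    for part, name in ((nu, 'num'), (de, 'den')):
        P = sp.Poly(sp.expand(part), *atom_order)
        pows = []
        coefs = []
        for monom, coeff in P.terms():
            pows.append(monom)
            coefs.append(rcode(coeff))
        out[name] = (pows, coefs)
    return out


def numeric_shift(expr):
    """common vanishing order of num and den u-series at a generic point."""
    vals = {a: mp2.mpf('0.31'), b: mp2.mpf('0.77'),
            z: mp2.mpf(1), z3: mp2.mpf(-1)}
    nu, de = sp.fraction(sp.cancel(sp.together(expr)))

    def order(e):
        f = sp.lambdify([n, va, vb, Ln, La, Lb], e.subs(vals), 'mpmath')
        mp2.mp.dps = 40
        for k in range(12):
            u0 = mp2.mpf('1e-6')
            val = f(1 + u0, 1 + u0*(1 - vals[a]), 1 + u0*(1 - vals[b]),
                    mp2.log(1 + u0), mp2.log(1 + u0*(1 - vals[a])),
                    mp2.log(1 + u0*(1 - vals[b])))
            return val
    nv = order(nu)
    dv = order(de)
    sh_n = round(float(mp2.log(abs(nv), 10)/mp2.log(mp2.mpf('1e-6'), 10)))
    sh_d = round(float(mp2.log(abs(dv), 10)/mp2.log(mp2.mpf('1e-6'), 10)))
    return min(sh_n, sh_d)


lines2 = [
    '',
    '# Monomial tables of the coefficient closed forms: each row of pows',
    '# gives the exponents of (n, v_a, v_b, Ln, La, Lb); coef() returns the',
    '# matching coefficients as functions of (z, z3, alpha, beta).  shift is',
    '# the common analytically-vanishing u-order of numerator and',
    '# denominator, dropped before the formal series division.',
    '.coefs_tables <- list(',
]
for i2, nm in enumerate(names):
    tab = monomial_table(forms[nm])
    sh = numeric_shift(forms[nm])
    comma = ',' if i2 < len(names) - 1 else ''
    np_, nc_ = tab['num']
    dp_, dc_ = tab['den']
    def emit_pows(pws):
        rows = ', '.join('c(' + ', '.join(str(x) for x in row) + 'L)'
                         .replace(', ', 'L, ', 1) if False else
                         'c(' + ', '.join(f'{x}L' for x in row) + ')'
                         for row in pws)
        return f'rbind({rows})'
    def emit_coefs(cs):
        return ('function(z, z3, alpha, beta) c(' +
                ', '.join(cs) + ')')
    lines2.append(f'  {nm} = list(shift = {sh}L,')
    lines2.append(f'    num_pows = {emit_pows(np_)},')
    lines2.append(f'    num_coef = {emit_coefs(nc_)},')
    lines2.append(f'    den_pows = {emit_pows(dp_)},')
    lines2.append(f'    den_coef = {emit_coefs(dc_)}){comma}')
    print('table done:', nm, 'shift', sh, 'terms', len(np_), len(dp_))
lines2.append(')')
with open('R/coeffs-corrected.R', 'a') as fh:
    fh.write('\n'.join(lines2) + '\n')
print('appended tables')
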