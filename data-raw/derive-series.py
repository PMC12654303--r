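"""Derive the Taylor coefficients (about t = 1) used by the guarded scalar
functions in R/series-coeffs.R, and emit that file.

The flux expansion contains ratios whose numerator and denominator both vanish
as the transmembrane concentration ratio t (or s) tends to 1.  Direct
evaluation in double precision loses all significant digits there, so inside
|t - 1| < 1e-4 the package switches to these truncated Taylor series.

Run from the repository root:  python data-raw/derive-series.py
Requires sympy (any recent version).
"""
import sympy as sp
from sympy.printing.rcode import rcode

u, al, be = sp.symbols('u alpha beta')
NT = 12

t = 1 + u
wa = 1 + u*(1-al)           # omega(alpha) at ratio t = 1 + u
wb = 1 + u*(1-be)
lt = sp.log(1+u)
Lab = sp.log(wb) - sp.log(wa)

def tpoly(expr):
    return sp.Poly(sp.series(expr, u, 0, NT).removeO(), u)


def divser(num, den, shift, nkeep):
    """Formal power-series division num/den, both O(u^shift)."""
    nc = [num.coeff_monomial(u**k) for k in range(NT)]
    dc = [den.coeff_monomial(u**k) for k in range(NT)]
    for k in range(shift):
        assert sp.simplify(nc[k]) == 0 and sp.simplify(dc[k]) == 0
    nc, dc = nc[shift:], dc[shift:]
    q = []
    for k in range(nkeep):
        val = nc[k] - sum(q[j]*dc[k-j] for j in range(k))
        q.append(sp.cancel(sp.together(val/dc[0])))
    return q


def rpoly(coeffs):
    """Horner-form R expression in u with symbolic coefficients."""
    expr = '0'
    for c in reversed(coeffs):
        cs = rcode(sp.expand(c))
        expr = f'({cs}) + u * ({expr})'
    return expr


cases = {
    # name: (numerator, denominator, common vanishing order, args)
    'a':  (t-1,              lt,       1, 'u'),
    'b1': (t*lt - t + 1,     lt**2,    2, 'u'),
    'b2': (t - 1 - lt,       lt**2,    2, 'u'),
    'P':  (wa*wb*lt*Lab + (be-al)*u**2, wa*wb*lt**3, 3, 'u, alpha, beta'),
    'Qt': ((be-al)*u**2,     wa*wb*lt**2, 2, 'u, alpha, beta'),
}

out = ['# Generated by data-raw/derive-series.py -- do not edit by hand.',
       '# Truncated Taylor expansions about t = 1 (u = t - 1) of the',
       '# guarded scalar functions; used when |t - 1| < .t_series_switch.',
       '']
for name, (num, den, shift, args) in cases.items():
    q = divser(tpoly(num), tpoly(den), shift, 6)
    out.append(f'.ser_{name} <- function({args}) {{')
    out.append(f'  {rpoly(q)}')
    out.append('}\n')

with open('R/series-coeffs.R', 'w') as fh:
    fh.write('\n'.join(out))
print('wrote R/series-coeffs.R')
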