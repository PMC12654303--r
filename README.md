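# pnpcrit

Critical potentials and flux asymptotics for a three-species
Poisson–Nernst–Planck (PNP) ion channel.

## The problem

Ion channels conduct several ionic species at once, and experiments see
only the total current–voltage relation.  The classical continuum model of
that transport is the steady-state PNP system: a Poisson equation for the
electric potential coupled to Nernst–Planck drift–diffusion equations for
each species.  `pnpcrit` works with its one-dimensional, three-species
form — two cation species sharing a valence `z > 0` and one anion of
valence `z3 < 0` — with two physically important complications:

* a small **permanent charge** `Q0` on an interior segment `(x1, x2)` of
  the channel wall, the continuum picture of charged residues lining a
  selectivity filter;
* **relaxed electroneutrality** in the baths: the boundary concentrations
  may carry a slight charge imbalance, quantified by multiplicative
  deviations `sigma` (left) and `rho` (right) from exact neutrality,
  which feeds sharp Debye boundary layers at the channel ends.

In dimensionless form (potentials in thermal-voltage units, the
dielectric parameter `epsilon` = Debye length / channel length):

```
(eps^2 / h) (h phi')' = -(z c1 + z c2 + z3 c3 + Q(x)),
c_k' + z_k c_k phi'   = -J_k / h(x),        J_k constant,
phi(0) = V, c_k(0) = L_k;   phi(1) = 0, c_k(1) = R_k.
```

For small `epsilon`, small `Q0` and small deviations, the fluxes expand as
`J_k = J_k0 + Q0 J_k1 + o(Q0)`, and the influence of the permanent charge
on the *boundary-layer flux difference*
`J_kd = J_k(sigma, rho) - J_k(1, 1)` switches sign at computable
**critical potentials**: the Nernst-type reversal potentials
`V_ka = -ln(L_k/R_k)/z_k`, a cation coupling potential `Vb` (the root of
an affine coefficient function), and the anion coupling potentials
`Vc_lo`, `Vc_hi` (the real roots of a quadratic coefficient — possibly
none, in which case one sign holds on the whole voltage axis).  These
thresholds partition the voltage axis into regimes in which a small
positive permanent charge consistently enhances or consistently reduces
each species' flux difference — a computable organising principle for
rectification and selectivity phenomena.

The package provides:

* the explicit flux expansions and their coefficient functions, with
  numerically guarded evaluation (`zeroth_order_flux`,
  `first_order_flux`, `general_zeroth_flux`, `flux_difference`,
  `eval_DF`, `first_order_coeffs`);
* the critical potentials and the full sign-regime classifier, which
  re-verifies every pattern against brute-force sign sampling before
  returning (`critical_potentials`, `classify_regime`,
  `sign_sample_oracle`);
* an independent stiff boundary-value solver for the full system
  (Slotboom variables, box collocation, damped Newton, continuation in
  `epsilon`) and finite-difference sensitivity tools used to validate
  every analytic claim (`solve_pnp`, `numeric_flux_sensitivity`,
  `numeric_flux_difference_sensitivity`);
* validation harnesses, a seeded cross-platform fixture generator,
  current–voltage sweeps, YAML/JSON configuration input and a command-line
  interface (`compare_asymptotic_numeric`, `recover_critical_potentials`,
  `theorem_consistency`, `make_params`, `iv_curve`, `read_config`,
  `inst/cli/pnpcrit`).

The first-order coefficient functions are derived inside the package from
the outer electroneutral system with the interior Debye-layer jump
conditions, and validated against an independent high-precision
implementation and the full solver; the methods vignette
(`vignettes/pnp-critical-potentials.Rmd`) documents the derivation, the
numerical guards and the validation in detail.

## Worked example

```r
library(pnpcrit)

# two monovalent cations and one monovalent anion; baths L = (1, 1, ~1.96),
# R = (0.3, 0.7, ~1.02) realising deviations sigma = 1.02, rho = 0.98
p <- pnp_params(z = 1, z3 = -1, D = c(1, 1, 1),
                L = c(1, 1), R = c(0.3, 0.7),
                sigma = 1.02, rho = 0.98, V = 0.5)

critical_potentials(p)
#> <pnp_criticals>
#>   reversal   V1a = -1.20397, V2a = -0.356675, V3a = 0.653142
#>   cation     Vb = 4.07963 (D = -0.02009, F = 0.08197)
#>   anion      Vc = no real roots (c0 = -0.1485, c1 = -0.0008954, c2 = -0.004406)

classify_regime(p, 1)
#> <pnp_sign_pattern> species 1, case i3
#>   breakpoints: -1.20397, 4.07963;  signs (+ | - | +)
classify_regime(p, 3)
#> <pnp_sign_pattern> species 3, case a1o
#>   sign(Jkd1) = - for all V
```

Species 1 is in the negative-coupling regime (`D < 0`) with
`V1a < Vb`: a small positive permanent charge *enhances* its flux
difference below `V1a = -1.204` and above `Vb = 4.080`, and *reduces* it
in between.  For the anion the quadratic coefficient has no real roots
here, so the permanent charge reduces its flux difference at every
voltage.

The asymptotic fluxes and the independent solver agree closely:

```r
zeroth_order_flux(pnp_params(1, -1, c(1, 1, 1),
                             L = c(1, 1, 2), R = c(0.3, 0.7, 1)), V = 0)
#>  J1  J2  J3
#> 0.7 0.3 1.0

flux_expansion(p)$total(0.01)      # J0 + 0.01 * J1
#>        J1        J2        J3
#> 1.0082422 0.7092206 0.2209626
solve_pnp(p, epsilon = 1e-3, Q0 = 0.01)$J
#>        J1        J2        J3
#> 1.0083554 0.7093002 0.2209464
```

A thin command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "pnpcrit", package = "pnpcrit"))')
Rscript "$CLI" criticals --config channel.yaml
Rscript "$CLI" iv --config channel.yaml --vmin -2 --vmax 2 --out iv.csv
```

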