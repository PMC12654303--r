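# Explicit flux expansions in the permanent-charge magnitude Q0, expanded to
# first order in the neutrality deviations (sigma - 1, rho - 1).

# Internal: shared pieces of the expanded flux formulas; V may be a vector.
.flux_ctx <- function(p, V) {
  z <- p$valences$z; z3 <- p$valences$z3
  b <- p$baths
  Rtot <- b$R1 + b$R2
  t <- (b$L1 + b$L2) / Rtot
  s <- b$L3 / b$R3
  list(z = z, z3 = z3, b = b, D = p$diffusion, H1 = p$geometry$H1,
       al = p$geometry$alpha, be = p$geometry$beta,
       Rtot = Rtot, t = t, s = s,
       ezV = exp(-z * V),
       r = .gw(log1p(t - 1) + z * V) / t,  # (ln t + zV)/(t - e^{-zV})
       ls3 = log1p(s - 1) + z3 * V)        # anion driving factor
}

#' Zeroth-order fluxes (no permanent charge)
#'
#' Evaluates the leading fluxes of the expansion
#' `Jk(V; Q0) = Jk0(V) + Q0 Jk1(V) + o(Q0)`, with the bath charge imbalance
#' entering linearly through `(sigma - 1)` and `(rho - 1)` via [eval_f()]
#' (an excess-cation left bath, `sigma > 1`, dilutes the boundary-layer
#' inner concentrations and reduces the cation fluxes; the coefficient
#' signs follow the exact first-order expansion of the general
#' boundary-layer fluxes and are validated against the full solver).
#' At `sigma = rho = 1`, `Jk0` vanishes exactly at the species' Nernst-type
#' reversal potential (`V1a`, `V2a`, `V3a`; see [critical_potentials()]).
#'
#' The removable singularity of the cation factor
#' `(ln t + zV)/(t - exp(-zV))` at `V = -ln(t)/z` is evaluated through its
#' limit `1/t`, and the `t -> 1`, `s -> 1` ratios through series guards, so
#' the result is continuous in all arguments.
#'
#' @param p A [pnp_params] object.
#' @param V Potential(s); defaults to `p$baths$V`.
#' @return For scalar `V` a named vector `c(J1, J2, J3)`; for vector `V` a
#'   matrix with one row per potential.
#' @examples
#' p <- pnp_params(1, -1, c(1, 1, 1), L = c(1, 1, 2), R = c(0.3, 0.7, 1))
#' zeroth_order_flux(p, V = 0)   # c(0.7, 0.3, 1.0)
#' @export
zeroth_order_flux <- function(p, V = p$baths$V) {
  cx <- .flux_ctx(p, V)
  z <- cx$z; z3 <- cx$z3; b <- cx$b
  wt <- .fa(cx$t) - z / (z - z3) *
    (.fb1(cx$t) * (b$sigma - 1) + .fb2(cx$t) * (b$rho - 1))
  ws <- .fa(cx$s) - z3 / (z - z3) *
    (.fb1(cx$s) * (b$sigma - 1) + .fb2(cx$s) * (b$rho - 1))
  out <- cbind(
    J1 = cx$D$D1 * (b$L1 - b$R1 * cx$ezV) * cx$r * wt / cx$H1,
    J2 = cx$D$D2 * (b$L2 - b$R2 * cx$ezV) * cx$r * wt / cx$H1,
    J3 = cx$D$D3 * b$R3 * cx$ls3 * ws / cx$H1)
  if (length(V) == 1L) out[1L, ] else out
}

#' First-order fluxes in the permanent-charge magnitude
#'
#' Evaluates the coefficients `Jk1` of `Q0` in the flux expansion, combining
#' the species prefactors with the coefficient functions of
#' [first_order_coeffs()]; the neutrality deviations enter through the
#' antisymmetric combination `(sigma - 1) - (rho - 1) = sigma - rho`.
#'
#' @inheritParams zeroth_order_flux
#' @return As [zeroth_order_flux()].
#' @export
first_order_flux <- function(p, V = p$baths$V) {
  cx <- .flux_ctx(p, V)
  z <- cx$z; z3 <- cx$z3; b <- cx$b
  fc <- first_order_coeffs(p, V)
  dsr <- b$sigma - b$rho
  ct <- fc$J110 + fc$J111 * dsr
  pre <- cx$r * ct / ((z - z3) * cx$Rtot * cx$H1)
  # anion: neutral part factors through the driving prefactor (at the
  # cation ratio t, the expansion's base point); the deviation part is the
  # bare quadratic
  lt3 <- log1p(cx$t - 1) + z3 * V
  out <- cbind(
    J1 = cx$D$D1 * (b$L1 - b$R1 * cx$ezV) * pre,
    J2 = cx$D$D2 * (b$L2 - b$R2 * cx$ezV) * pre,
    J3 = -cx$D$D3 * lt3 * fc$J310 / ((z - z3) * cx$H1) +
      cx$D$D3 * fc$J3dev * dsr / cx$H1)
  if (length(V) == 1L) out[1L, ] else out
}

#' Flux expansion bundle
#'
#' Packages the zeroth- and first-order fluxes at one potential into an
#' object whose `total(Q0)` is the affine expansion `J0 + Q0 * J1`.
#'
#' @inheritParams zeroth_order_flux
#' @return Object of class `pnp_flux_expansion`: list with `J0`, `J1`
#'   (named vectors or matrices) and the function `total(Q0)`.
#' @export
flux_expansion <- function(p, V = p$baths$V) {
  J0 <- zeroth_order_flux(p, V)
  J1 <- first_order_flux(p, V)
  structure(list(J0 = J0, J1 = J1,
                 total = function(Q0) J0 + Q0 * J1),
            class = "pnp_flux_expansion")
}

#' @export
print.pnp_flux_expansion <- function(x, ...) {
  cat("<pnp_flux_expansion>  Jk(Q0) = Jk0 + Q0 * Jk1\n")
  cat("  J0:", paste(sprintf("%.6g", x$J0), collapse = ", "), "\n")
  cat("  J1:", paste(sprintf("%.6g", x$J1), collapse = ", "), "\n")
  invisible(x)
}

#' Zeroth-order fluxes for general (not nearly neutral) baths
#'
#' Evaluates the zeroth-order fluxes directly from the boundary-layer inner
#' limit values (see [inner_limits()]), without expanding in
#' `(sigma - 1, rho - 1)`.  For `k = 1, 2`
#' \deqn{J_{k0} = D_k \frac{c^L - c^R}{H(1)(\ln c^L - \ln c^R)}
#'   \cdot \frac{\ln c^L - \ln c^R - z\,\Delta\phi}{c^L - c^R e^{z\Delta\phi}}
#'   \left(c_k^L - c_k^R e^{z\Delta\phi}\right),}
#' with \eqn{\Delta\phi = \phi^R - \phi^L} and `c` the cation totals, and
#' \deqn{J_{30} = -\frac{z}{z_3} D_3
#'   \frac{c^L - c^R}{H(1)(\ln c^L - \ln c^R)}
#'   \left(\ln c^L - \ln c^R - z_3\,\Delta\phi\right).}
#' At `sigma = rho = 1` this agrees with [zeroth_order_flux()] to within
#' rounding (an identity used as a transcription cross-check in the test
#' suite); away from neutrality it is the more accurate of the two.
#'
#' @inheritParams zeroth_order_flux
#' @return As [zeroth_order_flux()].
#' @export
general_zeroth_flux <- function(p, V = p$baths$V) {
  z <- p$valences$z; z3 <- p$valences$z3
  D <- p$diffusion; H1 <- p$geometry$H1
  out <- matrix(NA_real_, length(V), 3,
                dimnames = list(NULL, c("J1", "J2", "J3")))
  for (i in seq_along(V)) {
    il <- inner_limits(with_potential(p, V[i]))
    dphi <- il$phiR - il$phiL
    lnr <- log(il$cL) - log(il$cR)
    A <- if (abs(lnr) > 1e-8) (il$cL - il$cR) / lnr else
      0.5 * (il$cL + il$cR) * (1 - lnr^2 / 24)  # log-mean limit
    A <- A / H1
    u2 <- lnr - z * dphi
    gi <- if (abs(u2) > 1e-8) u2 / expm1(u2) else 1 - u2 / 2 + u2^2 / 12
    core <- gi / (il$cR * exp(z * dphi))
    out[i, 1] <- D$D1 * A * core * (il$c1L - il$c1R * exp(z * dphi))
    out[i, 2] <- D$D2 * A * core * (il$c2L - il$c2R * exp(z * dphi))
    out[i, 3] <- -(z / z3) * D$D3 * A * (lnr - z3 * dphi)
  }
  if (length(V) == 1L) out[1L, ] else out
}

#' Boundary-layer flux differences and their permanent-charge coefficients
#'
#' The flux difference `Jkd(V) = Jk(V; sigma, rho) - Jk(V; 1, 1)` isolates
#' the effect of bath charge imbalance (the `(1, 1)` companion is the same
#' configuration with species 3 rescaled to exact electroneutrality).  Its
#' expansion in `Q0`, `Jkd = Jkd0 + Q0 Jkd1 + o(Q0)`, has first-order part
#' `Jkd1` proportional to `(sigma - rho)`: for the cations through the
#' affine coefficient `J111` times the species prefactor, for the anion
#' through the bare quadratic `J3dev`.  The sign of `Jkd1` -- whether a
#' small positive permanent charge enhances or reduces the flux difference
#' -- is the quantity organised by the critical potentials; see
#' [classify_regime()].
#'
#' @inheritParams zeroth_order_flux
#' @return List with components `Jd0` and `Jd1`, each a named vector
#'   `c(J1, J2, J3)` (or matrix for vector `V`).
#' @export
flux_difference <- function(p, V = p$baths$V) {
  cx <- .flux_ctx(p, V)
  z <- cx$z; z3 <- cx$z3; b <- cx$b
  fc <- first_order_coeffs(p, V)
  dsr <- b$sigma - b$rho
  # zeroth order: exact operational difference against the neutralised
  # companion (for the cations this collapses to the f-bracket term; the
  # anion difference also carries the concentration rescaling of species 3)
  pn <- neutralized_params(p)
  Jd0 <- zeroth_order_flux(p, V) - zeroth_order_flux(pn, V)
  if (length(V) > 1L && is.null(dim(Jd0)))
    Jd0 <- matrix(Jd0, nrow = length(V))
  Jd1 <- cbind(
    J1 = cx$D$D1 * (b$L1 - b$R1 * cx$ezV) * cx$r * fc$J111 * dsr /
      ((z - z3) * cx$Rtot * cx$H1),
    J2 = cx$D$D2 * (b$L2 - b$R2 * cx$ezV) * cx$r * fc$J111 * dsr /
      ((z - z3) * cx$Rtot * cx$H1),
    J3 = cx$D$D3 * fc$J3dev * dsr / cx$H1)
  if (length(V) == 1L) list(Jd0 = Jd0, Jd1 = Jd1[1L, ])
  else list(Jd0 = Jd0, Jd1 = Jd1)
}
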