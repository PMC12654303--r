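# Critical potentials and the sign-regime classification of the
# permanent-charge contribution Jkd1 to the boundary-layer flux difference.

# Internal: scale-aware zero test for a leading coefficient against the
# magnitude of its companion(s).
.is_degenerate <- function(lead, companion) {
  abs(lead) < 1e-12 * max(1, abs(companion))
}

#' The critical potentials
#'
#' Computes the potentials that partition the voltage axis into regimes of
#' qualitatively distinct flux response:
#' \deqn{V_{ka} = -\frac{1}{z}\ln\frac{L_k}{R_k}\ (k = 1,2), \qquad
#'       V_{3a} = -\frac{1}{z_3}\ln\frac{L_3}{R_3},}
#' the Nernst-type reversal potentials at which each species' leading flux
#' vanishes, and the coupling critical potentials of the permanent-charge
#' flux-difference term:
#' \deqn{V_b = -\frac{F(\beta)}{z\,D(\beta)}}
#' for the cations (the root of the affine coefficient `J111`; `Vb` is
#' undefined when `D(beta) = 0`, which selects the single-threshold
#' regime), and for the anion the real roots `Vc_lo <= Vc_hi` of the
#' quadratic deviation coefficient `c0 + c1 V + c2 V^2` -- the anion may
#' therefore have two, one or no coupling potentials, and (unlike the
#' cations) its reversal potential `V3a` is not a sign change of the
#' permanent-charge difference term.
#'
#' @param p A [pnp_params] object.
#' @return Object of class `pnp_criticals`: list with `V1a`, `V2a`, `V3a`,
#'   `Vb`, `Vc_lo`, `Vc_hi`, logical `Vb_defined`, `Vc_defined` (TRUE when
#'   the anion quadratic has real roots), and the coefficient values
#'   `Dbig`, `Fbig`, `c0`, `c1`, `c2`.
#' @examples
#' p <- pnp_params(1, -1, c(1, 1, 1), L = c(1, 1, 2), R = c(0.3, 0.7, 1))
#' critical_potentials(p)
#' @export
critical_potentials <- function(p) {
  z <- p$valences$z; z3 <- p$valences$z3
  b <- p$baths
  df <- eval_DF(p)
  Vb_def <- !.is_degenerate(df$Dbig, df$Fbig)

  # anion quadratic roots
  qroots <- .quad_roots(df$c0, df$c1, df$c2)

  structure(list(
    V1a = -log(b$L1 / b$R1) / z,
    V2a = -log(b$L2 / b$R2) / z,
    V3a = -log(b$L3 / b$R3) / z3,
    Vb = if (Vb_def) -df$Fbig / (z * df$Dbig) else NA_real_,
    Vc_lo = qroots$lo, Vc_hi = qroots$hi,
    Vb_defined = Vb_def, Vc_defined = qroots$n > 0,
    Dbig = df$Dbig, Fbig = df$Fbig,
    c0 = df$c0, c1 = df$c1, c2 = df$c2
  ), class = "pnp_criticals")
}

# Internal: real roots of c0 + c1 V + c2 V^2, with scale-aware degeneracy
# to an affine (or constant) polynomial.
.quad_roots <- function(c0, c1, c2) {
  scale <- max(abs(c0), abs(c1))
  if (.is_degenerate(c2, scale)) {
    if (.is_degenerate(c1, abs(c0))) {
      return(list(n = 0L, lo = NA_real_, hi = NA_real_, kind = "constant"))
    }
    r <- -c0 / c1
    return(list(n = 1L, lo = r, hi = r, kind = "linear"))
  }
  disc <- c1^2 - 4 * c0 * c2
  if (disc < 0)
    return(list(n = 0L, lo = NA_real_, hi = NA_real_, kind = "quadratic"))
  if (disc == 0) {
    r <- -c1 / (2 * c2)
    return(list(n = 1L, lo = r, hi = r, kind = "tangent"))
  }
  # numerically stable quadratic roots
  qq <- -(c1 + sign(c1 + (c1 == 0)) * sqrt(disc)) / 2
  r1 <- qq / c2
  r2 <- if (qq != 0) c0 / qq else -c1 / c2 - r1
  list(n = 2L, lo = min(r1, r2), hi = max(r1, r2), kind = "quadratic")
}

#' @export
print.pnp_criticals <- function(x, ...) {
  cat("<pnp_criticals>\n")
  cat(sprintf("  reversal   V1a = %.6g, V2a = %.6g, V3a = %.6g\n",
              x$V1a, x$V2a, x$V3a))
  cat(sprintf("  cation     Vb = %s (D = %.4g, F = %.4g)\n",
              if (x$Vb_defined) sprintf("%.6g", x$Vb) else "undefined",
              x$Dbig, x$Fbig))
  vc <- if (!x$Vc_defined) "no real roots"
  else if (x$Vc_lo == x$Vc_hi) sprintf("%.6g", x$Vc_lo)
  else sprintf("%.6g, %.6g", x$Vc_lo, x$Vc_hi)
  cat(sprintf("  anion      Vc = %s (c0 = %.4g, c1 = %.4g, c2 = %.4g)\n",
              vc, x$c0, x$c1, x$c2))
  invisible(x)
}

# Internal: cation sign-pattern table for sigma > rho: sign(Jkd1) =
# sign(Lk - Rk e^{-zV}) * sign(J111(V)), with J111 = z3 (z D V + F)/(+),
# z3 < 0.  Breakpoints {Vka, Vb},
# outer sign + for D < 0.
.cation_pattern <- function(Dval, Fval, Va, Vbc) {
  if (.is_degenerate(Dval, Fval)) {
    if (Fval > 0) {
      return(list(breakpoints = Va, signs = c("+", "-"), case_label = "ii1"))
    } else if (Fval < 0) {
      return(list(breakpoints = Va, signs = c("-", "+"), case_label = "ii2"))
    } else {
      return(list(breakpoints = numeric(0), signs = "0",
                  case_label = "degenerate"))
    }
  }
  branch <- if (Dval < 0) "i" else "iii"
  outer_sign <- if (Dval < 0) "+" else "-"
  inner_sign <- if (Dval < 0) "-" else "+"
  if (abs(Va - Vbc) < 1e-10) {
    list(breakpoints = numeric(0), signs = outer_sign,
         case_label = paste0(branch, "2"))
  } else if (Va > Vbc) {
    list(breakpoints = c(Vbc, Va),
         signs = c(outer_sign, inner_sign, outer_sign),
         case_label = paste0(branch, "1"))
  } else {
    list(breakpoints = c(Va, Vbc),
         signs = c(outer_sign, inner_sign, outer_sign),
         case_label = paste0(branch, "3"))
  }
}

# Internal: anion pattern for sigma > rho: sign(J3d1) = sign of the
# quadratic c0 + c1 V + c2 V^2.
.anion_pattern <- function(roots, c0, c1, c2) {
  sgn <- function(x) if (x > 0) "+" else if (x < 0) "-" else "0"
  if (identical(roots$kind, "constant")) {
    return(list(breakpoints = numeric(0), signs = sgn(c0),
                case_label = if (c0 == 0) "degenerate" else "a0"))
  }
  if (identical(roots$kind, "linear")) {
    s_inf <- sgn(-c1)   # sign as V -> -Inf
    return(list(breakpoints = roots$lo,
                signs = c(s_inf, if (s_inf == "+") "-" else "+"),
                case_label = "a-lin"))
  }
  outer <- sgn(c2)
  if (roots$n == 2L) {
    list(breakpoints = c(roots$lo, roots$hi),
         signs = c(outer, if (outer == "+") "-" else "+", outer),
         case_label = if (c2 > 0) "a2" else "a1")
  } else {
    # tangent or no real roots: single sign (tangent point has measure 0)
    list(breakpoints = numeric(0), signs = outer,
         case_label = if (roots$n == 1L) "a-tangent" else
           if (c2 > 0) "a2o" else "a1o")
  }
}

.flip_signs <- function(signs) {
  vapply(signs, function(s) switch(s, "+" = "-", "-" = "+", "0" = "0"),
         character(1), USE.NAMES = FALSE)
}

#' Sign-regime classification of the permanent-charge flux-difference term
#'
#' Determines, for one species, the sign of `Jkd1(V)` -- the first-order
#' (permanent-charge) coefficient of the boundary-layer flux difference --
#' on each interval of the potential axis cut at the relevant critical
#' potentials.  A `+` interval is one where a small positive permanent
#' charge enhances the flux difference of that species, `-` one where it
#' reduces it.
#'
#' For the cations (`species` 1 or 2) the breakpoints are the species
#' reversal potential `Vka` and (when `D(beta) != 0`) the coupling
#' threshold `Vb`; the pattern is `+/-/+` for `D(beta) < 0` and `-/+/-`
#' for `D(beta) > 0`, collapsing to a single sign when the two breakpoints
#' coincide, and to a single switch at `Vka` when `D(beta) = 0` (the sign
#' of `F(beta)` deciding the parity).  For the anion (`species` 3) the
#' term is a quadratic polynomial in `V`: the breakpoints are its real
#' roots `Vc_lo`, `Vc_hi` (possibly none, in which case one sign holds on
#' the whole axis), with the sign of the leading coefficient `c2` outside
#' the roots.
#'
#' The classification is stated for `sigma > rho`; for `sigma < rho` every
#' sign is flipped (the term is proportional to `sigma - rho`), and
#' `sigma = rho` yields the everywhere-zero pattern.  Before returning,
#' the predicted pattern is verified against direct sign sampling of
#' [flux_difference()] at representative potentials; a disagreement raises
#' an error with a diagnostic dump rather than silently adjusting either
#' side.
#'
#' @param p A [pnp_params] object.
#' @param species Species index: 1, 2 (cations) or 3 (anion).
#' @return Object of class `pnp_sign_pattern`: list with `species`,
#'   `breakpoints` (increasing, possibly empty), `signs` (one more entry
#'   than breakpoints, each `"+"`, `"-"` or `"0"`), and `case_label`
#'   (cations: `i1, i2, i3, ii1, ii2, iii1, iii2, iii3`; anion: `a1`/`a2`
#'   for two roots with negative/positive leading coefficient, `a1o`/`a2o`
#'   for the rootless single-sign cases, `a-lin`, `a-tangent`, `a0` for
#'   the degenerate ones; `zero` when `sigma = rho`).
#' @examples
#' p <- pnp_params(1, -1, c(1, 1, 1), L = c(1, 1), R = c(0.3, 0.7),
#'                 sigma = 1.02, rho = 0.98)
#' classify_regime(p, 1)
#' @export
classify_regime <- function(p, species) {
  if (!species %in% 1:3) stop("species must be 1, 2 or 3")
  b <- p$baths
  if (abs(b$sigma - b$rho) < 1e-14) {
    return(structure(list(species = species, breakpoints = numeric(0),
                          signs = "0", case_label = "zero"),
                     class = "pnp_sign_pattern"))
  }
  cp <- critical_potentials(p)
  pat <- if (species == 3L) {
    roots <- .quad_roots(cp$c0, cp$c1, cp$c2)
    .anion_pattern(roots, cp$c0, cp$c1, cp$c2)
  } else {
    Va <- if (species == 1L) cp$V1a else cp$V2a
    .cation_pattern(cp$Dbig, cp$Fbig, Va, cp$Vb)
  }
  if (b$sigma < b$rho) pat$signs <- .flip_signs(pat$signs)

  out <- structure(c(list(species = species), pat),
                   class = "pnp_sign_pattern")
  .verify_pattern(p, out)
  out
}

#' @export
print.pnp_sign_pattern <- function(x, ...) {
  cat(sprintf("<pnp_sign_pattern> species %d, case %s\n",
              x$species, x$case_label))
  if (length(x$breakpoints) == 0L) {
    cat(sprintf("  sign(Jkd1) = %s for all V\n", x$signs))
  } else {
    bits <- sprintf("(%s)", paste(x$signs, collapse = " | "))
    cat(sprintf("  breakpoints: %s;  signs %s\n",
                paste(sprintf("%.6g", x$breakpoints), collapse = ", "), bits))
  }
  invisible(x)
}

# Internal: midpoint/outer sampling check of a predicted pattern against
# the formulas themselves.  Stops with a diagnostic on any mismatch.
.verify_pattern <- function(p, pat, offset = 1e-5) {
  if (identical(pat$signs, "0")) return(invisible(TRUE))
  bp <- pat$breakpoints
  probes <- if (length(bp) == 0L) {
    cp <- critical_potentials(p)
    ctr <- if (pat$species == 3L) cp$V3a else cp$V1a
    c(ctr - 1, ctr + 1)
  } else {
    c(min(bp) - 1,
      if (length(bp) > 1L) (bp[-length(bp)] + bp[-1L]) / 2,
      max(bp) + 1)
  }
  # potentials beyond a few hundred thermal units overflow the Boltzmann
  # factors (and are physically meaningless); skip such probes
  probes_ok <- abs(probes) < 250 / max(abs(p$valences$z),
                                       abs(p$valences$z3))
  idx <- if (length(bp) == 0L) c(1L, 1L) else seq_along(pat$signs)
  # an interval too narrow to probe reliably is skipped, not shifted (a
  # shifted probe would land in the neighbouring interval)
  keep <- probes_ok
  for (j in seq_along(probes)) {
    if (length(bp) && min(abs(probes[j] - bp)) < offset) keep[j] <- FALSE
  }
  probes <- probes[keep]
  idx <- idx[keep]
  if (length(probes) == 0L) return(invisible(TRUE))
  got <- sign_sample_oracle(p, pat$species, probes)
  want <- pat$signs[idx]
  if (!identical(got, want)) {
    stop(sprintf(paste0(
      "sign-regime classification disagrees with direct formula sampling\n",
      "  species %d, case %s\n  probes: %s\n  predicted: %s\n  sampled: %s\n",
      "  (possible coefficient-function fault -- not patched)"),
      pat$species, pat$case_label,
      paste(sprintf("%.8g", probes), collapse = ", "),
      paste(want, collapse = ""), paste(got, collapse = "")))
  }
  invisible(TRUE)
}

#' Brute-force sign sampling of the flux-difference term
#'
#' Evaluates `sign(Jkd1(V))` from [flux_difference()] on a grid of
#' potentials.  This is the ground truth against which [classify_regime()]
#' patterns are verified (the grid should avoid the exact breakpoints,
#' where the sign is 0 up to rounding).
#'
#' @param p A [pnp_params] object.
#' @param species Species index 1, 2 or 3.
#' @param V_grid Potentials to sample.
#' @return Character vector over the grid: `"+"`, `"-"` or `"0"`.
#' @export
sign_sample_oracle <- function(p, species, V_grid) {
  if (!species %in% 1:3) stop("species must be 1, 2 or 3")
  vals <- flux_difference(p, V_grid)$Jd1
  vals <- if (is.matrix(vals)) vals[, species] else vals[species]
  out <- rep(NA_character_, length(vals))
  ok <- is.finite(vals)
  out[ok] <- c("-", "0", "+")[sign(vals[ok]) + 2]
  out
}
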