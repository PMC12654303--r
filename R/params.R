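#' Model parameters for a three-species PNP channel
#'
#' Assembles and validates the complete dimensionless description of one
#' channel/bath configuration: valences, bath concentrations, transmembrane
#' potential, neutrality deviations, permanent charge, channel geometry,
#' diffusion coefficients and the dielectric small parameter.
#'
#' Species 1 and 2 are cations sharing the valence `z > 0`; species 3 is the
#' anion with valence `z3 < 0`.  The left bath holds potential `V` and
#' concentrations `L`, the right bath is grounded with concentrations `R`.
#'
#' The anion concentrations can be supplied in two equivalent ways:
#' * `L` and `R` of length 3 -- the neutrality deviations `sigma`, `rho` are
#'   then derived from the charge balance (see [neutral_deviation()]);
#' * `L` and `R` of length 2 together with `sigma` and `rho` -- the anion
#'   concentrations are then derived as `L3 = z*(L1+L2)/(-z3*sigma)` (and the
#'   mirrored expression on the right), so that the requested deviation holds
#'   exactly.
#'
#' @param z Common cation valence (> 0).
#' @param z3 Anion valence (< 0).
#' @param D Diffusion coefficients, length 3, all > 0.
#' @param L,R Bath concentrations (length 2 or 3, see Details), all > 0.
#' @param V Transmembrane potential at the left end (right end is 0).
#' @param sigma,rho Neutrality-deviation factors (> 0); alternative to
#'   supplying `L3`, `R3` directly.
#' @param Q0 Permanent-charge magnitude on `(x1, x2)`; intended small.
#' @param x1,x2 Endpoints of the permanent-charge region, `0 < x1 < x2 < 1`.
#' @param h Channel cross-section profile: `NULL` for the uniform channel
#'   (`h(x) = 1`), a positive function on `[0, 1]`, or a two-column
#'   `data.frame` with columns `x` and `h` interpolated monotonically.
#' @param epsilon Dielectric small parameter (ratio of Debye length to channel
#'   length); used only by the numerical solver.
#'
#' @return An object of class `pnp_params`: a list with components `valences`
#'   (`z`, `z3`), `baths` (`L1..L3`, `R1..R3`, `V`, `sigma`, `rho`),
#'   `geometry` (`h`, `x1`, `x2`, `H1`, `alpha`, `beta`), `charge` (`Q0`),
#'   `diffusion` (`D1..D3`) and `epsilon`.
#'
#' @examples
#' p <- pnp_params(z = 1, z3 = -1, D = c(1, 1, 1),
#'                 L = c(1, 1), R = c(0.3, 0.7),
#'                 sigma = 1.02, rho = 0.98, V = 0.5)
#' p$baths$L3            # derived anion concentration
#' @export
pnp_params <- function(z, z3, D, L, R, V = 0, sigma = NULL, rho = NULL,
                       Q0 = 0, x1 = 1/3, x2 = 2/3, h = NULL,
                       epsilon = 1e-4) {
  stopifnot(is.numeric(z), length(z) == 1L, is.finite(z),
            is.numeric(z3), length(z3) == 1L, is.finite(z3))
  if (z <= 0) stop("cation valence z must be positive")
  if (z3 >= 0) stop("anion valence z3 must be negative")
  if (length(D) != 3L || any(!is.finite(D)) || any(D <= 0))
    stop("D must be three positive diffusion coefficients")
  if (!is.numeric(V) || length(V) != 1L || !is.finite(V))
    stop("V must be a finite scalar")
  if (!is.numeric(Q0) || length(Q0) != 1L || !is.finite(Q0))
    stop("Q0 must be a finite scalar")
  if (!(x1 > 0 && x1 < x2 && x2 < 1))
    stop("permanent-charge region must satisfy 0 < x1 < x2 < 1")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("epsilon must be positive")

  if (length(L) == 2L || length(R) == 2L) {
    if (is.null(sigma) || is.null(rho))
      stop("with two cation concentrations, sigma and rho must be supplied")
    if (sigma <= 0 || rho <= 0) stop("sigma and rho must be positive")
    if (any(L[1:2] <= 0) || any(R[1:2] <= 0))
      stop("bath concentrations must be positive")
    L <- c(L[1:2], z * sum(L[1:2]) / (-z3 * sigma))
    R <- c(R[1:2], z * sum(R[1:2]) / (-z3 * rho))
  } else {
    if (length(L) != 3L || length(R) != 3L)
      stop("L and R must have length 2 or 3")
    if (any(L <= 0) || any(R <= 0))
      stop("bath concentrations must be positive")
    sr <- neutral_deviation(z, z3, L, R)
    if (!is.null(sigma) && abs(sigma - sr[["sigma"]]) > 1e-8 * sigma)
      stop("supplied sigma inconsistent with the supplied concentrations")
    if (!is.null(rho) && abs(rho - sr[["rho"]]) > 1e-8 * rho)
      stop("supplied rho inconsistent with the supplied concentrations")
    sigma <- sr[["sigma"]]
    rho <- sr[["rho"]]
  }

  geom <- geometry_reduce(h, x1, x2)

  p <- structure(list(
    valences = list(z = z, z3 = z3),
    baths = list(L1 = L[1], L2 = L[2], L3 = L[3],
                 R1 = R[1], R2 = R[2], R3 = R[3],
                 V = V, sigma = sigma, rho = rho),
    geometry = c(geom, list(x1 = x1, x2 = x2)),
    charge = list(Q0 = Q0, x1 = x1, x2 = x2),
    diffusion = list(D1 = D[1], D2 = D[2], D3 = D[3]),
    epsilon = epsilon
  ), class = "pnp_params")
  validate_params(p)
  p
}

#' @export
print.pnp_params <- function(x, ...) {
  b <- x$baths
  cat("<pnp_params>\n")
  cat(sprintf("  valences     z = %g (cations 1,2), z3 = %g (anion)\n",
              x$valences$z, x$valences$z3))
  cat(sprintf("  left  bath   L = (%g, %g, %g), potential V = %g\n",
              b$L1, b$L2, b$L3, b$V))
  cat(sprintf("  right bath   R = (%g, %g, %g), grounded\n", b$R1, b$R2, b$R3))
  cat(sprintf("  neutrality   sigma = %.6g, rho = %.6g\n", b$sigma, b$rho))
  cat(sprintf("  charge       Q0 = %g on (%g, %g);  alpha = %.4g, beta = %.4g, H(1) = %.6g\n",
              x$charge$Q0, x$charge$x1, x$charge$x2,
              x$geometry$alpha, x$geometry$beta, x$geometry$H1))
  cat(sprintf("  diffusion    D = (%g, %g, %g);  epsilon = %g\n",
              x$diffusion$D1, x$diffusion$D2, x$diffusion$D3, x$epsilon))
  invisible(x)
}

# Internal: check every structural invariant of a pnp_params object.
validate_params <- function(p) {
  stopifnot(inherits(p, "pnp_params"))
  b <- p$baths
  conc <- c(b$L1, b$L2, b$L3, b$R1, b$R2, b$R3)
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("all bath concentrations must be finite and positive")
  if (b$sigma <= 0 || b$rho <= 0) stop("sigma and rho must be positive")
  g <- p$geometry
  if (!(g$H1 > 0)) stop("total resistance integral H(1) must be positive")
  if (!(g$alpha > 0 && g$alpha < g$beta && g$beta < 1))
    stop("normalised charge-region endpoints must satisfy 0 < alpha < beta < 1")
  if (p$epsilon <= 0) stop("epsilon must be positive")
  invisible(p)
}

#' Neutrality-deviation factors of the two baths
#'
#' The relaxed electroneutrality boundary conditions quantify the bath charge
#' imbalance by multiplicative factors: the cation charge equals `sigma`
#' (left) or `rho` (right) times the anion charge,
#' \deqn{\sigma = \frac{z (L_1 + L_2)}{-z_3 L_3}, \qquad
#'       \rho   = \frac{z (R_1 + R_2)}{-z_3 R_3}.}
#' `sigma = rho = 1` is the exactly electroneutral state.
#'
#' @param z,z3 Cation and anion valences (`z > 0`, `z3 < 0`).
#' @param L,R Bath concentration vectors of length 3.
#' @return Named numeric vector `c(sigma = , rho = )`.
#' @examples
#' neutral_deviation(1, -1, L = c(1, 1, 2), R = c(0.3, 0.7, 1))  # c(1, 1)
#' @export
neutral_deviation <- function(z, z3, L, R) {
  stopifnot(z > 0, z3 < 0, length(L) == 3L, length(R) == 3L)
  if (any(L <= 0) || any(R <= 0))
    stop("bath concentrations must be positive")
  c(sigma = z * (L[1] + L[2]) / (-z3 * L[3]),
    rho   = z * (R[1] + R[2]) / (-z3 * R[3]))
}

# Uniform cross-section profile (package-level so that generated parameter
# sets compare identical across calls).
.uniform_h <- function(x) rep(1, length(x))

#' Reduce a channel cross-section profile to its resistance coordinates
#'
#' The flux formulas depend on the cross-section profile `h(x)` only through
#' the channel resistance integral \eqn{H(x) = \int_0^x ds/h(s)}: the total
#' resistance `H1 = H(1)` and the normalised permanent-charge endpoints
#' `alpha = H(x1)/H(1)`, `beta = H(x2)/H(1)`.  For the uniform channel
#' (`h = 1`) these reduce to `H1 = 1`, `alpha = x1`, `beta = x2`.
#'
#' @param h `NULL` (uniform channel), a positive vectorised function on
#'   `[0, 1]`, or a `data.frame` with columns `x` and `h` that is interpolated
#'   by a monotone cubic spline.
#' @param x1,x2 Permanent-charge region endpoints, `0 < x1 < x2 < 1`.
#' @param rel_tol Relative tolerance of the adaptive quadrature.
#' @return List with `H1`, `alpha`, `beta` and the profile function `h`.
#' @examples
#' geometry_reduce(NULL, 1/3, 2/3)                       # H1 = 1
#' geometry_reduce(function(x) 1/(1 + x), 0.5, 0.8)      # H1 = 1.5
#' @export
geometry_reduce <- function(h, x1, x2, rel_tol = 1e-10) {
  if (!(x1 > 0 && x1 < x2 && x2 < 1))
    stop("permanent-charge region must satisfy 0 < x1 < x2 < 1")
  if (is.null(h)) {
    return(list(h = .uniform_h, H1 = 1, alpha = x1, beta = x2,
                uniform = TRUE))
  }
  if (is.data.frame(h)) {
    if (!all(c("x", "h") %in% names(h)))
      stop("profile table must have columns 'x' and 'h'")
    if (any(h$h <= 0)) stop("cross-section profile must be positive")
    sp <- stats::splinefun(h$x, h$h, method = "monoH.FC")
    hfun <- function(x) sp(x)
  } else if (is.function(h)) {
    hfun <- h
  } else stop("h must be NULL, a function, or a data.frame(x, h)")

  probe <- hfun(seq(0, 1, length.out = 201))
  if (any(!is.finite(probe)) || any(probe <= 0))
    stop("cross-section profile must be positive and finite on [0, 1]")

  inv <- function(x) 1 / hfun(x)
  quad <- function(a, b)
    stats::integrate(inv, a, b, rel.tol = rel_tol, abs.tol = 0,
                     subdivisions = 500L)$value
  Hx1 <- quad(0, x1)
  Hx2 <- Hx1 + quad(x1, x2)
  H1 <- Hx2 + quad(x2, 1)
  list(h = hfun, H1 = H1, alpha = Hx1 / H1, beta = Hx2 / H1, uniform = FALSE)
}

#' Convert between dimensional and dimensionless model quantities
#'
#' The model is posed in dimensionless variables: potentials are measured in
#' units of the thermal voltage `kB*T/e`, concentrations in units of a
#' characteristic number density `C0`, lengths in units of the channel length
#' `l`, and the dielectric parameter is
#' \deqn{\varepsilon^2 = \frac{\varepsilon_r \varepsilon_0 k_B T}{e^2 l^2 C_0}.}
#'
#' @param scales List with elements `l` (channel length, m), `C0`
#'   (characteristic number density, 1/m^3), `thermal_voltage` (`kB*T/e`, V)
#'   and optionally `eps_r` (relative dielectric coefficient, needed for
#'   `epsilon`).
#' @param V Dimensional potentials (V), or `NULL`.
#' @param conc Dimensional number densities (1/m^3), or `NULL`.
#' @param X Dimensional axial positions (m), or `NULL`.
#' @return For `nondimensionalize()`, a list with the dimensionless `V`, `conc`,
#'   `x`, and `epsilon` (when `eps_r` is given).  `dimensionalize()` is its
#'   exact inverse (round-trips to relative error below 1e-12).
#' @examples
#' sc <- list(l = 1, C0 = 1, thermal_voltage = 1)
#' nondimensionalize(sc, V = 2.5)$V   # identity scales: unchanged
#' @export
nondimensionalize <- function(scales, V = NULL, conc = NULL, X = NULL) {
  .check_scales(scales)
  out <- list()
  if (!is.null(V)) out$V <- V / scales$thermal_voltage
  if (!is.null(conc)) out$conc <- conc / scales$C0
  if (!is.null(X)) out$x <- X / scales$l
  if (!is.null(scales$eps_r)) {
    e <- 1.602176634e-19     # elementary charge, C
    eps0 <- 8.8541878128e-12 # vacuum permittivity, F/m
    out$epsilon <- sqrt(scales$eps_r * eps0 * scales$thermal_voltage /
                          (e * scales$l^2 * scales$C0))
  }
  out
}

#' @rdname nondimensionalize
#' @param v,c_,x Dimensionless potentials, concentrations, positions.
#' @export
dimensionalize <- function(scales, v = NULL, c_ = NULL, x = NULL) {
  .check_scales(scales)
  out <- list()
  if (!is.null(v)) out$V <- v * scales$thermal_voltage
  if (!is.null(c_)) out$conc <- c_ * scales$C0
  if (!is.null(x)) out$X <- x * scales$l
  out
}

.check_scales <- function(scales) {
  for (nm in c("l", "C0", "thermal_voltage")) {
    val <- scales[[nm]]
    if (is.null(val) || !is.finite(val) || val <= 0)
      stop(sprintf("scale '%s' must be a positive finite number", nm))
  }
  if (!is.null(scales$eps_r) && scales$eps_r <= 0)
    stop("eps_r must be positive")
  invisible(scales)
}

#' Boundary-layer limits of potential and concentrations at the channel ends
#'
#' Just inside each Debye boundary layer the potential and concentrations
#' relax from their bath values to electroneutral "inner" values: Boltzmann
#' factors connect the two edges of each Debye layer, and the inner edge is
#' electroneutral, which fixes the potential jump across the layer.  With
#' the neutrality deviations `sigma` (left) and `rho` (right),
#' \deqn{\phi^L = V + \frac{\ln\sigma}{z - z_3}, \qquad
#'       c_k^L = L_k\,\sigma^{-z/(z-z_3)}\ (k = 1,2), \qquad
#'       c_3^L = L_3\,\sigma^{-z_3/(z-z_3)},}
#' and the mirrored expressions with `rho` (and potential 0) on the right.
#' At `sigma = rho = 1` the limits coincide with the bath values.  The
#' formulas are exact for any positive deviation, not only near 1 (an
#' excess-cation bath, `sigma > 1`, pushes the layer potential up and dilutes
#' the cations at the inner edge; the full solver reproduces these limits as
#' the dielectric parameter shrinks).
#'
#' @param p A [pnp_params] object.
#' @return Object of class `pnp_inner_limits`: list with `phiL`, `phiR`,
#'   `c1L`, `c2L`, `c3L`, `c1R`, `c2R`, `c3R` and the cation totals
#'   `cL`, `cR`.
#' @examples
#' p <- pnp_params(1, -1, c(1, 1, 1), L = c(1, 1), R = c(0.3, 0.7),
#'                 sigma = exp(2), rho = 1, V = 0)
#' inner_limits(p)$phiL   # V + ln(sigma)/2 = 1
#' @export
inner_limits <- function(p) {
  validate_params(p)
  z <- p$valences$z; z3 <- p$valences$z3
  b <- p$baths
  ec <- -z / (z - z3)   # cation exponent
  ea <- -z3 / (z - z3)  # anion exponent
  out <- list(
    phiL = b$V + log(b$sigma) / (z - z3),
    phiR = log(b$rho) / (z - z3),
    c1L = b$L1 * b$sigma^ec, c2L = b$L2 * b$sigma^ec, c3L = b$L3 * b$sigma^ea,
    c1R = b$R1 * b$rho^ec, c2R = b$R2 * b$rho^ec, c3R = b$R3 * b$rho^ea
  )
  out$cL <- out$c1L + out$c2L
  out$cR <- out$c1R + out$c2R
  structure(out, class = "pnp_inner_limits")
}

#' @export
print.pnp_inner_limits <- function(x, ...) {
  cat("<pnp_inner_limits>\n")
  cat(sprintf("  left  (x = 0+): phi = %.6g, c = (%.6g, %.6g, %.6g)\n",
              x$phiL, x$c1L, x$c2L, x$c3L))
  cat(sprintf("  right (x = 1-): phi = %.6g, c = (%.6g, %.6g, %.6g)\n",
              x$phiR, x$c1R, x$c2R, x$c3R))
  invisible(x)
}

# Internal: params with species 3 reset to exact electroneutrality
# (sigma = rho = 1), all other fields unchanged.  Used by the flux-difference
# baseline runs.
neutralized_params <- function(p) {
  z <- p$valences$z; z3 <- p$valences$z3
  b <- p$baths
  pnp_params(z = z, z3 = z3,
             D = c(p$diffusion$D1, p$diffusion$D2, p$diffusion$D3),
             L = c(b$L1, b$L2), R = c(b$R1, b$R2),
             sigma = 1, rho = 1, V = b$V, Q0 = p$charge$Q0,
             x1 = p$charge$x1, x2 = p$charge$x2,
             h = if (isTRUE(p$geometry$uniform)) NULL else p$geometry$h,
             epsilon = p$epsilon)
}

# Internal: copy of p with a different transmembrane potential.
with_potential <- function(p, V) {
  p$baths$V <- V
  p
}
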