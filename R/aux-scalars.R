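# Scalar building blocks of the flux expansion.
#
# Every ratio here has numerator and denominator vanishing together as the
# concentration ratio t (or s) tends to 1, so each function carries two
# branches: the literal formula away from t = 1 and a truncated Taylor
# series (R/series-coeffs.R) inside |t - 1| < .t_series_switch, where double
# precision cancellation would otherwise destroy all significant digits.

.t_series_switch <- 1e-4   # series guard half-width in t and s
.w_series_switch <- 1e-6   # limit guard half-width in w = ln t + z V
.t_coefs_switch <- 0.35    # wider guard for the first-order coefficient
                           # closed forms, whose direct evaluation cancels
                           # through four powers of ln t

# (t - 1)/ln t
.fa <- function(t) {
  u <- t - 1
  if (abs(u) < .t_series_switch) .ser_a(u) else u / log1p(u)
}

# (t ln t - t + 1)/ln^2 t
.fb1 <- function(t) {
  u <- t - 1
  if (abs(u) < .t_series_switch) .ser_b1(u)
  else (t * log1p(u) - u) / log1p(u)^2  # t ln t - t + 1, without the 1 - t
                                        # cancellation through magnitude 1
}

# (t - 1 - ln t)/ln^2 t
.fb2 <- function(t) {
  u <- t - 1
  if (abs(u) < .t_series_switch) .ser_b2(u)
  else (t - 1 - log1p(u)) / log1p(u)^2
}

# [w(a) w(b) ln t ln(w(b)/w(a)) + (beta-alpha)(t-1)^2] / [w(a) w(b) ln^3 t]
.fP <- function(t, alpha, beta) {
  u <- t - 1
  if (abs(u) < .t_series_switch) return(.ser_P(u, alpha, beta))
  wa <- eval_omega(alpha, t); wb <- eval_omega(beta, t)
  lt <- log1p(u)  # accurate also for t near 1
  lab <- log1p(u * (alpha - beta) / wa)  # log(wb/wa), robust for wb ~ wa
  (wa * wb * lt * lab + (beta - alpha) * u^2) / (wa * wb * lt^3)
}

# (beta - alpha)(t-1)^2 / [w(a) w(b) ln^2 t]
.fQt <- function(t, alpha, beta) {
  u <- t - 1
  if (abs(u) < .t_series_switch) return(.ser_Qt(u, alpha, beta))
  wa <- eval_omega(alpha, t); wb <- eval_omega(beta, t)
  (beta - alpha) * u^2 / (wa * wb * log1p(u)^2)
}

# w / (1 - exp(-w)), the removable factor (ln t + zV)/(t - exp(-zV)) after
# pulling out 1/t; equals 1 at w = 0.  Vectorised over w.
.gw <- function(w) {
  out <- numeric(length(w))
  small <- abs(w) < .w_series_switch
  out[small] <- 1 + w[small] / 2 + w[small]^2 / 12
  ws <- w[!small]
  out[!small] <- ws / (-expm1(-ws))
  out
}

#' Neutrality-deviation weight function f
#'
#' The zeroth-order fluxes depend on the bath charge imbalance through
#' \deqn{f(x) = (x\ln x - x + 1)(\sigma - 1) + (x - 1 - \ln x)(\rho - 1).}
#' Both bracket factors are nonnegative for `x > 0` and vanish only at
#' `x = 1`, so `f >= 0` whenever `sigma >= 1` and `rho >= 1`.
#'
#' @param x Positive evaluation point(s) (a concentration ratio).
#' @param sigma,rho Neutrality deviations of the left and right bath.
#' @return Numeric vector of the same length as `x`.
#' @examples
#' eval_f(exp(1), 2, 1)   # e*1 - e + 1 = 1
#' @export
eval_f <- function(x, sigma, rho) {
  if (any(x <= 0)) stop("f is defined for positive arguments only")
  (x * log(x) - x + 1) * (sigma - 1) + (x - 1 - log(x)) * (rho - 1)
}

#' Zeroth-order total-concentration profile weight
#'
#' `eval_omega(x, t) = t + x(1 - t)` interpolates the scaled total cation
#' concentration between its left value `t = L/R` (at `x = 0`) and its right
#' value 1 (at `x = 1`) in the resistance coordinate `x = H(.)/H(1)`.
#'
#' @param x Position(s) in `[0, 1]` (resistance coordinate).
#' @param t Left/right concentration ratio, > 0.
#' @return `t + x * (1 - t)`.
#' @export
eval_omega <- function(x, t) {
  if (t <= 0) stop("concentration ratio t must be positive")
  if (any(x < 0 | x > 1)) stop("omega is defined on [0, 1]")
  t + x * (1 - t)
}

# Internal: truncated u-series (u = t - 1) of one coefficient closed form,
# rebuilt at run time from its monomial table (.coefs_tables).  The atoms
# n, v_a, v_b, ln n, ln v_a, ln v_b have elementary expansions; monomials
# are convolved with a shared power cache and the analytically-vanishing
# leading orders are dropped before the formal division, which is what
# makes this branch stable where the direct closed form cancels.
.series_conv <- function(A, B) {
  K <- length(A)
  out <- numeric(K)
  for (k in seq_len(K))
    out[k] <- sum(A[seq_len(k)] * B[k:1])
  out
}

.coeffs_corrected_series <- function(u, alpha, beta, z, z3, K = 26L) {
  kk <- seq_len(K - 1L)
  atoms <- list(
    c(1, 1, numeric(K - 2L)),                        # n = 1 + u
    c(1, 1 - alpha, numeric(K - 2L)),                # v_a
    c(1, 1 - beta, numeric(K - 2L)),                 # v_b
    c(0, (-1)^(kk + 1) / kk),                        # ln n
    c(0, (-1)^(kk + 1) * (1 - alpha)^kk / kk),       # ln v_a
    c(0, (-1)^(kk + 1) * (1 - beta)^kk / kk)         # ln v_b
  )
  cache <- vector("list", 6L)
  for (i in 1:6) cache[[i]] <- list(atoms[[i]])
  apow <- function(i, p) {
    while (length(cache[[i]]) < p)
      cache[[i]][[length(cache[[i]]) + 1L]] <<-
        .series_conv(cache[[i]][[length(cache[[i]])]], atoms[[i]])
    cache[[i]][[p]]
  }
  poly_series <- function(pows, coefs) {
    tot <- numeric(K)
    for (r in seq_along(coefs)) {
      cur <- NULL
      for (i in 1:6) {
        p <- pows[r, i]
        if (p > 0L) {
          s <- apow(i, p)
          cur <- if (is.null(cur)) s else .series_conv(cur, s)
        }
      }
      if (is.null(cur)) tot[1] <- tot[1] + coefs[r]
      else tot <- tot + coefs[r] * cur
    }
    tot
  }
  out <- list()
  for (nm in names(.coefs_tables)) {
    tab <- .coefs_tables[[nm]]
    nc <- poly_series(tab$num_pows, tab$num_coef(z, z3, alpha, beta))
    dc <- poly_series(tab$den_pows, tab$den_coef(z, z3, alpha, beta))
    sh <- tab$shift
    nc <- nc[(sh + 1L):K]
    dc <- dc[(sh + 1L):K]
    m <- length(nc)
    q <- numeric(m)
    for (k in seq_len(m))
      q[k] <- (nc[k] - sum(q[seq_len(k - 1L)] * dc[k:2])) / dc[1]
    # Horner evaluation at u
    val <- 0
    for (k in m:1) val <- q[k] + u * val
    out[[nm]] <- val
  }
  out
}

# Internal: corrected first-order coefficient bundle at ratio t, with the
# series branch taking over near t = 1 (all members have finite limits
# there, unlike the raw composite functions, whose direct evaluation
# cancels catastrophically through the ln^4 t denominators).
.coefs <- function(t, alpha, beta, z, z3) {
  u <- t - 1
  if (abs(u) < .t_coefs_switch) {
    .coeffs_corrected_series(u, alpha, beta, z, z3)
  } else {
    .coeffs_corrected(t, alpha, beta, z, z3)
  }
}

#' Composite coupling functions of the first-order flux coefficients
#'
#' Evaluates the composite scalar functions that couple the channel
#' geometry (`alpha`, `beta`), the bath concentration ratio `t = L/R` and
#' the valences into the first-order (permanent-charge) flux coefficients.
#'
#' For the cations the deviation coefficient is affine in the potential,
#' `J111(V) = z3 (z D V + F) / ((z - z3) omega(alpha)^2 omega(beta)^2
#' ln^4 t)`, and `Dbig`, `Fbig` are the slope and intercept carriers; the
#' coupling critical potential is `Vb = -F/(z D)`.  For the anion the
#' deviation coefficient is a plain quadratic in the potential,
#' `c0 + c1 V + c2 V^2`, whose real roots (0, 1 or 2 of them) are the
#' anion coupling critical potentials; the leading coefficient satisfies
#' the identity `c2 = -z/((z - z3)) * (cation slope)`.
#'
#' These closed forms derive from the exact first-order reduction of the
#' outer electroneutral system with the interior Debye-layer jump
#' conditions at the permanent-charge edges; they are validated against an
#' independent quadrature implementation of the same reduction and against
#' the full boundary-value solver (see the methods vignette for why they
#' differ from a naive reading of the run-on printed display they
#' reconstruct).
#'
#' @param p A [pnp_params] object.
#' @return List with `Dbig`, `Fbig` (cation family), `c0`, `c1`, `c2`
#'   (anion quadratic), and the ratios `t`, `s`.
#' @export
eval_DF <- function(p) {
  z <- p$valences$z; z3 <- p$valences$z3
  g <- p$geometry; b <- p$baths
  t <- (b$L1 + b$L2) / (b$R1 + b$R2)
  s <- b$L3 / b$R3
  co <- .coefs(t, g$alpha, g$beta, z, z3)
  wa <- eval_omega(g$alpha, t); wb <- eval_omega(g$beta, t)
  lt4 <- log1p(t - 1)^4
  list(
    Dbig = co$catB * (z - z3) * wa^2 * wb^2 * lt4 / (z * z3),
    Fbig = co$catA * (z - z3) * wa^2 * wb^2 * lt4 / z3,
    c0 = co$an_c0, c1 = co$an_c1, c2 = co$an_c2,
    t = t, s = s
  )
}

#' First-order flux coefficient functions
#'
#' The first-order-in-`Q0` fluxes decompose into species prefactors times
#' coefficient functions of the concentration ratio, geometry and
#' valences:
#' \describe{
#'   \item{`J110`}{cation neutral-state coefficient, affine in `V`;}
#'   \item{`J111`}{cation deviation coefficient (multiplies
#'     `sigma - rho`), affine in `V` with root `Vb`;}
#'   \item{`J310`}{anion neutral-state coefficient, affine in `V`;}
#'   \item{`J3dev`}{anion deviation coefficient (multiplies
#'     `sigma - rho`), a quadratic polynomial in `V` -- it does not factor
#'     through the anion driving prefactor, so unlike the cations the
#'     anion difference term need not vanish at the anion reversal
#'     potential.}
#' }
#' All evaluations switch to series expansions near `t = 1`.
#'
#' @param p A [pnp_params] object.
#' @param V Potential(s) at which to evaluate; defaults to `p$baths$V`.
#' @return List of numeric vectors `J110`, `J111`, `J310`, `J3dev`
#'   matching `length(V)`.
#' @export
first_order_coeffs <- function(p, V = p$baths$V) {
  z <- p$valences$z; z3 <- p$valences$z3
  g <- p$geometry; b <- p$baths
  t <- (b$L1 + b$L2) / (b$R1 + b$R2)
  al <- g$alpha; be <- g$beta
  co <- .coefs(t, al, be, z, z3)
  list(J110 = -z3 * .fP(t, al, be) * V - .fQt(t, al, be),
       J111 = co$catA + co$catB * V,
       J310 = -z * .fP(t, al, be) * V - .fQt(t, al, be),
       J3dev = co$an_c0 + co$an_c1 * V + co$an_c2 * V^2)
}

#' All auxiliary scalars of the flux expansion at one parameter set
#'
#' Convenience bundle: concentration ratios, omega values at the
#' permanent-charge endpoints, the composite coupling functions, the four
#' first-order coefficient functions at the configured potential, and the
#' general-boundary-condition auxiliaries `lam` (the log-mean slope
#' lambda), `M` and `N`.  `lam`, `M` and `N` are reported for completeness
#' and documentation; no flux path of this package consumes them (the general
#' first-order expansion they belong to requires interior matching unknowns
#' that are outside this package's scope).
#'
#' @param p A [pnp_params] object.
#' @return A list of named scalars.
#' @export
aux_scalars <- function(p) {
  g <- p$geometry
  df <- eval_DF(p)
  fc <- first_order_coeffs(p)
  il <- inner_limits(p)

  lnC <- log(il$cL) - log(il$cR)
  lam <- if (abs(lnC) < 1e-12) NA_real_ else (il$phiL - il$phiR) / lnC
  tc <- il$cL / il$cR
  C01 <- il$cR * eval_omega(g$alpha, tc)  # zeroth-order totals at x1, x2
  C02 <- il$cR * eval_omega(g$beta, tc)
  M <- if (abs(lnC) < 1e-12) NA_real_ else
    (il$cR - il$cL) * (C01 - C02) / (C01 * C02 * lnC)
  N <- if (is.na(M) || abs(M) < 1e-300) NA_real_ else
    (log(C02) - log(C01)) / M

  c(list(t = df$t, s = df$s,
         omega_alpha = eval_omega(g$alpha, df$t),
         omega_beta = eval_omega(g$beta, df$t),
         Dbig = df$Dbig, Fbig = df$Fbig,
         c0 = df$c0, c1 = df$c1, c2 = df$c2),
    fc, list(lam = lam, M = M, N = N))
}
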