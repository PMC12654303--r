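# Finite-difference sensitivities of the numerical fluxes in Q0, used to
# confront the analytic first-order coefficients with the BVP solver.

#' Numerical estimate of the first-order flux coefficients Jk1
#'
#' Solves the full BVP at `Q0 = 0` and at each requested permanent-charge
#' step, forms the one-sided difference quotients `(Jk(q) - Jk(0))/q` and
#' Richardson-extrapolates them to `q -> 0` (the quotients of an expansion
#' `Jk0 + q Jk1 + O(q^2)` converge linearly in `q`, so with steps `q` and
#' `q/2` the combination `2 E(q/2) - E(q)` cancels the leading remainder).
#'
#' @param p A [pnp_params] object.
#' @param mesh A [mesh_config()].
#' @param q_steps Decreasing positive permanent-charge steps (at least two;
#'   each subsequent step should halve the previous for the extrapolation).
#' @param epsilon Dielectric parameter of the runs.
#' @return List with `J1` (extrapolated, named vector), `quotients` (matrix
#'   of raw difference quotients, one row per step) and `step_dependence`
#'   (max relative change between the two finest quotients, a diagnostic of
#'   how far from the asymptotic regime the steps are).
#' @export
numeric_flux_sensitivity <- function(p, mesh = mesh_config(),
                                     q_steps = c(0.02, 0.01),
                                     epsilon = p$epsilon) {
  stopifnot(length(q_steps) >= 2, all(q_steps > 0), all(q_steps <= 0.1),
            all(diff(q_steps) < 0))
  base <- solve_pnp(p, mesh, epsilon = epsilon, Q0 = 0)
  quot <- matrix(NA_real_, length(q_steps), 3,
                 dimnames = list(NULL, c("J1", "J2", "J3")))
  sol <- base
  for (i in seq_along(q_steps)) {
    sol <- solve_pnp(p, mesh, epsilon = epsilon, Q0 = q_steps[i], init = sol)
    quot[i, ] <- (sol$J - base$J) / q_steps[i]
  }
  m <- length(q_steps)
  extrap <- (q_steps[m - 1] * quot[m, ] - q_steps[m] * quot[m - 1, ]) /
    (q_steps[m - 1] - q_steps[m])
  list(J1 = extrap, quotients = quot,
       step_dependence = max(abs(quot[m, ] - quot[m - 1, ]) /
                               pmax(abs(extrap), 1e-12)))
}

#' Numerical estimate of the flux-difference coefficients Jkd1
#'
#' Estimates `Jkd1 = d/dQ0 [Jk(sigma, rho; Q0) - Jk(1, 1; Q0)]` at `Q0 = 0`
#' from four BVP solves per step: the configured baths and their neutralised
#' companion (species 3 rescaled to exact electroneutrality), each at
#' `Q0 = 0` and at the step, followed by Richardson extrapolation as in
#' [numeric_flux_sensitivity()].
#'
#' @inheritParams numeric_flux_sensitivity
#' @return List with `Jd1` (extrapolated, named), `quotients`, and the two
#'   zero-charge flux differences `Jd0_numeric`.
#' @export
numeric_flux_difference_sensitivity <- function(p, mesh = mesh_config(),
                                                q_steps = c(0.02, 0.01),
                                                epsilon = p$epsilon) {
  stopifnot(length(q_steps) >= 2, all(q_steps > 0), all(diff(q_steps) < 0))
  pn <- neutralized_params(p)
  base_s <- solve_pnp(p, mesh, epsilon = epsilon, Q0 = 0)
  base_n <- solve_pnp(pn, mesh, epsilon = epsilon, Q0 = 0, init = base_s)
  quot <- matrix(NA_real_, length(q_steps), 3,
                 dimnames = list(NULL, c("J1", "J2", "J3")))
  sol_s <- base_s; sol_n <- base_n
  for (i in seq_along(q_steps)) {
    sol_s <- solve_pnp(p, mesh, epsilon = epsilon, Q0 = q_steps[i],
                       init = sol_s)
    sol_n <- solve_pnp(pn, mesh, epsilon = epsilon, Q0 = q_steps[i],
                       init = sol_n)
    quot[i, ] <- ((sol_s$J - base_s$J) - (sol_n$J - base_n$J)) / q_steps[i]
  }
  m <- length(q_steps)
  extrap <- (q_steps[m - 1] * quot[m, ] - q_steps[m] * quot[m - 1, ]) /
    (q_steps[m - 1] - q_steps[m])
  list(Jd1 = extrap, quotients = quot,
       Jd0_numeric = base_s$J - base_n$J)
}

#' Locate a sign change of a scalar function of the potential
#'
#' Thin wrapper around Brent root finding with an explicit bracketing check:
#' refuses to "find" a root where the function does not change sign.
#'
#' @param fn Function of one numeric argument (typically `V`).
#' @param bracket Length-2 interval with a sign change of `fn`.
#' @param tol Absolute tolerance on the root (use around 1e-9 for analytic
#'   integrands, 1e-3 or coarser for BVP-backed ones).
#' @return The located root.
#' @export
detect_zero_crossing <- function(fn, bracket, tol = 1e-9) {
  stopifnot(length(bracket) == 2L, bracket[1] < bracket[2])
  fa <- fn(bracket[1]); fb <- fn(bracket[2])
  if (!is.finite(fa) || !is.finite(fb))
    stop("function not finite at bracket endpoints")
  if (sign(fa) * sign(fb) > 0)
    stop("no sign change over the bracket [", bracket[1], ", ",
         bracket[2], "]")
  if (fa == 0) return(bracket[1])
  if (fb == 0) return(bracket[2])
  stats::uniroot(fn, interval = bracket, tol = tol)$root
}
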