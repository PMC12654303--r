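# Unit checks of the BVP solver at moderate epsilon (the deep-asymptotics
# comparisons at epsilon = 1e-4 live in the acceptance suite).

test_that("equilibrium boundary data yields zero flux to solver precision", {
  p <- pnp_params(1, -1, c(1, 1, 1), L = c(1, 1, 2), R = c(1, 1, 2),
                  V = 0, Q0 = 0.03, epsilon = 1e-2)
  sol <- solve_pnp(p)
  expect_true(sol$converged)
  expect_lt(max(abs(sol$J)), 1e-8)
  # Boltzmann relation: concentrations stay positive and profiles smooth
  expect_true(all(sol$c1 > 0 & sol$c2 > 0 & sol$c3 > 0))
})

test_that("mirror-image configurations carry negated fluxes", {
  pa <- pnp_params(1, -1, c(1, 1, 1), L = c(1, 1), R = c(0.3, 0.7),
                   sigma = 1.05, rho = 0.95, V = 0.7, Q0 = 0.02,
                   x1 = 0.3, x2 = 0.7, epsilon = 1e-2)
  pb <- pnp_params(1, -1, c(1, 1, 1), L = c(0.3, 0.7), R = c(1, 1),
                   sigma = 0.95, rho = 1.05, V = -0.7, Q0 = 0.02,
                   x1 = 0.3, x2 = 0.7, epsilon = 1e-2)
  sa <- solve_pnp(pa); sb <- solve_pnp(pb)
  expect_lt(max(abs(sa$J + sb$J) / abs(sa$J)), 1e-6)
})

test_that("solved fluxes approach the asymptotic formulas as eps shrinks", {
  # relaxed baths: the mismatch is already inside the second-order
  # deviation remainder at moderate eps
  p <- ref_params(V = 0.5)
  J0 <- zeroth_order_flux(p)
  sol <- solve_pnp(p, epsilon = 1e-3, Q0 = 0)
  expect_lt(max(abs(sol$J - J0) / abs(J0)), 0.01)
  # exactly neutral baths: pure eps-refinement is monotone down to the
  # solver discretisation floor
  pn <- ref_params(sigma = 1, rho = 1, V = 0.5)
  Jn <- zeroth_order_flux(pn)
  gaps <- vapply(c(3e-2, 1e-2, 3e-3), function(eps) {
    s <- solve_pnp(pn, epsilon = eps, Q0 = 0)
    max(abs(s$J - Jn) / abs(Jn))
  }, numeric(1))
  expect_true(all(diff(gaps) < 1e-6))
})

test_that("profile reconstruction reproduces the constant fluxes", {
  p <- ref_params(V = 0.4, epsilon = 3e-3)
  sol <- solve_pnp(p, Q0 = 0.02)
  pw <- pointwise_flux(sol, p)
  # away from the layers the centred-difference flux matches the global
  # flux unknowns closely
  interior <- sol$x[-1] > 0.05 & sol$x[-length(sol$x)] < 0.95
  for (k in 1:3) {
    expect_lt(max(abs(pw[interior, k] - sol$J[k]) / abs(sol$J[k])), 5e-3)
  }
})

test_that("boundary layers reproduce the inner-limit potential jump", {
  # for sigma != 1 the potential drops by ln(sigma)/(z - z3) across the
  # left Debye layer
  p <- pnp_params(1, -1, c(1, 1, 1), L = c(1, 1), R = c(0.3, 0.7),
                  sigma = 1.2, rho = 1, V = 0, epsilon = 1e-3)
  sol <- solve_pnp(p)
  il <- inner_limits(p)
  jump_expected <- il$phiL - p$baths$V
  # potential just inside the left layer (a few layer widths in)
  probe <- which.min(abs(sol$x - 30 * p$epsilon))
  jump_numeric <- sol$phi[probe] - p$baths$V
  expect_lt(abs(jump_numeric - jump_expected) / abs(jump_expected), 0.1)
})

test_that("the solver reports failure rather than returning garbage", {
  p <- ref_params(epsilon = 1e-2)
  expect_error(solve_pnp(p, mesh_config(max_nodes = 50L)), "max_nodes")
  bad <- mesh_config(epsilon_schedule = c(1e-1, 1e-2), tol = 1e-9)
  # absurd charge amplitude at large eps jump: Newton must either converge
  # or raise a labelled solver error -- never return unconverged output
  res <- tryCatch(solve_pnp(p, bad, epsilon = 1e-2, Q0 = 80),
                  error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "converge|concentrations")
  } else {
    expect_true(res$converged)
  }
})

test_that("warm starts reproduce cold-start solutions", {
  p <- ref_params(V = 0.3, epsilon = 3e-3)
  cold <- solve_pnp(p, Q0 = 0.02)
  warm <- solve_pnp(p, Q0 = 0.02,
                    init = solve_pnp(p, Q0 = 0))
  expect_lt(max(abs(cold$J - warm$J)), 1e-9)
})
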