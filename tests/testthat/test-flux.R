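test_that("zeroth-order fluxes reproduce the worked reference values", {
  p <- pnp_params(1, -1, c(1, 1, 1), L = c(1, 1, 2), R = c(0.3, 0.7, 1))
  J <- zeroth_order_flux(p, V = 0)
  expect_equal(unname(J), c(0.7, 0.3, 1.0), tolerance = 1e-12)
})

test_that("fluxes vanish at equilibrium and at the reversal potentials", {
  # identical baths, no potential: detailed balance
  pe <- pnp_params(2, -1, c(1.3, 0.8, 1.1), L = c(0.5, 1.2, 3.4),
                   R = c(0.5, 1.2, 3.4), V = 0)
  expect_equal(unname(zeroth_order_flux(pe)), c(0, 0, 0), tolerance = 1e-14)
  expect_equal(unname(general_zeroth_flux(pe)), c(0, 0, 0), tolerance = 1e-14)
  # neutral baths: Jk0 vanishes exactly at Vka, J30 at V3a
  p <- pnp_params(1, -1, c(1, 1, 1), L = c(1, 1, 2), R = c(0.3, 0.7, 1))
  cp <- critical_potentials(p)
  expect_equal(zeroth_order_flux(p, cp$V1a)[["J1"]], 0, tolerance = 1e-14)
  expect_equal(zeroth_order_flux(p, cp$V2a)[["J2"]], 0, tolerance = 1e-14)
  expect_equal(zeroth_order_flux(p, cp$V3a)[["J3"]], 0, tolerance = 1e-14)
})

test_that("general zeroth fluxes agree with the expansion at neutrality", {
  # transcription cross-check: the two independently transcribed formula
  # routes must coincide when sigma = rho = 1
  ps <- make_params(fixture_spec(seed = 11, n = 20))
  for (p in ps) {
    pn <- pnpcrit:::neutralized_params(p)
    a <- zeroth_order_flux(pn)
    b <- general_zeroth_flux(pn)
    expect_lt(max(rel_err(b, a)), 1e-10)
  }
})

test_that("general zeroth fluxes track the relaxed boundary conditions", {
  # away from neutrality the expanded and general routes agree to first
  # order in (sigma - 1, rho - 1): difference is O(deviation^2)
  for (d in c(0.02, 0.01, 0.005)) {
    p <- ref_params(sigma = 1 + d, rho = 1 - d, V = 0.4)
    gap <- max(abs(general_zeroth_flux(p) - zeroth_order_flux(p)))
    expect_lt(gap, 5 * d^2)
  }
})

test_that("the flux expansion is affine in the permanent charge", {
  p <- ref_params(V = -0.6, Q0 = 0.02)
  fe <- flux_expansion(p)
  expect_equal(fe$total(0), fe$J0)
  q <- 0.013
  expect_equal(fe$total(2 * q) - fe$total(q), q * fe$J1, tolerance = 1e-12)
  expect_equal(fe$total(q), fe$J0 + q * fe$J1)
})

test_that("first-order fluxes separate symmetric and antisymmetric parts", {
  # at sigma = rho the deviation contributions cancel: the first-order
  # fluxes equal the neutral-state coefficients (evaluated at the cation
  # ratio t, which equal deviations leave unchanged)
  p_eq <- ref_params(sigma = 1.03, rho = 1.03, V = 0.9)
  fc <- first_order_coeffs(p_eq)
  J1_eq <- first_order_flux(p_eq)
  t <- (p_eq$baths$L1 + p_eq$baths$L2) / (p_eq$baths$R1 + p_eq$baths$R2)
  expect_equal(J1_eq[["J3"]],
               -p_eq$diffusion$D3 * (log(t) - 0.9) / 2 * fc$J310,
               tolerance = 1e-12)
  # swapping sigma and rho flips the difference terms exactly (all three
  # species: the deviation coefficients depend on t only)
  pa <- ref_params(sigma = 1.04, rho = 0.97, V = 0.9)
  pb <- ref_params(sigma = 0.97, rho = 1.04, V = 0.9)
  da <- flux_difference(pa)$Jd1
  db <- flux_difference(pb)$Jd1
  expect_equal(unname(da), -unname(db), tolerance = 1e-9)
})

test_that("flux differences are consistent with the flux expansions", {
  # Jkd0 is the operational difference against the neutralised companion,
  # and Jkd1 equals the difference of the first-order fluxes, exactly
  p <- ref_params(sigma = 1.05, rho = 0.97, V = -0.3)
  pn <- pnpcrit:::neutralized_params(p)
  fd <- flux_difference(p)
  d0 <- zeroth_order_flux(p) - zeroth_order_flux(pn)
  expect_equal(unname(fd$Jd0), unname(d0), tolerance = 1e-12)
  d1 <- first_order_flux(p) - first_order_flux(pn)
  expect_equal(unname(fd$Jd1), unname(d1), tolerance = 1e-10)
})

test_that("flux differences vanish identically at matching deviations", {
  p0 <- ref_params(sigma = 1, rho = 1, V = 1.3)
  fd0 <- flux_difference(p0)
  expect_equal(unname(c(fd0$Jd0, fd0$Jd1)), rep(0, 6))
  # common deviation: only the Jd1 (sigma - rho) part vanishes
  pc <- ref_params(sigma = 1.05, rho = 1.05, V = 1.3)
  fdc <- flux_difference(pc)
  expect_equal(unname(fdc$Jd1), rep(0, 3))
  expect_true(all(abs(fdc$Jd0) > 0))
  # J1d1 vanishes at V = V1a regardless of deviations
  p <- ref_params(sigma = 1.07, rho = 0.94)
  cp <- critical_potentials(p)
  expect_equal(flux_difference(p, cp$V1a)$Jd1[["J1"]], 0, tolerance = 1e-15)
})

test_that("flux evaluation is continuous across its removable potential", {
  p <- ref_params(sigma = 1.01, rho = 0.99)
  t <- 2
  Vstar <- -log(t)  # z = 1
  for (off in c(1e-7, 1e-5)) {
    a <- zeroth_order_flux(p, Vstar + off)
    b <- zeroth_order_flux(p, Vstar - off)
    expect_lt(max(rel_err(a, b)), 50 * off)
  }
})
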