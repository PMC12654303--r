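test_that("parameter validation enforces the model invariants", {
  expect_error(pnp_params(-1, -1, c(1, 1, 1), c(1, 1, 2), c(1, 1, 2)),
               "z must be positive")
  expect_error(pnp_params(1, 1, c(1, 1, 1), c(1, 1, 2), c(1, 1, 2)),
               "z3 must be negative")
  expect_error(pnp_params(1, -1, c(1, 1, 1), c(1, 1, 0), c(1, 1, 2)),
               "positive")
  expect_error(pnp_params(1, -1, c(1, 1, 1), c(1, 1, 2), c(1, 1, 2),
                          x1 = 0.7, x2 = 0.3), "x1 < x2")
  expect_error(pnp_params(1, -1, c(1, 1, 1), c(1, 1), c(1, 1)),
               "sigma and rho")
  # supplying both L3 and an inconsistent sigma is rejected
  expect_error(pnp_params(1, -1, c(1, 1, 1), c(1, 1, 2), c(1, 1, 2),
                          sigma = 1.3), "inconsistent")
})

test_that("neutrality deviations follow the bath charge balance", {
  expect_identical(neutral_deviation(1, -1, c(1, 1, 2), c(1, 1, 2)),
                   c(sigma = 1, rho = 1))
  expect_equal(neutral_deviation(1, -1, c(1, 1, 2.5), c(1, 1, 2))[["sigma"]],
               0.8)
  expect_equal(neutral_deviation(2, -1, c(1, 1, 4), c(1, 1, 4))[["sigma"]], 1)
  expect_error(neutral_deviation(1, -1, c(1, 1, 0), c(1, 1, 1)), "positive")
  # derived-anion constructor realises the requested deviations exactly
  p <- pnp_params(2, -2, c(1, 1, 1), L = c(0.4, 1.1), R = c(2, 0.25),
                  sigma = 1.07, rho = 0.93)
  sr <- neutral_deviation(2, -2, c(p$baths$L1, p$baths$L2, p$baths$L3),
                          c(p$baths$R1, p$baths$R2, p$baths$R3))
  expect_equal(sr[["sigma"]], 1.07, tolerance = 1e-12)
  expect_equal(sr[["rho"]], 0.93, tolerance = 1e-12)
})

test_that("geometry reduction maps profiles to resistance coordinates", {
  g <- geometry_reduce(NULL, 1/3, 2/3)
  expect_equal(c(g$H1, g$alpha, g$beta), c(1, 1/3, 2/3))
  g2 <- geometry_reduce(function(x) rep(2, length(x)), 1/3, 2/3)
  expect_equal(c(g2$H1, g2$alpha, g2$beta), c(0.5, 1/3, 2/3),
               tolerance = 1e-10)
  # closed form for h(x) = 1/(1+x): H(x) = x + x^2/2
  g3 <- geometry_reduce(function(x) 1 / (1 + x), 0.5, 0.8)
  expect_equal(g3$H1, 1.5, tolerance = 1e-10)
  expect_equal(g3$alpha, 0.625 / 1.5, tolerance = 1e-10)
  expect_equal(g3$beta, 1.12 / 1.5, tolerance = 1e-10)
  expect_error(geometry_reduce(function(x) x - 0.5, 1/3, 2/3), "positive")
})

test_that("alpha and beta are invariant under profile rescaling", {
  for (cc in c(0.2, 3, 17)) {
    g <- geometry_reduce(function(x) cc * (1 + 0.5 * sin(pi * x)), 0.3, 0.8)
    g1 <- geometry_reduce(function(x) 1 + 0.5 * sin(pi * x), 0.3, 0.8)
    expect_equal(g$alpha, g1$alpha, tolerance = 1e-9)
    expect_equal(g$beta, g1$beta, tolerance = 1e-9)
    expect_equal(g$H1 * cc, g1$H1, tolerance = 1e-9)
  }
})

test_that("nondimensionalisation round-trips and scales as defined", {
  sc <- list(l = 1, C0 = 1, thermal_voltage = 1)
  expect_equal(nondimensionalize(sc, V = 2.5)$V, 2.5)
  sc2 <- list(l = 5e-9, C0 = 6.022e26, thermal_voltage = 25.85e-3,
              eps_r = 80)
  nd <- nondimensionalize(sc2, V = 25.85e-3, conc = c(3.011e26), X = 2.5e-9)
  expect_equal(nd$V, 1.0, tolerance = 1e-12)
  expect_equal(nd$conc, 0.5, tolerance = 1e-12)
  expect_equal(nd$x, 0.5, tolerance = 1e-12)
  back <- dimensionalize(sc2, v = nd$V, c_ = nd$conc, x = nd$x)
  expect_equal(back$V, 25.85e-3, tolerance = 1e-12)
  expect_equal(back$conc, 3.011e26, tolerance = 1e-12)
  expect_equal(back$X, 2.5e-9, tolerance = 1e-12)
  # epsilon^2 is proportional to 1/l^2
  sc3 <- sc2; sc3$l <- 2 * sc2$l
  e1 <- nondimensionalize(sc2)$epsilon
  e2 <- nondimensionalize(sc3)$epsilon
  expect_equal(e1^2 / e2^2, 4, tolerance = 1e-12)
  expect_error(nondimensionalize(list(l = -1, C0 = 1, thermal_voltage = 1)),
               "positive")
})

test_that("boundary-layer limits reduce to bath values at neutrality", {
  p <- ref_params(sigma = 1, rho = 1, V = 0.7)
  il <- inner_limits(p)
  expect_equal(il$phiL, 0.7)
  expect_equal(il$phiR, 0)
  expect_equal(c(il$c1L, il$c2L, il$c3L),
               c(p$baths$L1, p$baths$L2, p$baths$L3))
  expect_equal(c(il$c1R, il$c2R, il$c3R),
               c(p$baths$R1, p$baths$R2, p$baths$R3))
})

test_that("boundary-layer limits obey the closed forms off neutrality", {
  # z = 1, z3 = -1: cation exponent -z/(z-z3) = -1/2, so sigma = e^2 gives
  # phiL = V + 1 and c1L = L1/e (an excess-cation bath raises the layer
  # potential, which dilutes cations and concentrates anions inside)
  p <- pnp_params(1, -1, c(1, 1, 1), L = c(1, 1), R = c(0.3, 0.7),
                  sigma = exp(2), rho = 1, V = 0.25)
  il <- inner_limits(p)
  expect_equal(il$phiL, 0.25 + 1, tolerance = 1e-14)
  expect_equal(il$c1L, exp(-1), tolerance = 1e-14)
  expect_equal(il$c3L, p$baths$L3 * exp(1), tolerance = 1e-14)
  # one-sided deviation leaves the right limits untouched
  expect_equal(il$phiR, 0)
  expect_equal(c(il$c1R, il$c2R, il$c3R),
               c(p$baths$R1, p$baths$R2, p$baths$R3))
})

test_that("inner limits are continuous at neutrality with the stated slope", {
  # d(phiL)/d(sigma) at sigma = 1 equals +1/(z - z3)
  z <- 2; z3 <- -1
  h <- 1e-6
  phiL <- function(sg) {
    p <- pnp_params(z, z3, c(1, 1, 1), L = c(1, 1), R = c(1, 1),
                    sigma = sg, rho = 1, V = 0)
    inner_limits(p)$phiL
  }
  slope <- (phiL(1 + h) - phiL(1 - h)) / (2 * h)
  expect_equal(slope, 1 / (z - z3), tolerance = 1e-6)
  expect_equal(phiL(1 + h), h / (z - z3), tolerance = 1e-5)
})
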