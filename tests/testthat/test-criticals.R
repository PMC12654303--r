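test_that("reversal potentials follow the Nernst-type closed forms", {
  p <- pnp_params(1, -1, c(1, 1, 1), L = c(1, 1, 2), R = c(1, 0.3, 1.3))
  cp <- critical_potentials(p)
  expect_equal(cp$V1a, 0)
  expect_equal(cp$V2a, -log(1 / 0.3), tolerance = 1e-14)
  expect_equal(cp$V3a, log(2 / 1.3), tolerance = 1e-14)
  p2 <- pnp_params(2, -1, c(1, 1, 1), L = c(1, 1), R = c(0.3, 0.7),
                   sigma = 1, rho = 1)
  expect_equal(critical_potentials(p2)$V1a, -log(1 / 0.3) / 2,
               tolerance = 1e-14)
})

test_that("coupling potentials are the roots of the coefficient functions", {
  p <- ref_params(sigma = 1.03, rho = 0.96)
  cp <- critical_potentials(p)
  expect_true(cp$Vb_defined)
  # J111(Vb) = 0 by construction, and Vb equals the bisection root of J1d1
  expect_lt(abs(first_order_coeffs(p, cp$Vb)$J111), 1e-14)
  rootb <- detect_zero_crossing(
    function(v) flux_difference(p, v)$Jd1[["J1"]],
    cp$Vb + c(-0.3, 0.3), tol = 1e-12)
  expect_lt(abs(rootb - cp$Vb), 1e-9)
  # anion: a configuration with two real quadratic roots; J3dev vanishes
  # at both and J3d1 changes sign there
  p2 <- pnp_params(1, -1, c(1, 1, 1), L = c(1, 1), R = c(0.5, 0.5),
                   sigma = 1.05, rho = 0.95, x1 = 0.5, x2 = 0.95)
  cp2 <- critical_potentials(p2)
  expect_true(cp2$Vc_defined)
  for (vc in c(cp2$Vc_lo, cp2$Vc_hi)) {
    expect_lt(abs(first_order_coeffs(p2, vc)$J3dev), 1e-12)
    rootc <- detect_zero_crossing(
      function(v) flux_difference(p2, v)$Jd1[["J3"]],
      vc + c(-0.5, 0.5), tol = 1e-12)
    expect_lt(abs(rootc - vc), 1e-9)
  }
})

test_that("degenerate coupling is flagged, not raised", {
  sp <- special_case_params()
  cp <- critical_potentials(sp$ii_hi)
  expect_false(cp$Vb_defined)
  expect_true(is.na(cp$Vb))
  # rootless anion quadratic: flagged undefined, no error
  cpa <- critical_potentials(sp$anion_a1o)
  expect_false(cpa$Vc_defined)
  expect_true(is.na(cpa$Vc_lo) && is.na(cpa$Vc_hi))
})

test_that("zero crossings of the cation difference term are exactly {Vka, Vb}", {
  ps <- make_params(fixture_spec(seed = 5, n = 10))
  for (p in ps) {
    cp <- critical_potentials(p)
    if (!cp$Vb_defined) next
    for (k in 1:2) {
      va <- if (k == 1) cp$V1a else cp$V2a
      roots <- sort(c(va, cp$Vb))
      if (diff(roots) < 1e-6) next
      fn <- function(v) flux_difference(p, v)$Jd1[[k]]
      mid <- mean(roots)
      for (r0 in roots) {
        w <- min(1, abs(mid - r0))
        got <- detect_zero_crossing(fn, r0 + c(-w, w), tol = 1e-12)
        expect_lt(abs(got - r0), 1e-9)
      }
      # no further crossing inside the middle interval: sign is constant
      grid <- seq(roots[1] + 1e-3, roots[2] - 1e-3, length.out = 25)
      sgns <- unique(sign_sample_oracle(p, k, grid))
      expect_length(sgns, 1)
    }
  }
})

test_that("classification matches brute-force sampling on seeded sets", {
  reports <- theorem_consistency(n_sets = 15, seed = 3, n_grid = 400,
                                 include_special = FALSE)
  for (r in reports)
    for (s in r$species)
      expect_equal(s$agreement, 1)
})

test_that("constructed special cases exercise every regime label", {
  sp <- special_case_params()
  labs <- vapply(names(sp), function(nm)
    classify_regime(sp[[nm]], if (grepl("anion", nm)) 3L else 1L)$case_label,
    character(1))
  expect_equal(unname(labs[c("i1", "i2", "i3")]), c("i1", "i2", "i3"))
  expect_equal(unname(labs[c("iii1", "iii2", "iii3")]),
               c("iii1", "iii2", "iii3"))
  expect_setequal(unname(labs[c("ii_hi", "ii_lo")]), c("ii1", "ii2"))
  expect_equal(unname(labs[["anion_a2"]]), "a2")
  expect_equal(unname(labs[["anion_a1o"]]), "a1o")
})

test_that("swapping the deviations flips every sign in the pattern", {
  p <- ref_params(sigma = 1.06, rho = 0.95)
  q <- ref_params(sigma = 0.95, rho = 1.06)
  for (k in 1:3) {
    a <- classify_regime(p, k)
    b <- classify_regime(q, k)
    # cation breakpoints depend only on the (unchanged) cation ratio t;
    # anion breakpoints move with the species-3 concentrations, which the
    # deviation swap rescales, so compare them only loosely there
    if (k < 3) expect_equal(a$breakpoints, b$breakpoints)
    else expect_equal(a$breakpoints, b$breakpoints, tolerance = 0.3)
    expect_equal(pnpcrit:::.flip_signs(a$signs), b$signs)
  }
  # equal deviations: the everywhere-zero pattern
  z <- classify_regime(ref_params(sigma = 1.01, rho = 1.01), 1)
  expect_equal(z$signs, "0")
  expect_length(z$breakpoints, 0)
})

test_that("patterns collapse continuously as the breakpoints merge", {
  # move V1a towards Vb: the middle interval shrinks and the coincident
  # case becomes single-signed with the outer sign
  base <- ref_params(sigma = 1.05, rho = 0.95)
  cp <- critical_potentials(base)
  mk <- function(shift) {
    L1 <- base$baths$R1 * exp(-(cp$Vb + shift))
    pnp_params(1, -1, c(1, 1, 1), L = c(L1, 2 - L1),
               R = c(base$baths$R1, base$baths$R2),
               sigma = 1.05, rho = 0.95)
  }
  for (shift in c(0.1, 1e-3, 1e-6)) {
    pat <- classify_regime(mk(shift), 1)
    expect_equal(pat$case_label, "i1")
    expect_equal(diff(pat$breakpoints), shift, tolerance = 1e-6)
    expect_equal(pat$signs, c("+", "-", "+"))
  }
  pat0 <- classify_regime(mk(0), 1)
  expect_equal(pat0$case_label, "i2")
  expect_equal(pat0$signs, "+")
})

test_that("the sampling oracle reports signed patterns on grids", {
  p <- ref_params(sigma = 1.05, rho = 0.95)
  cp <- critical_potentials(p)
  # reference set is case i3 for species 1: V1a < Vb, pattern + / - / +
  grid <- c(cp$V1a - 1, (cp$V1a + cp$Vb) / 2, cp$Vb + 1)
  expect_equal(sign_sample_oracle(p, 1, grid), c("+", "-", "+"))
  expect_equal(sign_sample_oracle(ref_params(sigma = 1, rho = 1), 1, grid),
               rep("0", 3))
})
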