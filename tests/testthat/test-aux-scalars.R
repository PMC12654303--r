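test_that("the neutrality weight f has its closed-form special values", {
  expect_identical(eval_f(1, 1.7, 0.2), 0)
  x <- c(0.05, 0.3, 1, 2.7, 40)
  expect_equal(eval_f(x, 1, 1), rep(0, length(x)))
  expect_equal(eval_f(exp(1), 2, 1), 1, tolerance = 1e-14)
  expect_error(eval_f(-1, 1, 1), "positive")
})

test_that("f is nonnegative when both deviations exceed one", {
  set.seed(7)
  for (i in 1:50) {
    x <- exp(runif(1, -4, 4))
    sg <- 1 + runif(1, 0, 0.5); rh <- 1 + runif(1, 0, 0.5)
    expect_gte(eval_f(x, sg, rh), 0)
  }
})

test_that("omega interpolates the concentration ratio", {
  expect_equal(eval_omega(0, 2.7), 2.7)
  expect_equal(eval_omega(1, 2.7), 1)
  expect_equal(eval_omega(0.5, 2), 1.5)
  expect_error(eval_omega(1.5, 2), "\\[0, 1\\]")
  expect_error(eval_omega(0.5, -1), "positive")
})

test_that("coupling coefficients vanish for a degenerate charge region", {
  for (t in c(0.3, 2, 7)) {
    co <- pnpcrit:::.coeffs_corrected(t, 0.4, 0.4, 1, -1)
    expect_true(all(abs(unlist(co)) < 1e-14))
  }
  for (u in c(-0.05, 1e-3, 0.2)) {   # series branch within its radius
    cs <- pnpcrit:::.coeffs_corrected_series(u, 0.4, 0.4, 1, -1)
    expect_true(all(abs(unlist(cs)) < 1e-13))
  }
})

test_that("auxiliaries match the frozen arbitrary-precision transcription", {
  par <- oracle_params()
  orc <- oracle_values()
  for (i in seq_len(nrow(par))) {
    p <- params_from_row(par[i, ])
    got <- oracle_quantities(p)
    for (nm in names(got)) {
      expect_lt(rel_err(got[[nm]], orc[i, nm]), 1e-10,
                label = sprintf("row %d (%s) %s relative error",
                                i, par$variant[i], nm))
    }
  }
})

test_that("guarded ratios are continuous across t = 1", {
  # finite-limit ratios: series values at t = 1 +/- 1e-6 agree closely
  for (fn in list(pnpcrit:::.fa, pnpcrit:::.fb1, pnpcrit:::.fb2)) {
    expect_lt(rel_err(fn(1 + 1e-6), fn(1 - 1e-6)), 1e-5)
    # both branches agree at the switch boundary
    expect_lt(rel_err(fn(1 + 1.0000001e-4), fn(1 + 0.9999999e-4)), 1e-9)
  }
  al <- 0.27; be <- 0.81
  expect_lt(rel_err(pnpcrit:::.fP(1 + 1e-6, al, be),
                    pnpcrit:::.fP(1 - 1e-6, al, be)), 1e-5)
  expect_lt(rel_err(pnpcrit:::.fQt(1 + 1e-6, al, be),
                    pnpcrit:::.fQt(1 - 1e-6, al, be)), 1e-5)
  # the corrected coefficient functions have finite t -> 1 limits: series
  # evaluations straddling t = 1 agree to the expected smoothness
  sp_ <- pnpcrit:::.coeffs_corrected_series
  for (nm in c("catA", "catB", "an_c0", "an_c1", "an_c2")) {
    vp <- sp_(1e-6, al, be, 2, -1)[[nm]]
    vm <- sp_(-1e-6, al, be, 2, -1)[[nm]]
    expect_lt(abs(vp - vm) / max(abs(vp), abs(vm), 1e-300), 2e-5)
  }
  # direct and series branches agree at the switch boundary
  d <- pnpcrit:::.coeffs_corrected(1 + 0.36, al, be, 2, -1)
  s <- sp_(0.34, al, be, 2, -1)
  s2 <- sp_(0.36, al, be, 2, -1)
  for (nm in names(d)) {
    expect_lt(abs(d[[nm]] - s2[[nm]]) / max(abs(d[[nm]]), 1e-300), 1e-9)
  }
})

test_that("the removable potential factor is continuous in w", {
  g <- pnpcrit:::.gw
  expect_equal(g(0), 1)
  expect_lt(rel_err(g(1e-6 * 1.01), g(1e-6 * 0.99)), 1e-7)
  expect_lt(rel_err(g(-1e-6 * 1.01), g(-1e-6 * 0.99)), 1e-7)
  expect_equal(g(2), 2 / (1 - exp(-2)), tolerance = 1e-14)
})

test_that("documented-but-unused general auxiliaries are finite and exposed", {
  p <- ref_params()
  a <- aux_scalars(p)
  expect_true(all(is.finite(unlist(
    a[c("t", "s", "omega_alpha", "omega_beta", "Dbig", "Fbig",
        "c0", "c1", "c2", "J110", "J111", "J310", "J3dev",
        "lam", "M", "N")]))))
  # lam is the log-mean potential slope: at neutrality it reduces to
  # (V - 0)/ln(L/R)
  pn <- ref_params(sigma = 1, rho = 1, V = 0.8)
  an <- aux_scalars(pn)
  expect_equal(an$lam, 0.8 / log(2), tolerance = 1e-12)
})
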