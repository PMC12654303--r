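test_that("critical-potential recovery matches the closed forms", {
  p <- ref_params(sigma = 1.03, rho = 0.97)
  tab <- recover_critical_potentials(p)
  expect_equal(tab$potential,
               c("V1a", "V2a", "V3a", "Vb", "Vc_lo", "Vc_hi"))
  ok <- tab$defined
  expect_true(all(abs(tab$formula_root[ok] - tab$analytic[ok]) < 1e-9))
  # a configuration whose anion quadratic has two real roots: all six
  # rows recovered
  p2 <- pnp_params(1, -1, c(1, 1, 1), L = c(1, 1), R = c(0.5, 0.5),
                   sigma = 1.05, rho = 0.95, x1 = 0.5, x2 = 0.95)
  t2 <- recover_critical_potentials(p2)
  expect_true(all(t2$defined))
  expect_true(all(abs(t2$formula_root - t2$analytic) < 1e-9))
})

test_that("degenerate coupling rows are flagged as undefined", {
  sp <- special_case_params()
  tab <- recover_critical_potentials(sp$ii_hi)
  expect_false(tab$defined[tab$potential == "Vb"])
  expect_true(is.na(tab$formula_root[tab$potential == "Vb"]))
  # the reversal rows are still recovered
  expect_lt(abs(tab$formula_root[1] - tab$analytic[1]), 1e-9)
})

test_that("theorem consistency holds across seeded and constructed sets", {
  reports <- theorem_consistency(n_sets = 25, seed = 2, n_grid = 500)
  expect_gte(length(reports), 25)
  ok <- vapply(reports, function(r)
    all(vapply(r$species, function(s) s$agreement == 1, logical(1))),
    logical(1))
  expect_true(all(ok))
  # coverage of the coupling-sign cases and breakpoint orderings
  labs <- unlist(lapply(reports, function(r)
    vapply(r$species, `[[`, character(1), "case_label")))
  expect_true(any(labs == "i1") && any(labs == "i3"))  # D < 0, both orders
  expect_true(any(grepl("^iii", labs)))        # D > 0
  expect_true(any(grepl("^ii[12]$", labs)))    # D = 0
  expect_true(any(grepl("^a", labs)))          # anion quadratic cases
})

test_that("asymptotic-numeric comparison reports shrinking errors", {
  # pure eps-refinement at exactly neutral baths: the asymptotic error is
  # dominated by the dielectric parameter and must shrink monotonically
  p0 <- ref_params(sigma = 1, rho = 1, V = 0.5)
  rep0 <- compare_asymptotic_numeric(p0, eps_list = c(3e-2, 1e-2, 3e-3),
                                     q_list = c(0.02))
  tab0 <- rep0$table
  expect_true(all(c("eps", "Q0", "err", "rel_err") %in% names(tab0)))
  # monotone down to the solver discretisation floor (~1e-6 relative)
  for (q in unique(tab0$Q0)) {
    sub <- tab0[tab0$Q0 == q, ]
    sub <- sub[order(-sub$eps), ]
    expect_true(all(diff(sub$rel_err) <= 1e-6))
  }
  expect_equal(length(rep0$failures), 0)
  # with relaxed baths the error saturates at the second-order deviation
  # remainder rather than growing
  p <- ref_params(V = 0.5)
  rep_ <- compare_asymptotic_numeric(p, eps_list = c(1e-2, 1e-3),
                                     q_list = c(0.02))
  expect_lt(max(rep_$table$rel_err), 1e-3)
})
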