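test_that("identical seeds give identical parameter sets", {
  a <- make_params(fixture_spec(seed = 123, n = 8))
  b <- make_params(fixture_spec(seed = 123, n = 8))
  expect_identical(a, b)
  c_ <- make_params(fixture_spec(seed = 124, n = 8))
  expect_false(identical(a, c_))
})

test_that("generated sets satisfy every model invariant by construction", {
  ps <- make_params(fixture_spec(seed = 9, n = 25))
  for (p in ps) {
    expect_silent(pnpcrit:::validate_params(p))
    b <- p$baths
    # baseline (species 3 rescaled to neutrality) is exactly neutral
    sr0 <- neutral_deviation(p$valences$z, p$valences$z3,
                             c(b$L1, b$L2,
                               p$valences$z * (b$L1 + b$L2) /
                                 (-p$valences$z3)),
                             c(b$R1, b$R2,
                               p$valences$z * (b$R1 + b$R2) /
                                 (-p$valences$z3)))
    expect_equal(unname(sr0), c(1, 1), tolerance = 1e-12)
    # emitted deviations are recovered from the concentrations
    sr <- neutral_deviation(p$valences$z, p$valences$z3,
                            c(b$L1, b$L2, b$L3), c(b$R1, b$R2, b$R3))
    expect_equal(sr[["sigma"]], b$sigma, tolerance = 1e-12)
    expect_equal(sr[["rho"]], b$rho, tolerance = 1e-12)
    expect_true(b$sigma >= 0.9 && b$sigma <= 1.1)
    expect_true(p$charge$Q0 >= 0 && p$charge$Q0 <= 0.05)
    expect_true(abs(b$V) <= 5)
  }
})

test_that("the frozen oracle parameter table is regenerated bit-for-bit", {
  par <- oracle_params()
  ps <- make_params(fixture_spec(seed = 42, n = 20))
  for (i in 1:20) {
    p <- ps[[i]]
    b <- p$baths
    got <- c(p$valences$z, p$valences$z3, p$diffusion$D1, p$diffusion$D2,
             p$diffusion$D3, b$L1, b$L2, b$L3, b$R1, b$R2, b$R3,
             b$V, b$sigma, b$rho, p$charge$Q0, p$charge$x1, p$charge$x2)
    want <- as.numeric(par[i, c("z", "z3", "D1", "D2", "D3", "L1", "L2",
                                "L3", "R1", "R2", "R3", "V", "sigma",
                                "rho", "Q0", "x1", "x2")])
    expect_identical(got, want)
  }
})

test_that("configuration files round-trip through the reader", {
  cfg <- list(z = 1, z3 = -1, D = c(1, 1, 1), L = c(1, 1, 2),
              R = c(0.3, 0.7, 1), V = 0.5, Q0 = 0.01,
              x1 = 1/3, x2 = 2/3, epsilon = 1e-3, h = "uniform")
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  p <- read_config(path)
  expect_s3_class(p, "pnp_params")
  expect_equal(p$baths$V, 0.5)
  expect_equal(p$baths$sigma, 1)
  expect_equal(p$epsilon, 1e-3)
  # JSON works too
  pj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, pj, auto_unbox = TRUE, digits = NA)
  expect_equal(read_config(pj)$baths$L3, 2)
  # unknown keys are an error, not a silent ignore
  cfg$typo_key <- 1
  yaml::write_yaml(cfg, path)
  expect_error(read_config(path), "unknown configuration keys")
})

test_that("CSV output is schema-stable and numerically round-trip safe", {
  p <- ref_params()
  df <- iv_curve(p, c(-1, 1), 11, Q0 = 0.01)
  expect_equal(names(df), c("V", "J1", "J2", "J3", "I"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_csv17(df, path)
  back <- read.csv(path)
  expect_equal(back$J1, df$J1, tolerance = 0)
  expect_equal(back$I, df$I, tolerance = 0)
})

test_that("current-voltage curves honour equilibrium and reversal points", {
  # symmetric baths: zero current at zero potential
  pe <- pnp_params(1, -1, c(1, 1, 1), L = c(0.6, 1.4, 2),
                   R = c(0.6, 1.4, 2), V = 0)
  df <- iv_curve(pe, c(-1, 1), 21, Q0 = 0)
  expect_equal(df$I[df$V == 0], 0, tolerance = 1e-14)
  # neutral baths at Q0 = 0: the J1 column vanishes at V = V1a
  p <- pnp_params(1, -1, c(1, 1, 1), L = c(1, 1, 2), R = c(0.3, 0.7, 1))
  v1a <- critical_potentials(p)$V1a
  df2 <- iv_curve(p, c(v1a, v1a + 1), 3, Q0 = 0)
  expect_equal(df2$J1[1], 0, tolerance = 1e-14)
})

test_that("run records trace outputs to their configuration", {
  p <- ref_params()
  h1 <- config_hash(p)
  expect_match(h1, "^[0-9a-f]{8}$")
  expect_identical(h1, config_hash(ref_params()))
  expect_false(identical(h1, config_hash(ref_params(V = 0.50001))))
  rec <- run_record(p, "flux", "out.csv")
  expect_identical(rec$config_hash, h1)
  expect_identical(rec$command, "flux")
})
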