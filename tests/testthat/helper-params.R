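# Shared fixtures for the test suite.

# Reference channel/bath configuration: symmetric uniform channel with a
# central charge region, generic concentration ratios t = s = 2 at baseline
# neutrality, deviations sigma > rho.
ref_params <- function(sigma = 1.02, rho = 0.98, V = 0.5, Q0 = 0,
                       epsilon = 1e-4) {
  pnp_params(z = 1, z3 = -1, D = c(1, 1, 1),
             L = c(1, 1), R = c(0.3, 0.7),
             sigma = sigma, rho = rho, V = V, Q0 = Q0,
             x1 = 1/3, x2 = 2/3, epsilon = epsilon)
}

# Rebuild a pnp_params object from one row of the frozen oracle parameter
# table.
params_from_row <- function(r) {
  pnp_params(r$z, r$z3, c(r$D1, r$D2, r$D3),
             L = c(r$L1, r$L2, r$L3), R = c(r$R1, r$R2, r$R3),
             V = r$V, Q0 = r$Q0, x1 = r$x1, x2 = r$x2)
}

oracle_params <- function() {
  read.csv(test_path("oracle-params.csv"))
}

oracle_values <- function() {
  read.csv(test_path("oracle-values.csv"))
}

# All sixteen oracle-checked quantities of one parameter set, as the
# package computes them.
oracle_quantities <- function(p) {
  df <- eval_DF(p)
  fc <- first_order_coeffs(p)
  fd <- flux_difference(p)
  c(Dbig = df$Dbig, Fbig = df$Fbig, c0 = df$c0, c1 = df$c1, c2 = df$c2,
    J110 = fc$J110, J111 = fc$J111, J310 = fc$J310, J3dev = fc$J3dev,
    J1d0 = fd$Jd0[["J1"]], J2d0 = fd$Jd0[["J2"]], J3d0 = fd$Jd0[["J3"]],
    J1d1 = fd$Jd1[["J1"]], J2d1 = fd$Jd1[["J2"]], J3d1 = fd$Jd1[["J3"]])
}

rel_err <- function(got, want) {
  abs(got - want) / pmax(abs(want), 1e-300)
}
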