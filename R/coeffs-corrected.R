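# Generated by data-raw/derive-coeffs.py -- do not edit by hand.
# Closed forms of the first-order (permanent-charge) flux coefficient
# functions, derived from the outer electroneutral system with O(Q0)
# interior-layer jump conditions and validated against an independent
# quadrature implementation and the full BVP solver.
#
# .coeffs_corrected(t, alpha, beta, z, z3) returns:
#   catA, catB : cation deviation coefficient  A + B V
#   cat0A, cat0B : cation neutral coefficient (J110 analogue)
#   an_c0..an_c2 : anion deviation quadratic  c0 + c1 V + c2 V^2
#   an0A, an0B : anion neutral coefficient (J310 analogue)

.coeffs_corrected <- function(t, alpha, beta, z, z3) {
  n <- t
  Ln <- log1p(t - 1)
  v_a <- t + alpha * (1 - t)
  v_b <- t + beta * (1 - t)
  La <- log(v_a)
  Lb <- log(v_b)
  x0 <- 1.0/(z - z3)
  x1 <- La*Ln
  x2 <- v_a^2
  x3 <- v_b^2
  x4 <- x2*x3
  x5 <- x4*z3
  x6 <- x1*x5
  x7 <- Lb*Ln
  x8 <- x5*x7
  x9 <- v_b*x2
  x10 <- x9*z3
  x11 <- v_a*x3
  x12 <- x11*z3
  x13 <- n*v_a
  x14 <- x13*x3
  x15 <- x14*z3
  x16 <- n*v_b
  x17 <- x16*x2
  x18 <- x17*z3
  x19 <- 2*z
  x20 <- Ln*n
  x21 <- x2*x20
  x22 <- x21*z
  x23 <- Ln*n^2
  x24 <- x23*x3
  x25 <- x24*z
  x26 <- x20*x3
  x27 <- x26*z
  x28 <- x2*x23
  x29 <- x28*z
  x30 <- Ln*x17
  x31 <- Ln*x14
  x32 <- -alpha*x25 + alpha*x27 - beta*x22 + beta*x29 - x11*x19 + x14*x19 - x17*x19 + x19*x9 + x22 + x25 - x27 - x29 + x30*z - x31*z
  x33 <- x10 - x12 + x15 - x18 + x32
  x34 <- Ln^(-3)
  x35 <- 1/(x2*x3)
  x36 <- x34*x35
  x37 <- alpha*x26
  x38 <- beta*x21
  x39 <- beta*x28
  x40 <- Ln^2
  x41 <- x17*x40
  x42 <- 2*x4
  x43 <- alpha*x24
  x44 <- x14*x40
  x45 <- alpha*x44
  x46 <- beta*x41
  x47 <- z3*(x1*x42 - 3*x11 + 3*x14 - 3*x17 + x21 + x24 - x26 - x28 + x30 - x31 + x37 - x38 + x39 + x41 - x42*x7 - x43 - x44 + x45 - x46 + 3*x9)/Ln^4
  x48 <- 1.0/x40
  x49 <- 1/(v_a*v_b)
  x50 <- -x48*x49*(-v_a + v_b + x13 - x16)
  x51 <- v_a*v_b
  x52 <- x34*x49*(v_a - v_b + x1*x51 - x13 + x16 - x51*x7)
  x53 <- x4*z
  x54 <- x1*x53 - x53*x7
  x55 <- z^2
  x56 <- 1.0/(-x19*z3 + x55 + z3^2)
  x57 <- x35*x56
  list(
    catA = x0*x36*(x33 + x6 - x8),
    catB = x0*x35*x47*z,
    cat0A = x50,
    cat0B = x52*z3,
    an_c0 = -x48*x57*(x33 + x54),
    an_c1 = -x36*x56*z*(-Ln*x15 + Ln*x18 + 4*x10 - 4*x12 + 4*x15 - 4*x18 + x21*z3 + x24*z3 - x26*z3 - x28*z3 + x32 + x37*z3 - x38*z3 + x39*z3 + x41*z - x43*z3 - x44*z + x45*z - x46*z + x54 + 2*x6 - 2*x8),
    an_c2 = -x47*x55*x57,
    an0A = x50,
    an0B = x52*z
  )
}

# Monomial tables of the coefficient closed forms: each row of pows
# gives the exponents of (n, v_a, v_b, Ln, La, Lb); coef() returns the
# matching coefficients as functions of (z, z3, alpha, beta).  shift is
# the common analytically-vanishing u-order of numerator and
# denominator, dropped before the formal series division.
.coefs_tables <- list(
  catA = list(shift = 3L,
    num_pows = rbind(c(2L, 2L, 0L, 1L, 0L, 0L), c(2L, 0L, 2L, 1L, 0L, 0L), c(1L, 2L, 1L, 1L, 0L, 0L), c(1L, 2L, 1L, 0L, 0L, 0L), c(1L, 2L, 0L, 1L, 0L, 0L), c(1L, 1L, 2L, 1L, 0L, 0L), c(1L, 1L, 2L, 0L, 0L, 0L), c(1L, 0L, 2L, 1L, 0L, 0L), c(0L, 2L, 2L, 1L, 1L, 0L), c(0L, 2L, 2L, 1L, 0L, 1L), c(0L, 2L, 1L, 0L, 0L, 0L), c(0L, 1L, 2L, 0L, 0L, 0L)),
    num_coef = function(z, z3, alpha, beta) c(beta*z - z, -alpha*z + z, z, -2*z - z3, -beta*z + z, -z, 2*z + z3, alpha*z - z, z3, -z3, 2*z + z3, -2*z - z3),
    den_pows = rbind(c(0L, 2L, 2L, 3L, 0L, 0L)),
    den_coef = function(z, z3, alpha, beta) c(z - z3)),
  catB = list(shift = 4L,
    num_pows = rbind(c(2L, 2L, 0L, 1L, 0L, 0L), c(2L, 0L, 2L, 1L, 0L, 0L), c(1L, 2L, 1L, 2L, 0L, 0L), c(1L, 2L, 1L, 1L, 0L, 0L), c(1L, 2L, 1L, 0L, 0L, 0L), c(1L, 2L, 0L, 1L, 0L, 0L), c(1L, 1L, 2L, 2L, 0L, 0L), c(1L, 1L, 2L, 1L, 0L, 0L), c(1L, 1L, 2L, 0L, 0L, 0L), c(1L, 0L, 2L, 1L, 0L, 0L), c(0L, 2L, 2L, 1L, 1L, 0L), c(0L, 2L, 2L, 1L, 0L, 1L), c(0L, 2L, 1L, 0L, 0L, 0L), c(0L, 1L, 2L, 0L, 0L, 0L)),
    num_coef = function(z, z3, alpha, beta) c(beta*z*z3 - z*z3, -alpha*z*z3 + z*z3, -beta*z*z3 + z*z3, z*z3, -3*z*z3, -beta*z*z3 + z*z3, alpha*z*z3 - z*z3, -z*z3, 3*z*z3, alpha*z*z3 - z*z3, 2*z*z3, -2*z*z3, 3*z*z3, -3*z*z3),
    den_pows = rbind(c(0L, 2L, 2L, 4L, 0L, 0L)),
    den_coef = function(z, z3, alpha, beta) c(z - z3)),
  cat0A = list(shift = 2L,
    num_pows = rbind(c(1L, 1L, 0L, 0L, 0L, 0L), c(1L, 0L, 1L, 0L, 0L, 0L), c(0L, 1L, 0L, 0L, 0L, 0L), c(0L, 0L, 1L, 0L, 0L, 0L)),
    num_coef = function(z, z3, alpha, beta) c(-1, 1, 1, -1),
    den_pows = rbind(c(0L, 1L, 1L, 2L, 0L, 0L)),
    den_coef = function(z, z3, alpha, beta) c(1)),
  cat0B = list(shift = 3L,
    num_pows = rbind(c(1L, 1L, 0L, 0L, 0L, 0L), c(1L, 0L, 1L, 0L, 0L, 0L), c(0L, 1L, 1L, 1L, 1L, 0L), c(0L, 1L, 1L, 1L, 0L, 1L), c(0L, 1L, 0L, 0L, 0L, 0L), c(0L, 0L, 1L, 0L, 0L, 0L)),
    num_coef = function(z, z3, alpha, beta) c(-z3, z3, z3, -z3, z3, -z3),
    den_pows = rbind(c(0L, 1L, 1L, 3L, 0L, 0L)),
    den_coef = function(z, z3, alpha, beta) c(1)),
  an_c0 = list(shift = 2L,
    num_pows = rbind(c(2L, 2L, 0L, 1L, 0L, 0L), c(2L, 0L, 2L, 1L, 0L, 0L), c(1L, 2L, 1L, 1L, 0L, 0L), c(1L, 2L, 1L, 0L, 0L, 0L), c(1L, 2L, 0L, 1L, 0L, 0L), c(1L, 1L, 2L, 1L, 0L, 0L), c(1L, 1L, 2L, 0L, 0L, 0L), c(1L, 0L, 2L, 1L, 0L, 0L), c(0L, 2L, 2L, 1L, 1L, 0L), c(0L, 2L, 2L, 1L, 0L, 1L), c(0L, 2L, 1L, 0L, 0L, 0L), c(0L, 1L, 2L, 0L, 0L, 0L)),
    num_coef = function(z, z3, alpha, beta) c(-beta*z + z, alpha*z - z, -z, 2*z + z3, beta*z - z, z, -2*z - z3, -alpha*z + z, -z, z, -2*z - z3, 2*z + z3),
    den_pows = rbind(c(0L, 2L, 2L, 2L, 0L, 0L)),
    den_coef = function(z, z3, alpha, beta) c(z^2 - 2*z*z3 + z3^2)),
  an_c1 = list(shift = 3L,
    num_pows = rbind(c(2L, 2L, 0L, 1L, 0L, 0L), c(2L, 0L, 2L, 1L, 0L, 0L), c(1L, 2L, 1L, 2L, 0L, 0L), c(1L, 2L, 1L, 1L, 0L, 0L), c(1L, 2L, 1L, 0L, 0L, 0L), c(1L, 2L, 0L, 1L, 0L, 0L), c(1L, 1L, 2L, 2L, 0L, 0L), c(1L, 1L, 2L, 1L, 0L, 0L), c(1L, 1L, 2L, 0L, 0L, 0L), c(1L, 0L, 2L, 1L, 0L, 0L), c(0L, 2L, 2L, 1L, 1L, 0L), c(0L, 2L, 2L, 1L, 0L, 1L), c(0L, 2L, 1L, 0L, 0L, 0L), c(0L, 1L, 2L, 0L, 0L, 0L)),
    num_coef = function(z, z3, alpha, beta) c(-beta*z^2 - beta*z*z3 + z^2 + z*z3, alpha*z^2 + alpha*z*z3 - z^2 - z*z3, beta*z^2 - z^2, -z^2 - z*z3, 2*z^2 + 4*z*z3, beta*z^2 + beta*z*z3 - z^2 - z*z3, -alpha*z^2 + z^2, z^2 + z*z3, -2*z^2 - 4*z*z3, -alpha*z^2 - alpha*z*z3 + z^2 + z*z3, -z^2 - 2*z*z3, z^2 + 2*z*z3, -2*z^2 - 4*z*z3, 2*z^2 + 4*z*z3),
    den_pows = rbind(c(0L, 2L, 2L, 3L, 0L, 0L)),
    den_coef = function(z, z3, alpha, beta) c(z^2 - 2*z*z3 + z3^2)),
  an_c2 = list(shift = 4L,
    num_pows = rbind(c(2L, 2L, 0L, 1L, 0L, 0L), c(2L, 0L, 2L, 1L, 0L, 0L), c(1L, 2L, 1L, 2L, 0L, 0L), c(1L, 2L, 1L, 1L, 0L, 0L), c(1L, 2L, 1L, 0L, 0L, 0L), c(1L, 2L, 0L, 1L, 0L, 0L), c(1L, 1L, 2L, 2L, 0L, 0L), c(1L, 1L, 2L, 1L, 0L, 0L), c(1L, 1L, 2L, 0L, 0L, 0L), c(1L, 0L, 2L, 1L, 0L, 0L), c(0L, 2L, 2L, 1L, 1L, 0L), c(0L, 2L, 2L, 1L, 0L, 1L), c(0L, 2L, 1L, 0L, 0L, 0L), c(0L, 1L, 2L, 0L, 0L, 0L)),
    num_coef = function(z, z3, alpha, beta) c(-beta*z^2*z3 + z^2*z3, alpha*z^2*z3 - z^2*z3, beta*z^2*z3 - z^2*z3, -z^2*z3, 3*z^2*z3, beta*z^2*z3 - z^2*z3, -alpha*z^2*z3 + z^2*z3, z^2*z3, -3*z^2*z3, -alpha*z^2*z3 + z^2*z3, -2*z^2*z3, 2*z^2*z3, -3*z^2*z3, 3*z^2*z3),
    den_pows = rbind(c(0L, 2L, 2L, 4L, 0L, 0L)),
    den_coef = function(z, z3, alpha, beta) c(z^2 - 2*z*z3 + z3^2)),
  an0A = list(shift = 2L,
    num_pows = rbind(c(1L, 1L, 0L, 0L, 0L, 0L), c(1L, 0L, 1L, 0L, 0L, 0L), c(0L, 1L, 0L, 0L, 0L, 0L), c(0L, 0L, 1L, 0L, 0L, 0L)),
    num_coef = function(z, z3, alpha, beta) c(-1, 1, 1, -1),
    den_pows = rbind(c(0L, 1L, 1L, 2L, 0L, 0L)),
    den_coef = function(z, z3, alpha, beta) c(1)),
  an0B = list(shift = 3L,
    num_pows = rbind(c(1L, 1L, 0L, 0L, 0L, 0L), c(1L, 0L, 1L, 0L, 0L, 0L), c(0L, 1L, 1L, 1L, 1L, 0L), c(0L, 1L, 1L, 1L, 0L, 1L), c(0L, 1L, 0L, 0L, 0L, 0L), c(0L, 0L, 1L, 0L, 0L, 0L)),
    num_coef = function(z, z3, alpha, beta) c(-z, z, z, -z, z, -z),
    den_pows = rbind(c(0L, 1L, 1L, 3L, 0L, 0L)),
    den_coef = function(z, z3, alpha, beta) c(1))
)
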