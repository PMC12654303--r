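# Collocation solver for the full steady-state PNP boundary-value problem.
#
# The second-order Poisson equation is rewritten as a first-order system in
# (phi, u) with u = eps * h * phi', which keeps the conditioning uniform in
# eps (standard singular-perturbation practice), and the Nernst-Planck
# equations are solved in Slotboom variables eta_k = c_k * exp(z_k * phi):
#
#   phi'   =  u / (eps h)
#   u'     = -h (z c1 + z c2 + z3 c3 + Q(x)) / eps
#   eta_k' = -Jhat_k exp(z_k phi) / h ,   c_k = eta_k exp(-z_k phi)
#
# with the three scaled fluxes Jhat_k as global unknowns (flux constancy is
# then exact by construction, and the discrete system inherits detailed
# balance: at equilibrium boundary data the solver returns Jhat = 0 to
# Newton tolerance).  Physical fluxes are J_k = D_k * Jhat_k.  The interval
# midpoint (box) scheme is second order and A-stable; the permanent charge
# is smoothed over a tanh ramp of half-width delta so the collocation
# residual stays well defined at x1, x2.

#' Mesh and continuation configuration for the PNP solver
#'
#' @param n_base Number of uniformly spaced base nodes.
#' @param tol Convergence tolerance on the maximum Newton residual.
#' @param max_nodes Hard cap on mesh size.
#' @param epsilon_schedule Decreasing sequence of dielectric parameters for
#'   continuation; stages above the target `epsilon` are used as warm starts.
#' @param delta Half-width of the tanh ramp smoothing the permanent charge.
#' @param layer_ratio Geometric growth factor of the boundary-layer mesh.
#' @return List of class `pnp_mesh_config`.
#' @export
mesh_config <- function(n_base = 201L, tol = 1e-9, max_nodes = 20000L,
                        epsilon_schedule = c(1e-1, 3e-2, 1e-2, 3e-3,
                                             1e-3, 3e-4, 1e-4),
                        delta = 1e-3, layer_ratio = 1.3) {
  stopifnot(tol > 0, all(diff(epsilon_schedule) < 0), all(epsilon_schedule > 0))
  structure(list(n_base = as.integer(n_base), tol = tol,
                 max_nodes = as.integer(max_nodes),
                 epsilon_schedule = epsilon_schedule,
                 delta = delta, layer_ratio = layer_ratio),
            class = "pnp_mesh_config")
}

# Internal: graded mesh resolving the O(eps) Debye layers at both ends and
# the permanent-charge ramps at x1, x2.
.build_mesh <- function(epsilon, x1, x2, mesh) {
  r <- mesh$layer_ratio
  lay <- epsilon / 50 * r^(0:200)
  lay <- lay[lay <= 0.15]
  ramp <- mesh$delta * seq(-8, 8, by = 0.5)
  x <- c(seq(0, 1, length.out = mesh$n_base),
         lay, 1 - lay, x1 + ramp, x2 + ramp)
  x <- sort(unique(x[x >= 0 & x <= 1]))
  keep <- c(TRUE, diff(x) > min(epsilon / 200, mesh$delta / 50))
  keep[length(x)] <- TRUE
  x <- x[keep]
  if (length(x) > mesh$max_nodes)
    stop("mesh exceeds max_nodes; increase max_nodes or coarsen the grading")
  x
}

# Internal: one damped-Newton solve of the discrete system at fixed epsilon.
# y is a 5 x n matrix (phi, u, eta1, eta2, eta3); J the scaled flux triple.
.newton_pnp <- function(x, y, J, pp, epsilon, Q0, mesh, max_iter = 30L) {
  z <- pp$valences$z; z3 <- pp$valences$z3
  zs <- c(z, z, z3)
  b <- pp$baths
  hfun <- pp$geometry$h
  n <- length(x)
  hstep <- diff(x)
  xm <- (x[-1] + x[-n]) / 2
  hm <- hfun(xm)
  Qm <- Q0 * 0.5 * (tanh((xm - pp$charge$x1) / mesh$delta) -
                      tanh((xm - pp$charge$x2) / mesh$delta))
  Lk <- c(b$L1, b$L2, b$L3)
  Rk <- c(b$R1, b$R2, b$R3)
  nv <- 5L * n + 3L
  ji <- 5L * n + 1:3

  resid <- function(y, J) {
    ym <- (y[, -1, drop = FALSE] + y[, -n, drop = FALSE]) / 2
    ck <- ym[3:5, , drop = FALSE] * exp(-zs * rep(ym[1, ], each = 3))
    feta <- matrix(-(J * exp(zs * rep(ym[1, ], each = 3))) /
                     rep(hm, each = 3), 3L, n - 1L)
    f <- rbind(
      ym[2, ] / (epsilon * hm),
      -hm * (colSums(zs * ck) + Qm) / epsilon,
      feta)
    r_int <- (y[, -1, drop = FALSE] - y[, -n, drop = FALSE]) -
      f * rep(hstep, each = 5)
    r_bc <- c(y[1, 1] - b$V, y[3:5, 1] - Lk * exp(zs * b$V),
              y[1, n], y[3:5, n] - Rk)
    c(as.vector(r_int), r_bc)
  }

  jacobian <- function(y, J) {
    ym <- (y[, -1, drop = FALSE] + y[, -n, drop = FALSE]) / 2
    phim <- ym[1, ]
    em <- exp(-zs * rep(phim, each = 3))      # 3 x (n-1), e^{-zk phi}
    dim(em) <- c(3L, n - 1L)
    ep <- exp(zs * rep(phim, each = 3))       # e^{+zk phi}
    dim(ep) <- c(3L, n - 1L)
    ck <- ym[3:5, , drop = FALSE] * em
    ii <- seq_len(n - 1L)
    rowb <- 5L * (ii - 1L)       # residual row offset of interval i
    colL <- 5L * (ii - 1L)       # unknown column offset of node i
    colR <- 5L * ii

    # A = df/dy at midpoints (nonzero entries only)
    A12 <- 1 / (epsilon * hm)
    A21 <- hm * colSums(zs^2 * ck) / epsilon
    A2c <- -(hm / epsilon) * rep(1, n - 1L)   # times zs[k] e^{-zk phi}
    trip_i <- integer(0); trip_j <- integer(0); trip_v <- numeric(0)
    add <- function(r, cl, v) {
      trip_i <<- c(trip_i, r); trip_j <<- c(trip_j, cl); trip_v <<- c(trip_v, v)
    }
    for (side in 1:2) {
      colb <- if (side == 1) colL else colR
      sgn <- if (side == 1) -1 else 1
      half <- hstep / 2
      # identity part
      for (k in 1:5) add(rowb + k, colb + k, rep(sgn, n - 1L))
      # -(h/2) A part
      add(rowb + 1L, colb + 2L, -half * A12)
      add(rowb + 2L, colb + 1L, -half * A21)
      for (k in 1:3)
        add(rowb + 2L, colb + 2L + k, -half * A2c * zs[k] * em[k, ])
      for (k in 1:3)
        add(rowb + 2L + k, colb + 1L,
            -half * (-J[k] * zs[k] * ep[k, ] / hm))
    }
    # flux columns
    for (k in 1:3)
      add(rowb + 2L + k, rep(ji[k], n - 1L), hstep * ep[k, ] / hm)
    # boundary conditions
    nb <- 5L * (n - 1L)
    add(nb + 1L, 1L, 1)
    for (k in 1:3) add(nb + 1L + k, 2L + k, 1)
    add(nb + 5L, 5L * (n - 1L) + 1L, 1)
    for (k in 1:3) add(nb + 5L + k, 5L * (n - 1L) + 2L + k, 1)
    Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_v,
                         dims = c(nv, nv))
  }

  r <- resid(y, J)
  rn <- max(abs(r))
  iter <- 0L
  while (rn > mesh$tol && iter < max_iter) {
    iter <- iter + 1L
    Jm <- jacobian(y, J)
    dv <- tryCatch(as.numeric(Matrix::solve(Jm, -r)),
                   error = function(e) stop("Newton linear solve failed: ",
                                            conditionMessage(e)))
    lam <- 1
    repeat {
      y_try <- y + lam * matrix(dv[seq_len(5L * n)], 5L, n)
      J_try <- J + lam * dv[ji]
      r_try <- resid(y_try, J_try)
      rn_try <- max(abs(r_try))
      if (is.finite(rn_try) && (rn_try < (1 - 0.1 * lam) * rn ||
                                rn_try < mesh$tol)) break
      lam <- lam / 2
      if (lam < 1e-6) break
    }
    if (lam < 1e-6) break   # stalled; report unconverged
    y <- y_try; J <- J_try; r <- r_try; rn <- rn_try
  }
  list(y = y, J = J, residual = rn, converged = rn <= mesh$tol, iter = iter)
}

#' Solve the full PNP boundary-value problem
#'
#' Solves the dimensionless steady-state PNP system with piecewise-constant
#' (tanh-smoothed) permanent charge and the bath Dirichlet data of the model,
#' by a second-order box scheme with damped Newton iteration and continuation
#' in the dielectric parameter `epsilon` (each stage warm-starts the next).
#' This solver is deliberately independent of the asymptotic formulas; it is
#' the numerical oracle against which they are validated.
#'
#' @param p A [pnp_params] object (supplies `epsilon` and `Q0` defaults).
#' @param mesh A [mesh_config()].
#' @param epsilon Target dielectric parameter.
#' @param Q0 Permanent-charge magnitude.
#' @param init Optional previous `pnp_solution` used as warm start (skips
#'   continuation when its mesh matches the target `epsilon` mesh).
#' @param keep_stages If `TRUE`, also return the converged solution of every
#'   continuation stage (used by convergence studies).
#' @return Object of class `pnp_solution`: list with the grid `x`, profiles
#'   `phi`, `c1`, `c2`, `c3`, physical fluxes `J` (named, `Jk = Dk*Jhat_k`),
#'   `residual`, `converged`, `epsilon`, `Q0`, and optionally `stages`.
#' @examples
#' \donttest{
#' p <- pnp_params(1, -1, c(1, 1, 1), L = c(1, 1, 2), R = c(0.3, 0.7, 1),
#'                 epsilon = 1e-2)
#' sol <- solve_pnp(p)
#' sol$J     # compare zeroth_order_flux(p, 0)
#' }
#' @export
solve_pnp <- function(p, mesh = mesh_config(), epsilon = p$epsilon,
                      Q0 = p$charge$Q0, init = NULL, keep_stages = FALSE) {
  validate_params(p)
  zs <- c(p$valences$z, p$valences$z, p$valences$z3)
  b <- p$baths
  Lk <- c(b$L1, b$L2, b$L3); Rk <- c(b$R1, b$R2, b$R3)

  sched <- mesh$epsilon_schedule[mesh$epsilon_schedule > epsilon * (1 + 1e-12)]
  sched <- c(sched, epsilon)

  interp_to <- function(xold, yold, xnew) {
    t(vapply(1:5, function(k)
      stats::approx(xold, yold[k, ], xout = xnew, rule = 2)$y,
      numeric(length(xnew))))
  }

  if (!is.null(init)) {
    stopifnot(inherits(init, "pnp_solution"))
    sched <- epsilon   # warm start: single stage
  }

  stages <- list()
  xprev <- NULL; yprev <- NULL; Jprev <- c(0, 0, 0)
  res <- NULL
  for (se in sched) {
    x <- .build_mesh(se, p$charge$x1, p$charge$x2, mesh)
    n <- length(x)
    if (is.null(xprev)) {
      if (!is.null(init)) {
        eta0 <- rbind(init$c1, init$c2, init$c3) *
          exp(zs * rep(init$phi, each = 3))
        y <- interp_to(init$x, rbind(init$phi, init$u, eta0), x)
        Jprev <- init$J / c(p$diffusion$D1, p$diffusion$D2, p$diffusion$D3)
      } else {
        phi0 <- b$V * (1 - x)
        y <- rbind(phi0, rep(0, n),
                   (Lk[1] + (Rk[1] - Lk[1]) * rep(x, 1)) * exp(zs[1] * phi0),
                   (Lk[2] + (Rk[2] - Lk[2]) * rep(x, 1)) * exp(zs[2] * phi0),
                   (Lk[3] + (Rk[3] - Lk[3]) * rep(x, 1)) * exp(zs[3] * phi0))
      }
    } else {
      y <- interp_to(xprev, yprev, x)
    }
    res <- .newton_pnp(x, y, Jprev, p, se, Q0, mesh)
    if (!res$converged)
      stop(sprintf(paste0("PNP solver failed to converge at epsilon = %g ",
                          "(residual %.3g)"), se, res$residual))
    xprev <- x; yprev <- res$y; Jprev <- res$J
    if (keep_stages)
      stages[[length(stages) + 1L]] <-
        .wrap_solution(x, res, p, se, Q0)
  }
  out <- .wrap_solution(xprev, res, p, epsilon, Q0)
  if (keep_stages) out$stages <- stages
  out
}

.wrap_solution <- function(x, res, p, epsilon, Q0) {
  zs <- c(p$valences$z, p$valences$z, p$valences$z3)
  y <- res$y
  ck <- y[3:5, , drop = FALSE] * exp(-zs * rep(y[1, ], each = 3))
  if (any(ck <= 0))
    stop("converged PNP solution has non-positive concentrations")
  D <- c(p$diffusion$D1, p$diffusion$D2, p$diffusion$D3)
  structure(list(
    x = x, phi = y[1, ], u = y[2, ],
    c1 = ck[1, ], c2 = ck[2, ], c3 = ck[3, ],
    J = stats::setNames(D * res$J, c("J1", "J2", "J3")),
    Jhat = res$J,
    residual = res$residual, converged = res$converged,
    epsilon = epsilon, Q0 = Q0, iterations = res$iter
  ), class = "pnp_solution")
}

#' @export
print.pnp_solution <- function(x, ...) {
  cat(sprintf("<pnp_solution>  epsilon = %g, Q0 = %g, %d nodes, residual %.3g\n",
              x$epsilon, x$Q0, length(x$x), x$residual))
  cat(sprintf("  fluxes  J1 = %.8g, J2 = %.8g, J3 = %.8g\n",
              x$J[1], x$J[2], x$J[3]))
  invisible(x)
}

#' @export
as.data.frame.pnp_solution <- function(x, ...) {
  data.frame(x = x$x, phi = x$phi, c1 = x$c1, c2 = x$c2, c3 = x$c3)
}

#' Pointwise Nernst-Planck flux along a solved profile
#'
#' Reconstructs the per-species flux from centred differences of the
#' concentration and potential profiles.  In an accurate solution this is
#' constant in `x` (the solver enforces flux constancy exactly through its
#' global flux unknowns; this reconstruction is an independent consistency
#' diagnostic of the profiles themselves).
#'
#' @param sol A `pnp_solution`.
#' @param p The [pnp_params] used to produce it.
#' @return Matrix (intervals x 3) of pointwise fluxes.
#' @export
pointwise_flux <- function(sol, p) {
  zs <- c(p$valences$z, p$valences$z, p$valences$z3)
  D <- c(p$diffusion$D1, p$diffusion$D2, p$diffusion$D3)
  hfun <- p$geometry$h
  x <- sol$x
  n <- length(x)
  hm <- hfun((x[-1] + x[-n]) / 2)
  dx <- diff(x)
  ck <- rbind(sol$c1, sol$c2, sol$c3)
  phim <- diff(sol$phi) / dx
  out <- matrix(NA_real_, n - 1L, 3)
  for (k in 1:3) {
    cm <- (ck[k, -1] + ck[k, -n]) / 2
    out[, k] <- -D[k] * hm * (diff(ck[k, ]) / dx + zs[k] * cm * phim)
  }
  colnames(out) <- c("J1", "J2", "J3")
  out
}
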