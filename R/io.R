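# Configuration files, CSV writers, current-voltage curves and run records.

.known_config_keys <- c("z", "z3", "D", "L", "R", "V", "sigma", "rho", "Q0",
                        "x1", "x2", "epsilon", "h", "units")

#' Read a model configuration file
#'
#' Reads a YAML (or JSON) configuration into a [pnp_params] object.
#' Recognised keys: `z`, `z3`, `D` (list of 3), `L`, `R` (lists of 2 or 3),
#' `V`, `sigma`, `rho`, `Q0`, `x1`, `x2`, `epsilon`, `h` (either the string
#' `"uniform"` or a table of `(x, h)` pairs, interpolated monotonically) and
#' an optional `units` block (`l`, `C0`, `thermal_voltage`, `eps_r`) that
#' triggers nondimensionalisation of `V`, `L`, `R`, `x1`, `x2` and computes
#' `epsilon` from the dielectric data.  Unknown keys raise an error rather
#' than being silently ignored.
#'
#' @param path Path to the configuration file.
#' @return A [pnp_params] object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(cfg), .known_config_keys)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))

  h <- cfg$h
  if (!is.null(h)) {
    if (identical(h, "uniform")) h <- NULL
    else {
      h <- as.data.frame(h)
      if (!all(c("x", "h") %in% names(h)))
        stop("h must be \"uniform\" or a table with columns x and h")
    }
  }

  num <- function(key, default = NULL) {
    v <- cfg[[key]]
    if (is.null(v)) return(default)
    as.numeric(v)
  }

  L <- num("L"); R <- num("R")
  V <- num("V", 0); x1 <- num("x1", 1/3); x2 <- num("x2", 2/3)
  epsilon <- num("epsilon", 1e-4)
  if (!is.null(cfg$units)) {
    u <- cfg$units
    sc <- list(l = u$l, C0 = u$C0, thermal_voltage = u$thermal_voltage,
               eps_r = u$eps_r)
    nd <- nondimensionalize(sc, V = V, conc = c(L, R), X = c(x1, x2) * sc$l)
    V <- nd$V
    conc <- nd$conc
    L <- conc[seq_along(L)]; R <- conc[-seq_along(L)]
    if (!is.null(nd$epsilon)) epsilon <- nd$epsilon
  }
  pnp_params(z = num("z"), z3 = num("z3"), D = num("D"),
             L = L, R = R, V = V,
             sigma = num("sigma"), rho = num("rho"),
             Q0 = num("Q0", 0), x1 = x1, x2 = x2, h = h,
             epsilon = epsilon)
}

#' Write a table as round-trip-safe CSV
#'
#' Writes numeric columns with 17 significant digits so values survive a
#' write/read cycle bit-exactly.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_csv17 <- function(df, path) {
  fmt <- function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  }
  out <- as.data.frame(lapply(df, fmt), stringsAsFactors = FALSE,
                       check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Current-voltage relation from the asymptotic expansion
#'
#' Tabulates the per-species fluxes and the total electric current
#' `I = z (J1 + J2) + z3 J3` over a potential sweep, from the affine
#' expansion `Jk0 + Q0 Jk1` (default) or from the full numerical solver.
#'
#' @param p A [pnp_params] object.
#' @param V_range Length-2 potential interval.
#' @param n_points Number of sweep points (>= 2).
#' @param Q0 Permanent-charge magnitude.
#' @param numeric Use the BVP solver instead of the expansion.
#' @param mesh,epsilon Solver settings when `numeric = TRUE`.
#' @return `data.frame` with columns `V`, `J1`, `J2`, `J3`, `I`.
#' @export
iv_curve <- function(p, V_range = c(-2, 2), n_points = 81L,
                     Q0 = p$charge$Q0, numeric = FALSE,
                     mesh = mesh_config(), epsilon = p$epsilon) {
  stopifnot(n_points >= 2, length(V_range) == 2L)
  z <- p$valences$z; z3 <- p$valences$z3
  V <- seq(V_range[1], V_range[2], length.out = n_points)
  if (numeric) {
    J <- matrix(NA_real_, n_points, 3)
    sol <- NULL
    for (i in seq_along(V)) {
      sol <- solve_pnp(with_potential(p, V[i]), mesh, epsilon = epsilon,
                       Q0 = Q0, init = sol)
      J[i, ] <- sol$J
    }
  } else if (Q0 == 0) {
    J <- zeroth_order_flux(p, V)   # avoid 0 * (undefined coefficient)
  } else {
    J <- zeroth_order_flux(p, V) + Q0 * first_order_flux(p, V)
  }
  data.frame(V = V, J1 = J[, 1], J2 = J[, 2], J3 = J[, 3],
             I = z * (J[, 1] + J[, 2]) + z3 * J[, 3])
}

#' Content hash of a configuration (run-record traceability)
#'
#' Small FNV-1a hash over the serialised parameter values, so CSV/JSON
#' outputs can be traced back to the inputs that produced them without an
#' external digest dependency.
#'
#' @param p A [pnp_params] object (or any list of numerics).
#' @return Hex string.
#' @export
config_hash <- function(p) {
  txt <- paste(utils::capture.output(utils::str(unclass(p), digits.d = 17)),
               collapse = "\n")
  bytes <- utf8ToInt(txt)
  # 32-bit modular multiply, exact in doubles via 16-bit limbs
  mul32 <- function(h, m) {
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    (lo * m + ((hi * m) %% 65536) * 65536) %% 4294967296
  }
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256  # xor affects the low byte only (b < 256)
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    h <- mul32(h, 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Assemble a run record for CLI outputs
#'
#' @param p A [pnp_params] object.
#' @param command Command name.
#' @param outputs Character vector of output paths.
#' @return List (serialise with `jsonlite::write_json`).
#' @export
run_record <- function(p, command, outputs = character(0)) {
  list(command = command,
       config_hash = config_hash(p),
       package_version = as.character(utils::packageVersion("pnpcrit")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       outputs = outputs)
}
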