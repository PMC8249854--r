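# Random reservoir networks and simulation of the two node families.

#' Build a random reservoir adjacency matrix
#'
#' `round(fill_fraction * M^2)` randomly chosen entries are drawn uniform on
#' \eqn{[-1, 1]}, the diagonal is zeroed, `offset` is added to every entry
#' (diagonal included), and the matrix is rescaled so its spectral radius
#' (largest eigenvalue magnitude) equals `spectral_radius` exactly.
#'
#' @param M Node count.
#' @param fill_fraction Fraction of entries filled (default 0.5).
#' @param offset Additive constant applied after the diagonal is zeroed
#'   (0.5 for the spiking family, 0 for the polynomial family).
#' @param spectral_radius Target spectral radius (> 0).
#' @param seed Optional RNG seed.
#' @return An `M x M` numeric matrix.
#' @export
build_adjacency <- function(M, fill_fraction = 0.5, offset = 0,
                            spectral_radius, seed = NULL) {
  if (fill_fraction <= 0 || fill_fraction > 1)
    stop_invalid("fill_fraction must be in (0, 1]")
  if (spectral_radius <= 0) stop_invalid("spectral_radius must be > 0")
  with_seed(seed, {
    n_fill <- round(fill_fraction * M^2)
    A <- matrix(0, M, M)
    idx <- sample.int(M^2, n_fill)
    A[idx] <- runif(n_fill, -1, 1)
    diag(A) <- 0
    A <- A + offset
    sr <- max(Mod(eigen(A, only.values = TRUE)$values))
    if (sr < 1e-12)
      stop_invalid("adjacency construction failed: spectral radius ~ 0")
    A * (spectral_radius / sr)
  })
}

#' Build the reservoir input-weight vector
#'
#' @param M Node count.
#' @param low,high Range of the uniform distribution (`high > low`).
#' @param seed Optional RNG seed.
#' @return Length-`M` numeric vector with i.i.d. uniform entries.
#' @export
build_input_weights <- function(M, low, high, seed = NULL) {
  if (high <= low) stop_invalid("need high > low")
  with_seed(seed, runif(M, low, high))
}

#' Node parameters for the spiking family
#'
#' Each spiking node is a two-variable relaxation unit: a fast variable
#' \eqn{u_i} with dynamics \eqn{\dot u_i = T_C(-u_i^3 + u_i g(v_i,\phi_i))}
#' and a slow variable \eqn{v_i} with
#' \eqn{\dot v_i = (T_C/R_\tau)(W_i S_V - \gamma v_i + \sum_j A_{ij} u_j)}.
#' The threshold function \eqn{g} is 0 below the node's firing threshold
#' \eqn{\phi_i} and 1 above it (0 at exact equality); whenever
#' \eqn{u_i > 0.5} the slow variable is reset to 0.
#'
#' @param T_C Global time-scale constant (default 15).
#' @param R_tau Fast-to-slow time ratio (default 36).
#' @param gamma Slow-variable damping (default 0.004).
#' @param reset_level Fast-variable level triggering the reset (default 0.5).
#' @return A `spiking_params` list.
#' @export
spiking_params <- function(T_C = 15, R_tau = 36, gamma = 0.004,
                           reset_level = 0.5) {
  if (T_C <= 0 || R_tau <= 0) stop_invalid("T_C and R_tau must be > 0")
  if (gamma < 0) stop_invalid("gamma must be >= 0")
  structure(list(T_C = T_C, R_tau = R_tau, gamma = gamma,
                 reset_level = reset_level),
            class = "spiking_params")
}

#' Node parameters for the polynomial ODE family
#'
#' Each node obeys \eqn{\dot r_i = \alpha[p_1 r_i + p_2 r_i^2 + p_3 r_i^3 +
#' \sum_j A_{ij} r_j + W_i s(t)]}.  The cubic coefficients default to an
#' odd-saturating nonlinearity (`p2 = 1`, `p3 = -1`).
#'
#' @param alpha Time-scale parameter (> 0, default 0.3).
#' @param p1,p2,p3 Polynomial coefficients (defaults -0.5, 1, -1).
#' @return A `polynomial_params` list.
#' @export
polynomial_params <- function(alpha = 0.3, p1 = -0.5, p2 = 1, p3 = -1) {
  if (alpha <= 0) stop_invalid("alpha must be > 0")
  structure(list(alpha = alpha, p1 = p1, p2 = p2, p3 = p3),
            class = "polynomial_params")
}

#' Construct a reservoir specification
#'
#' Draws the random network (adjacency matrix, input weights and, for the
#' spiking family, firing thresholds uniform on \eqn{[1, 1.1]}) from `seed`
#' and bundles it with the node parameters.  Family defaults follow the two
#' standard operating points: the spiking family uses spectral radius 0.5,
#' adjacency offset 0.5 and input weights uniform on `[0, 1]`; the
#' polynomial family uses spectral radius 0.8, no offset and input weights
#' uniform on `[-1, 1]`.
#'
#' @param family `"spiking"` or `"polynomial"`.
#' @param M Node count (default 100).
#' @param params A [spiking_params()] or [polynomial_params()] object;
#'   defaults to the family's defaults.
#' @param spectral_radius,offset,input_range,fill_fraction Network knobs;
#'   `NULL` means the family default.
#' @param seed RNG seed for the network draw (required for reproducibility).
#' @param adjacency,input_weights,thresholds Optional explicit matrices /
#'   vectors replacing the random draw (useful for reduced or hand-built
#'   networks); whatever is supplied is used as-is.
#' @return A `reservoir_spec` object.
#' @export
reservoir_spec <- function(family = c("spiking", "polynomial"), M = 100,
                           params = NULL, spectral_radius = NULL,
                           offset = NULL, input_range = NULL,
                           fill_fraction = 0.5, seed = 1,
                           adjacency = NULL, input_weights = NULL,
                           thresholds = NULL) {
  family <- match.arg(family)
  if (family == "spiking") {
    params <- params %||% spiking_params()
    stopifnot(inherits(params, "spiking_params"))
    spectral_radius <- spectral_radius %||% 0.5
    offset <- offset %||% 0.5
    input_range <- input_range %||% c(0, 1)
  } else {
    params <- params %||% polynomial_params()
    stopifnot(inherits(params, "polynomial_params"))
    spectral_radius <- spectral_radius %||% 0.8
    offset <- offset %||% 0
    input_range <- input_range %||% c(-1, 1)
  }
  net <- with_seed(seed, {
    A <- adjacency %||% build_adjacency(M, fill_fraction, offset,
                                        spectral_radius)
    W <- input_weights %||% build_input_weights(M, input_range[1],
                                                input_range[2])
    phi <- if (family == "spiking")
      thresholds %||% runif(M, 1, 1.1) else NULL
    list(A = A, W = W, phi = phi)
  })
  structure(list(family = family, M = M, adjacency = net$A,
                 input_weights = net$W, thresholds = net$phi,
                 spectral_radius = spectral_radius, offset = offset,
                 input_range = input_range, fill_fraction = fill_fraction,
                 params = params, seed = seed),
            class = "reservoir_spec")
}

#' @export
print.reservoir_spec <- function(x, ...) {
  cat(sprintf("reservoir spec: %s family, M = %d, spectral radius = %g, seed = %s\n",
              x$family, x$M, x$spectral_radius, format(x$seed)))
  cat("node parameters:",
      paste(names(x$params), vapply(x$params, format, ""), sep = " = ",
            collapse = ", "), "\n")
  invisible(x)
}

#' Serialize / restore a reservoir specification as JSON
#'
#' The adjacency matrix is stored as nested lists so an experiment can be
#' replayed exactly.
#'
#' @param spec A `reservoir_spec`.
#' @param path JSON file path.
#' @export
write_reservoir_spec <- function(spec, path) {
  obj <- unclass(spec)
  obj$params <- unclass(obj$params)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_reservoir_spec
#' @export
read_reservoir_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pars <- if (obj$family == "spiking")
    do.call(spiking_params, as.list(obj$params))
  else do.call(polynomial_params, as.list(obj$params))
  structure(list(family = obj$family, M = obj$M,
                 adjacency = unname(as.matrix(obj$adjacency)),
                 input_weights = obj$input_weights,
                 thresholds = obj$thresholds,
                 spectral_radius = obj$spectral_radius, offset = obj$offset,
                 input_range = obj$input_range,
                 fill_fraction = obj$fill_fraction, params = pars,
                 seed = obj$seed),
            class = "reservoir_spec")
}

drive_values <- function(drive) {
  if (inherits(drive, "spike_train")) as.numeric(drive$values)
  else as.numeric(drive)
}

#' Simulate a reservoir over a drive signal
#'
#' Integrates the node ODEs with one output sample per drive sample (output
#' step 1 in reservoir time), holding the drive piecewise constant over each
#' unit step.  Integration is fixed-step RK4 with `substeps` internal steps
#' per unit; for the spiking family the reset `u_i > 0.5 => v_i = 0` is
#' applied after every internal step.
#'
#' @param spec A [reservoir_spec()].
#' @param drive A `spike_train` (spiking family) or numeric signal.
#' @param initial_state Optional starting state: for the spiking family a
#'   list with `u` and `v` (defaults: `u = 0.1`, `v = 0`), for the
#'   polynomial family a numeric vector `r` (defaults to zeros).  The
#'   spiking fast variable must start away from zero: `u = 0` is an
#'   invariant manifold of the node ODE (both terms are proportional to
#'   `u`), so a zero start would silence the reservoir permanently.
#' @param substeps Internal RK4 steps per unit output step; `NULL` means
#'   the family default: 15 for the spiking family (the fast cubic's local
#'   rate reaches `2 T_C` at the saturated state, so the internal step must
#'   keep `2 T_C / substeps` inside the RK4 stability region) and
#'   1 for the polynomial family, whose unit-step discretization is part of
#'   the computer: its numerical stability boundary, not that of the
#'   continuous flow, produces the instability seen for large `alpha`.
#' @param guard Divergence guard on \eqn{|state|} (default `1e6`).
#' @return A `reservoir_run`: list with `states` (`N x M` matrix of node
#'   outputs, `u` for spiking and `r` for polynomial), `aux` (`N x M` matrix
#'   of `v`, spiking only), `dt = 1`, `family` and `drive_reference`.
#' @export
simulate_reservoir <- function(spec, drive, initial_state = NULL,
                               substeps = NULL, guard = 1e6) {
  stopifnot(inherits(spec, "reservoir_spec"))
  substeps <- substeps %||% default_substeps(spec$family)
  s <- drive_values(drive)
  if (length(s) < 1) stop_invalid("drive must have length >= 1")
  M <- spec$M
  if (spec$family == "spiking") {
    u0 <- initial_state$u %||% rep(0.1, M)
    v0 <- initial_state$v %||% rep(0, M)
    sim <- spiking_sim_cpp(spec$adjacency, spec$input_weights,
                           spec$thresholds, spec$params$T_C,
                           spec$params$R_tau, spec$params$gamma,
                           s, as.integer(substeps), u0, v0, guard)
    states <- sim$u; aux <- sim$v
  } else {
    r0 <- if (is.list(initial_state)) initial_state$r %||% rep(0, M)
          else initial_state %||% rep(0, M)
    states <- poly_sim_cpp(spec$adjacency, spec$input_weights,
                           spec$params$alpha, spec$params$p1,
                           spec$params$p2, spec$params$p3,
                           s, as.integer(substeps), r0, guard)
    aux <- NULL
  }
  colnames(states) <- paste0("node_", seq_len(M))
  structure(list(states = states, aux = aux, dt = 1, family = spec$family,
                 drive_reference = attr(drive, "system_id") %||% NA_character_),
            class = "reservoir_run")
}

#' @export
print.reservoir_run <- function(x, ...) {
  cat(sprintf("reservoir run: %s family, %d steps x %d nodes\n",
              x$family, nrow(x$states), ncol(x$states)))
  invisible(x)
}

#' Write a reservoir run as CSV
#'
#' Columns `t, node_1, ..., node_M` (the node output series).
#'
#' @param run A `reservoir_run`.
#' @param path CSV file path.
#' @export
write_reservoir_run <- function(run, path) {
  df <- data.frame(t = seq_len(nrow(run$states)) * run$dt, run$states,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
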