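# The four algebraically minimal three-dimensional chaotic flows catalogued
# by Sprott (systems A-D) serve both as classification inputs and as the
# package's synthetic-data generator.

sprott_systems <- c("A", "B", "C", "D")

sprott_code <- function(system_id) {
  if (length(system_id) != 1L || !system_id %in% sprott_systems)
    stop_invalid("unknown Sprott system id: ", paste(system_id, collapse = ","),
                 " (must be one of A, B, C, D)")
  match(system_id, sprott_systems) - 1L
}

#' Vector field of a Sprott system
#'
#' Right-hand side of the chosen Sprott flow at a given state:
#' \describe{
#'   \item{A}{\eqn{\dot x = y,\ \dot y = -x + yz,\ \dot z = 1 - y^2}}
#'   \item{B}{\eqn{\dot x = yz,\ \dot y = x - y,\ \dot z = 1 - xy}}
#'   \item{C}{\eqn{\dot x = yz,\ \dot y = x - y,\ \dot z = 1 - x^2}}
#'   \item{D}{\eqn{\dot x = -y,\ \dot y = x + z,\ \dot z = xz - 3y^2}}
#' }
#'
#' @param system_id One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param state Numeric length-3 state `(x, y, z)`.
#' @return Named numeric vector `(x, y, z)` of time derivatives.
#' @export
sprott_derivative <- function(system_id, state) {
  code <- sprott_code(system_id)
  state <- as.numeric(state)
  if (length(state) != 3L || !all(is.finite(state)))
    stop_invalid("state must be a finite length-3 numeric vector")
  x <- state[1]; y <- state[2]; z <- state[3]
  d <- switch(code + 1L,
    c(y,      -x + y * z, 1 - y^2),
    c(y * z,   x - y,     1 - x * y),
    c(y * z,   x - y,     1 - x^2),
    c(-y,      x + z,     x * z + 3 * y^2))
  names(d) <- c("x", "y", "z")
  d
}

#' Integrate a Sprott system
#'
#' Classical fixed-step 4th-order Runge-Kutta integration with `substeps`
#' internal steps per output sample, so the internal step is
#' `dt_out / substeps`.  When `initial_state` is `NULL` an initial condition
#' is drawn uniformly from \eqn{[-0.1, 0.1]^3} using `seed`; because the
#' basin of the system-D attractor is interwoven with escaping sets near
#' the origin, a drawn condition whose trajectory diverges is rejected and
#' redrawn (deterministically from `seed`, up to 20 attempts), so seeded
#' draws always yield a bounded trajectory on the attractor.  An explicit
#' `initial_state` is never rejected: its divergence is an error.  The
#' first `transient_points` output samples are discarded.
#'
#' @param system_id One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param initial_state Length-3 numeric, or `NULL` for a seeded random draw.
#' @param dt_out Output sampling interval (dimensionless time).
#' @param n_points Number of retained samples.
#' @param transient_points Leading samples to discard (default 10000).
#' @param seed Seed for the random initial condition; ignored when
#'   `initial_state` is given.
#' @param substeps Internal RK4 steps per output sample (default 10).
#' @param guard Overflow guard; any \eqn{|component|} above it raises a
#'   divergence error naming the step.
#' @return A `sprott_trajectory`: a data frame with columns `t`, `x`, `y`,
#'   `z` and attributes `system_id`, `dt_out`, `seed`.
#' @export
integrate_sprott <- function(system_id, initial_state = NULL, dt_out = 0.01,
                             n_points, transient_points = 10000, seed = NULL,
                             substeps = 10, guard = 1e6) {
  code <- sprott_code(system_id)
  if (n_points < 1) stop_invalid("n_points must be >= 1")
  if (dt_out <= 0) stop_invalid("dt_out must be > 0")
  vals <- if (is.null(initial_state)) {
    out <- NULL
    for (attempt in seq_len(20)) {
      ic <- if (is.null(seed)) runif(3, -0.1, 0.1)
            else with_seed(if (attempt == 1) seed
                           else sub_seed(seed, 929, attempt),
                           runif(3, -0.1, 0.1))
      out <- tryCatch(
        sprott_rk4_cpp(code, ic, dt_out / substeps, substeps,
                       as.integer(n_points), as.integer(transient_points),
                       guard),
        error = function(e) e)
      if (!inherits(out, "error")) break
    }
    if (inherits(out, "error"))
      stop_invalid("all seeded initial conditions diverged: ",
                   conditionMessage(out))
    out
  } else {
    initial_state <- as.numeric(initial_state)
    if (length(initial_state) != 3L || !all(is.finite(initial_state)))
      stop_invalid("initial_state must be a finite length-3 numeric vector")
    sprott_rk4_cpp(code, initial_state, dt_out / substeps, substeps,
                   as.integer(n_points), as.integer(transient_points), guard)
  }
  out <- data.frame(t = (seq_len(n_points) - 1) * dt_out,
                    x = vals[, 1], y = vals[, 2], z = vals[, 3])
  structure(out, system_id = system_id, dt_out = dt_out, seed = seed,
            class = c("sprott_trajectory", "data.frame"))
}

#' @export
print.sprott_trajectory <- function(x, ...) {
  cat(sprintf("Sprott %s trajectory: %d samples, dt = %g\n",
              attr(x, "system_id"), nrow(x), attr(x, "dt_out")))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Rescale a signal to the unit interval
#'
#' Affine map sending the minimum of `signal` to 0 and its maximum to 1,
#' the normalization applied before spike encoding.
#'
#' @param signal Numeric vector with at least 2 points and `max > min`.
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_unit <- function(signal) {
  signal <- as.numeric(signal)
  if (length(signal) < 2L) stop_invalid("signal must have at least 2 points")
  rng <- range(signal)
  if (!all(is.finite(rng))) stop_invalid("signal must be finite")
  if (rng[2] <= rng[1])
    stop_invalid("degenerate input: constant signal cannot be normalized")
  (signal - rng[1]) / (rng[2] - rng[1])
}

#' Write / read a trajectory as CSV with a JSON sidecar
#'
#' The CSV holds columns `t, x, y, z`; the sidecar `<path>.json` records
#' `system_id`, `dt_out` and `seed` so the trajectory can be regenerated.
#'
#' @param trajectory A `sprott_trajectory`.
#' @param path CSV file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a `sprott_trajectory`.
#' @export
write_trajectory <- function(trajectory, path) {
  write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  meta <- list(system_id = attr(trajectory, "system_id"),
               dt_out = attr(trajectory, "dt_out"),
               seed = attr(trajectory, "seed"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  structure(df, system_id = meta$system_id, dt_out = meta$dt_out,
            seed = meta$seed, class = c("sprott_trajectory", "data.frame"))
}
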