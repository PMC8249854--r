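#' @useDynLib echoclass, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif cor sd rnorm
#' @importFrom utils write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state,
#' so seeded helpers do not perturb the global random stream.  With
#' `seed = NULL` the expression is evaluated with the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic derived seed, kept inside 32-bit integer range.
sub_seed <- function(seed, a = 0L, b = 0L) {
  s <- (as.double(seed) * 7919 + as.double(a) * 104729 + as.double(b) * 7) %% 2147483629
  as.integer(s)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

# Spiking: the stiffest local rate is ~2*T_C near the saturated fast state,
# so 15 sub-steps keep |lambda h| ~ 2 inside the RK4 stability region at the
# T_C = 15 operating point.  Polynomial: the unit-step map is the computer.
default_substeps <- function(family) if (family == "spiking") 15L else 1L
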