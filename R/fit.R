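# Linear readout training: design matrix, SVD ridge regression, and the two
# training-error statistics.

#' Assemble the readout design matrix
#'
#' Rows are the node outputs at consecutive post-transient steps; a final
#' column of ones absorbs any constant offset in the fit.
#'
#' @param run A `reservoir_run` or an `N x M` matrix of node outputs.
#' @param transient Leading steps discarded (default 1000).
#' @param n_fit Number of rows kept; defaults to everything after the
#'   transient.
#' @return An `n_fit x (M + 1)` matrix.
#' @export
build_design_matrix <- function(run, transient = 1000, n_fit = NULL) {
  states <- if (inherits(run, "reservoir_run")) run$states else as.matrix(run)
  n <- nrow(states)
  n_fit <- n_fit %||% (n - transient)
  if (n < transient + n_fit || n_fit < 1)
    stop_invalid("run too short: need transient + n_fit <= ", n,
                 " rows, got ", transient + n_fit)
  cbind(states[(transient + 1):(transient + n_fit), , drop = FALSE], 1)
}

#' Ridge regression of a training signal via the SVD
#'
#' Computes the singular value decomposition \eqn{\Omega = U S V^T} of the
#' design matrix and forms the regularized pseudo-inverse by replacing each
#' singular value \eqn{S_{ii}} with \eqn{S_{ii}/(S_{ii}^2 + k^2)}, a ridge
#' (Tikhonov) shrinkage that prevents overfitting of near-degenerate
#' directions.
#'
#' @param design Design matrix (rows = time steps).
#' @param target Training signal, one value per design row.
#' @param ridge_k Ridge constant \eqn{k} (default `1e-5`).
#' @return An `rc_fit`: list with `coefficients` (length `ncol(design)`),
#'   `fitted` (the fitted series), `ridge_k`, and `singular_values`.
#' @export
ridge_fit <- function(design, target, ridge_k = 1e-5) {
  design <- as.matrix(design)
  target <- as.numeric(target)
  if (nrow(design) != length(target))
    stop_invalid("design rows (", nrow(design), ") must equal target length (",
                 length(target), ")")
  if (all(design == 0)) stop_invalid("degenerate all-zero design matrix")
  sv <- svd(design)
  shrink <- sv$d / (sv$d^2 + ridge_k^2)
  coefs <- sv$v %*% (shrink * crossprod(sv$u, target))
  coefs <- drop(coefs)
  structure(list(coefficients = coefs, fitted = drop(design %*% coefs),
                 ridge_k = ridge_k, singular_values = sv$d),
            class = "rc_fit")
}

#' @export
coef.rc_fit <- function(object, ...) object$coefficients

#' @export
print.rc_fit <- function(x, ...) {
  cat(sprintf("ridge readout fit: %d coefficients, k = %g\n",
              length(x$coefficients), x$ridge_k))
  invisible(x)
}

#' Normalized-deviation training error
#'
#' \eqn{\Delta_{RC} = \mathrm{std}(fit - target) / \mathrm{std}(target)}:
#' 0 for a perfect fit (up to a constant shift), 1 for a constant fit.
#'
#' @param fit_series Fitted signal.
#' @param target Training signal of equal length.
#' @return Nonnegative scalar.
#' @export
training_error_rc <- function(fit_series, target) {
  stopifnot(length(fit_series) == length(target))
  s <- sd(target)
  if (s == 0) stop_invalid("degenerate constant target")
  sd(fit_series - target) / s
}

#' Cross-correlation training error
#'
#' \eqn{\Delta_{CC} = 1 - \rho}, where \eqn{\rho} is the Pearson correlation
#' between the fitted series and the spike target: 0 for a perfect fit, 1
#' for an uncorrelated fit, 2 for a perfectly anti-correlated one.
#'
#' @param fit_series Fitted signal.
#' @param spike_target Spike training signal of equal length.
#' @return Scalar in `[0, 2]`.
#' @export
training_error_cc <- function(fit_series, spike_target) {
  spike_target <- drive_values(spike_target)
  stopifnot(length(fit_series) == length(spike_target))
  if (sd(fit_series) == 0 || sd(spike_target) == 0)
    stop_invalid("degenerate constant input to cross-correlation error")
  1 - cor(fit_series, spike_target)
}
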