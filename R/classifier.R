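# Coefficient-distance classification of chaotic signals.  One readout
# coefficient vector is fitted per class during training; a test signal is
# assigned to the class whose stored coefficients are nearest (Euclidean) to
# the coefficients fitted on the test signal with the same network.

class_labels <- c("A", "B", "C", "D")

# Generate one drive/target pair for a class at the settings of a classifier:
# spiking family drives with the spike-encoded normalized x signal and
# targets the spike train itself; polynomial family drives with and targets
# the raw x signal.
make_instance <- function(spec, class, n_points, seed, st) {
  traj <- integrate_sprott(class, NULL, st$dt_out, n_points,
                           st$sprott_transient, seed = seed)
  if (spec$family == "spiking") {
    drive <- encode_spikes(normalize_unit(traj$x), st$t_min, st$t_max)
    list(drive = drive, target = as.numeric(drive$values))
  } else {
    list(drive = traj$x, target = traj$x)
  }
}

# Simulate + fit one instance; returns coefficients, training error and
# (optionally) the run for entropy computation.
fit_instance <- function(spec, class, n_points, seed, st, keep_run = FALSE) {
  inst <- make_instance(spec, class, n_points, seed, st)
  run <- simulate_reservoir(spec, inst$drive, substeps = st$substeps)
  n_fit <- n_points - st$transient
  omega <- build_design_matrix(run, st$transient, n_fit)
  target <- inst$target[(st$transient + 1):n_points]
  fit <- ridge_fit(omega, target, st$ridge_k)
  err <- if (spec$family == "spiking") training_error_cc(fit$fitted, target)
         else training_error_rc(fit$fitted, target)
  list(coefficients = coef(fit), training_error = err,
       run = if (keep_run) run else NULL, drive = inst$drive)
}

#' Train a coefficient-distance reservoir classifier
#'
#' For each of the four Sprott classes A-D, generates one training
#' realization of the system's `x` signal, drives the reservoir with it
#' (spike-encoded for the spiking family), and ridge-fits the readout to
#' reproduce the input.  The four coefficient vectors (length `M + 1`,
#' constant term included) are the trained model.
#'
#' @param spec A [reservoir_spec()]; the same network realization is reused
#'   for all classes and all subsequent testing.
#' @param train_length Training drive length in samples; defaults to 100000
#'   for the spiking family and 21000 for the polynomial family.
#' @param seed Seed governing the training-signal initial conditions.
#' @param ridge_k Ridge constant (default `1e-5`).
#' @param transient Reservoir steps discarded before fitting (default 1000).
#' @param dt_out Sprott output step; defaults to 0.01 (spiking) or 0.1
#'   (polynomial).
#' @param substeps Internal RK4 steps per reservoir output step (`NULL` =
#'   family default: 15 spiking, 1 polynomial).
#' @param t_min,t_max Spike-encoding period bounds (spiking family).
#' @param sprott_transient Discarded leading Sprott samples.
#' @param keep_states Keep the four training `reservoir_run`s (needed for
#'   entropy diagnostics; memory-heavy at full scale).
#' @return An `rc_classifier` with the 4 x (M+1) coefficient matrix, the
#'   per-class training errors, and all settings needed to process test
#'   signals identically.
#' @export
reservoir_classifier <- function(spec, train_length = NULL, seed = 1,
                                 ridge_k = 1e-5, transient = 1000,
                                 dt_out = NULL, substeps = NULL,
                                 t_min = 10, t_max = 100,
                                 sprott_transient = 10000,
                                 keep_states = FALSE) {
  stopifnot(inherits(spec, "reservoir_spec"))
  spiking <- spec$family == "spiking"
  train_length <- train_length %||% if (spiking) 100000 else 21000
  dt_out <- dt_out %||% if (spiking) 0.01 else 0.1
  substeps <- substeps %||% default_substeps(spec$family)
  st <- list(dt_out = dt_out, t_min = t_min, t_max = t_max,
             sprott_transient = sprott_transient, substeps = substeps,
             transient = transient, ridge_k = ridge_k)
  fits <- lapply(seq_along(class_labels), function(ci) {
    cl <- class_labels[ci]
    tryCatch(
      fit_instance(spec, cl, train_length, sub_seed(seed, ci, 0), st,
                   keep_run = keep_states),
      error = function(e) stop_invalid("training class ", cl, ": ",
                                       conditionMessage(e)))
  })
  names(fits) <- class_labels
  coefs <- do.call(rbind, lapply(fits, `[[`, "coefficients"))
  rownames(coefs) <- class_labels
  structure(list(spec = spec, class_coefficients = coefs,
                 training_errors = vapply(fits, `[[`, 0, "training_error"),
                 train_length = train_length, seed = seed, settings = st,
                 runs = if (keep_states) lapply(fits, `[[`, "run") else NULL),
            class = "rc_classifier")
}

#' @export
print.rc_classifier <- function(x, ...) {
  cat(sprintf("reservoir classifier: %s family, M = %d, trained on %d-sample signals\n",
              x$spec$family, x$spec$M, x$train_length))
  cat("training errors:\n")
  print(round(x$training_errors, 4))
  invisible(x)
}

#' @export
coef.rc_classifier <- function(object, ...) object$class_coefficients

#' @export
summary.rc_classifier <- function(object, ...) {
  cd <- as.matrix(stats::dist(object$class_coefficients))
  structure(list(family = object$spec$family, M = object$spec$M,
                 train_length = object$train_length,
                 training_errors = object$training_errors,
                 class_separation = cd),
            class = "summary.rc_classifier")
}

#' @export
print.summary.rc_classifier <- function(x, ...) {
  cat(sprintf("reservoir classifier (%s, M = %d)\n", x$family, x$M))
  cat("per-class training errors:\n"); print(round(x$training_errors, 4))
  cat("pairwise coefficient distances between classes:\n")
  print(round(x$class_separation, 4))
  invisible(x)
}

#' Euclidean distance between two readout coefficient vectors
#'
#' @param K,C Coefficient vectors of equal length.
#' @return \eqn{\sqrt{\sum_l (K_l - C_l)^2}}.
#' @export
coefficient_distance <- function(K, C) {
  if (length(K) != length(C))
    stop_invalid("coefficient vectors differ in length (", length(K),
                 " vs ", length(C), ")")
  sqrt(sum((K - C)^2))
}

#' Classify one coefficient vector against a trained model
#'
#' Picks the class whose stored coefficients minimize the Euclidean
#' distance; ties are broken by the fixed class order A < B < C < D.
#'
#' @param K Coefficient vector fitted on the test signal.
#' @param model An `rc_classifier`.
#' @return A class label, with the four distances as attribute `distances`.
#' @export
classify_instance <- function(K, model) {
  cc <- model$class_coefficients
  if (length(K) != ncol(cc))
    stop_invalid("coefficient vector length ", length(K),
                 " does not match model (", ncol(cc), ")")
  d <- apply(cc, 1, coefficient_distance, C = K)
  structure(names(d)[which.min(d)], distances = d)
}

#' Predict the class of new signals
#'
#' Each signal (raw Sprott `x` series or `sprott_trajectory`) is processed
#' exactly as in training — spike-encoded for the spiking family — then
#' simulated through the same network, ridge-fitted, and classified by
#' coefficient distance.
#'
#' @param object An `rc_classifier`.
#' @param newdata A numeric signal, a `sprott_trajectory`, or a list of
#'   either.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.rc_classifier <- function(object, newdata, ...) {
  if (!is.list(newdata) || inherits(newdata, "sprott_trajectory"))
    newdata <- list(newdata)
  st <- object$settings
  vapply(newdata, function(sig) {
    x <- if (inherits(sig, "sprott_trajectory")) sig$x else as.numeric(sig)
    drive <- if (object$spec$family == "spiking")
      encode_spikes(normalize_unit(x), st$t_min, st$t_max) else x
    target <- if (object$spec$family == "spiking")
      as.numeric(drive$values) else x
    run <- simulate_reservoir(object$spec, drive, substeps = st$substeps)
    n <- length(x)
    omega <- build_design_matrix(run, st$transient, n - st$transient)
    fit <- ridge_fit(omega, target[(st$transient + 1):n], st$ridge_k)
    as.character(classify_instance(coef(fit), object))
  }, "")
}

#' Build a classification report from truth/prediction labels
#'
#' @param truth,predicted Character vectors of class labels (A-D).
#' @param classes Class label set (default A-D).
#' @return An `rc_confusion`: row-stochastic confusion matrix (rows = true
#'   class), per-class counts, and overall `error_fraction`
#'   \eqn{E_C = 1 - } mean of the diagonal.
#' @export
classification_report <- function(truth, predicted, classes = class_labels) {
  stopifnot(length(truth) == length(predicted))
  truth <- factor(truth, levels = classes)
  predicted <- factor(predicted, levels = classes)
  counts <- table(truth = truth, predicted = predicted)
  n_per <- rowSums(counts)
  if (any(n_per == 0)) stop_invalid("every class needs at least one instance")
  confusion <- sweep(unclass(counts), 1, n_per, "/")
  structure(list(confusion = confusion, counts = unclass(counts),
                 error_fraction = 1 - mean(diag(confusion)),
                 n_instances = unname(n_per)),
            class = "rc_confusion")
}

#' @export
print.rc_confusion <- function(x, digits = 3, ...) {
  cat(sprintf("classification report: error fraction E_C = %.4f\n",
              x$error_fraction))
  cat("confusion matrix (rows = true class):\n")
  print(round(x$confusion, digits))
  invisible(x)
}

#' @export
plot.rc_confusion <- function(x, ...) {
  m <- x$confusion
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[nrow(m):1, ]),
                  axes = FALSE, xlab = "predicted", ylab = "true",
                  col = grDevices::hcl.colors(32, "Blues 3", rev = TRUE), ...)
  graphics::axis(1, seq_len(ncol(m)), colnames(m))
  graphics::axis(2, seq_len(nrow(m)), rev(rownames(m)))
  invisible(x)
}

#' Evaluate classification error over fresh test realizations
#'
#' For each class, `n_instances` independent realizations of the Sprott `x`
#' signal (fresh seeded initial conditions) of length `test_length` are
#' processed exactly as in training, fitted, and classified by coefficient
#' distance against the trained model.
#'
#' @param model An `rc_classifier`.
#' @param n_instances Test realizations per class (default 100).
#' @param test_length Test signal length; defaults to 5000 (spiking) or
#'   2000 (polynomial).
#' @param seed Seed governing the test initial conditions.
#' @return An `rc_confusion` (see [classification_report()]).
#' @export
evaluate_classification <- function(model, n_instances = 100,
                                    test_length = NULL, seed = 1) {
  stopifnot(inherits(model, "rc_classifier"))
  spiking <- model$spec$family == "spiking"
  test_length <- test_length %||% if (spiking) 5000 else 2000
  st <- model$settings
  truth <- character(0); predicted <- character(0)
  for (ci in seq_along(class_labels)) {
    cl <- class_labels[ci]
    for (j in seq_len(n_instances)) {
      res <- tryCatch(
        fit_instance(model$spec, cl, test_length,
                     sub_seed(seed, 1000 + ci, j), st),
        error = function(e) stop_invalid("test instance ", j, " of class ",
                                         cl, ": ", conditionMessage(e)))
      truth <- c(truth, cl)
      predicted <- c(predicted,
                     as.character(classify_instance(res$coefficients, model)))
    }
  }
  classification_report(truth, predicted)
}

#' Write a classification report as CSV / JSON
#'
#' @param report An `rc_confusion`.
#' @param csv_path Path for the labeled 4 x 4 confusion CSV.
#' @param json_path Optional path for a JSON record (confusion, counts,
#'   error fraction).
#' @export
write_classification_report <- function(report, csv_path, json_path = NULL) {
  write.csv(as.data.frame(report$confusion), csv_path, row.names = TRUE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(confusion = report$confusion, counts = report$counts,
           error_fraction = report$error_fraction,
           n_instances = report$n_instances),
      json_path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(csv_path)
}
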