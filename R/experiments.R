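# One-parameter sweep harness and the entropy-maximization optimizer.

#' Experiment configuration at the spiking operating point
#'
#' Bundles every knob of a classification experiment: node family and
#' parameters, network size and spectral radius, signal lengths, transient,
#' ridge constant, spike-encoding bounds, and the network seed held fixed
#' across a sweep.
#'
#' @param M Node count.
#' @param gamma,T_C,R_tau Spiking node parameters (operating point
#'   `gamma = 0.004`, `T_C = 15`, `R_tau = 36`).
#' @param sigma Spectral radius (0.5 spiking, 0.8 polynomial).
#' @param train_length,test_length Drive lengths for training and testing.
#' @param n_test_instances Test realizations per class.
#' @param transient Reservoir steps discarded before fitting.
#' @param ridge_k Ridge constant.
#' @param dt_out Sprott output step (0.01 spiking, 0.1 polynomial).
#' @param substeps Internal RK4 steps per reservoir step.
#' @param t_min,t_max Spike-encoding period bounds.
#' @param sprott_transient Discarded leading Sprott samples.
#' @param network_seed Seed of the network realization (fixed across a grid).
#' @param window_length Permutation-entropy window.
#' @return An `rc_config` list.
#' @export
spiking_config <- function(M = 100, gamma = 0.004, T_C = 15, R_tau = 36,
                           sigma = 0.5, train_length = 100000,
                           test_length = 5000, n_test_instances = 100,
                           transient = 1000, ridge_k = 1e-5, dt_out = 0.01,
                           substeps = 15, t_min = 10, t_max = 100,
                           sprott_transient = 10000, network_seed = 1,
                           window_length = 4) {
  structure(list(family = "spiking", M = M, gamma = gamma, T_C = T_C,
                 R_tau = R_tau, sigma = sigma, train_length = train_length,
                 test_length = test_length,
                 n_test_instances = n_test_instances, transient = transient,
                 ridge_k = ridge_k, dt_out = dt_out, substeps = substeps,
                 t_min = t_min, t_max = t_max,
                 sprott_transient = sprott_transient,
                 network_seed = network_seed, window_length = window_length),
            class = "rc_config")
}

#' @rdname spiking_config
#' @param p1,p2,p3,alpha Polynomial node parameters (operating point
#'   `p1 = -0.5`, `alpha = 0.3`; `p2 = 1`, `p3 = -1` complete the
#'   odd-saturating cubic).
#' @export
polynomial_config <- function(M = 100, p1 = -0.5, p2 = 1, p3 = -1,
                              alpha = 0.3, sigma = 0.8, train_length = 21000,
                              test_length = 2000, n_test_instances = 100,
                              transient = 1000, ridge_k = 1e-5, dt_out = 0.1,
                              substeps = 1, sprott_transient = 10000,
                              network_seed = 1, window_length = 4) {
  structure(list(family = "polynomial", M = M, p1 = p1, p2 = p2, p3 = p3,
                 alpha = alpha, sigma = sigma, train_length = train_length,
                 test_length = test_length,
                 n_test_instances = n_test_instances, transient = transient,
                 ridge_k = ridge_k, dt_out = dt_out, substeps = substeps,
                 t_min = NA, t_max = NA,
                 sprott_transient = sprott_transient,
                 network_seed = network_seed, window_length = window_length),
            class = "rc_config")
}

sweep_params_for <- function(family) {
  if (family == "spiking") c("gamma", "R_tau", "T_C", "sigma")
  else c("p1", "alpha", "sigma")
}

config_spec <- function(config) {
  if (config$family == "spiking")
    reservoir_spec("spiking", M = config$M,
                   params = spiking_params(T_C = config$T_C,
                                           R_tau = config$R_tau,
                                           gamma = config$gamma),
                   spectral_radius = config$sigma, seed = config$network_seed)
  else
    reservoir_spec("polynomial", M = config$M,
                   params = polynomial_params(alpha = config$alpha,
                                              p1 = config$p1, p2 = config$p2,
                                              p3 = config$p3),
                   spectral_radius = config$sigma, seed = config$network_seed)
}

config_settings <- function(config) {
  list(dt_out = config$dt_out, t_min = config$t_min, t_max = config$t_max,
       sprott_transient = config$sprott_transient,
       substeps = config$substeps, transient = config$transient,
       ridge_k = config$ridge_k)
}

set_config_param <- function(config, param_name, value) {
  valid <- sweep_params_for(config$family)
  if (!param_name %in% valid)
    stop_invalid("parameter '", param_name, "' is not sweepable for the ",
                 config$family, " family (valid: ",
                 paste(valid, collapse = ", "), ")")
  config[[param_name]] <- value
  config
}

#' Sweep one hyperparameter and measure every diagnostic
#'
#' For each grid value the reservoir is rebuilt (same network seed across
#' the whole grid, so curves vary only through the swept parameter), the
#' classifier is trained, the classification error over fresh test
#' instances is measured, and the per-class joint permutation entropy,
#' training errors and largest conditional Lyapunov exponent (on the class-A
#' training drive) are recorded.  Grid points whose simulation diverges are
#' recorded with `diverged = TRUE` rather than aborting the sweep.
#'
#' @param config An `rc_config` ([spiking_config()] or
#'   [polynomial_config()]).
#' @param param_name One of `gamma`, `R_tau`, `T_C`, `sigma` (spiking) or
#'   `p1`, `alpha`, `sigma` (polynomial).
#' @param grid Numeric vector of parameter values.
#' @param n_test_instances Test realizations per class (default from
#'   `config`).
#' @param seed Seed for training/test signal realizations (the same signal
#'   seeds are reused at every grid point).
#' @param lambda_steps Drive steps used for the conditional exponent
#'   (default `min(10000, train_length)`).
#' @return An `rc_sweep` data frame (one row per grid point) with the error
#'   fraction, per-system entropies and training errors, `lambda_max`, and
#'   a divergence flag; confusion matrices are attached as attribute
#'   `confusions`.
#' @export
sweep_parameter <- function(config, param_name, grid,
                            n_test_instances = NULL, seed = 1,
                            lambda_steps = NULL) {
  stopifnot(inherits(config, "rc_config"))
  if (length(grid) < 1) stop_invalid("grid must be nonempty")
  set_config_param(config, param_name, grid[1])  # validate the combination
  n_test_instances <- n_test_instances %||% config$n_test_instances
  lambda_steps <- lambda_steps %||% min(10000, config$train_length)
  rows <- vector("list", length(grid))
  confusions <- vector("list", length(grid))
  for (gi in seq_along(grid)) {
    cfg <- set_config_param(config, param_name, grid[gi])
    rec <- list(param_name = param_name, param_value = grid[gi],
                error_fraction = NA_real_,
                entropy_A = NA_real_, entropy_B = NA_real_,
                entropy_C = NA_real_, entropy_D = NA_real_,
                train_error_A = NA_real_, train_error_B = NA_real_,
                train_error_C = NA_real_, train_error_D = NA_real_,
                lambda_max = NA_real_, diverged = FALSE,
                message = "", seed = seed,
                n_test_instances = n_test_instances)
    res <- tryCatch({
      spec <- config_spec(cfg)
      model <- reservoir_classifier(
        spec, train_length = cfg$train_length, seed = seed,
        ridge_k = cfg$ridge_k, transient = cfg$transient,
        dt_out = cfg$dt_out, substeps = cfg$substeps, t_min = cfg$t_min,
        t_max = cfg$t_max, sprott_transient = cfg$sprott_transient,
        keep_states = TRUE)
      H <- vapply(model$runs, function(r)
        as.numeric(joint_permutation_entropy(r, cfg$window_length)), 0)
      lam <- largest_conditional_le(spec, fit_drive(model, "A"),
                                    n_steps = lambda_steps,
                                    substeps = cfg$substeps,
                                    seed = sub_seed(seed, 7, gi))
      report <- evaluate_classification(model, n_test_instances,
                                        cfg$test_length, seed)
      list(H = H, lam = lam, report = report,
           terr = model$training_errors)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rec$diverged <- TRUE
      rec$message <- conditionMessage(res)
    } else {
      rec$error_fraction <- res$report$error_fraction
      rec[paste0("entropy_", class_labels)] <- as.list(res$H)
      rec[paste0("train_error_", class_labels)] <- as.list(res$terr)
      rec$lambda_max <- as.numeric(res$lam)
      confusions[[gi]] <- res$report$confusion
    }
    rows[[gi]] <- rec
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r[names(rows[[1]])], stringsAsFactors = FALSE)))
  structure(out, confusions = confusions,
            class = c("rc_sweep", "data.frame"))
}

# Regenerate the training drive of a fitted classifier for one class (the
# classifier itself stores only coefficients and settings).
fit_drive <- function(model, class) {
  ci <- match(class, class_labels)
  make_instance(model$spec, class, model$train_length,
                sub_seed(model$seed, ci, 0), model$settings)$drive
}

#' Pick the hyperparameter value maximizing reservoir entropy
#'
#' Runs ONE training realization per class per grid point — no test
#' instances and no classification — computes the joint permutation entropy
#' of the reservoir response to each class, and returns the grid value with
#' the largest mean entropy across the four classes (ties broken by the
#' smaller grid index).  This is the cheap proxy for error-based
#' optimization: its simulation count (4 per grid point) is independent of
#' the number of test instances.
#'
#' @inheritParams sweep_parameter
#' @return An `rc_entropy_opt` list: `selected_value`, `selected_index`,
#'   the per-class entropy table, and `n_simulations` actually run.
#' @export
optimize_entropy <- function(config, param_name, grid, seed = 1) {
  stopifnot(inherits(config, "rc_config"))
  if (length(grid) < 1) stop_invalid("grid must be nonempty")
  set_config_param(config, param_name, grid[1])
  st0 <- config_settings(config)
  n_sim <- 0L
  tab <- matrix(NA_real_, length(grid), 4,
                dimnames = list(NULL, paste0("H_", class_labels)))
  for (gi in seq_along(grid)) {
    cfg <- set_config_param(config, param_name, grid[gi])
    spec <- try(config_spec(cfg), silent = TRUE)
    st <- config_settings(cfg)
    for (ci in seq_along(class_labels)) {
      h <- tryCatch({
        inst <- make_instance(spec, class_labels[ci], cfg$train_length,
                              sub_seed(seed, ci, 0), st)
        run <- simulate_reservoir(spec, inst$drive, substeps = cfg$substeps)
        n_sim <- n_sim + 1L
        as.numeric(joint_permutation_entropy(
          run$states[(cfg$transient + 1):nrow(run$states), , drop = FALSE],
          cfg$window_length))
      }, error = function(e) NA_real_)
      tab[gi, ci] <- h
    }
  }
  mean_H <- rowMeans(tab)
  if (all(is.na(mean_H)))
    stop_invalid("optimization failure: every grid point diverged")
  best <- which.max(mean_H)  # first index on ties
  structure(list(param_name = param_name,
                 selected_value = grid[best], selected_index = best,
                 entropy_table = data.frame(param_value = grid, tab,
                                            H_mean = mean_H),
                 n_simulations = n_sim, seed = seed),
            class = "rc_entropy_opt")
}

#' @export
print.rc_entropy_opt <- function(x, ...) {
  cat(sprintf("entropy-optimized %s = %g (grid point %d of %d; %d simulations)\n",
              x$param_name, x$selected_value, x$selected_index,
              nrow(x$entropy_table), x$n_simulations))
  print(x$entropy_table, digits = 4)
  invisible(x)
}

#' Write / read a sweep table as CSV (lossless round trip)
#'
#' Numeric columns are written with 17 significant digits so that
#' `read_sweep(write_sweep(x, f))` reproduces the doubles exactly.
#' Confusion matrices can be stored in a companion JSON file.
#'
#' @param sweep An `rc_sweep`.
#' @param path CSV file path.
#' @param json_path Optional path for the confusion matrices.
#' @export
write_sweep <- function(sweep, path, json_path = NULL) {
  df <- as.data.frame(sweep)
  out <- df
  num <- vapply(df, is.numeric, TRUE)
  out[num] <- lapply(df[num], function(col) sprintf("%.17g", col))
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  if (!is.null(json_path)) {
    conf <- attr(sweep, "confusions")
    jsonlite::write_json(conf, json_path, digits = NA, matrix = "rowmajor",
                         null = "null")
  }
  invisible(path)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  num_cols <- setdiff(names(df), c("param_name", "diverged", "message"))
  df$message <- as.character(df$message)
  df$message[is.na(df$message)] <- ""

  df[num_cols] <- lapply(df[num_cols], as.numeric)
  df$diverged <- as.logical(df$diverged)
  df$seed <- as.integer(df$seed)
  df$n_test_instances <- as.integer(df$n_test_instances)
  structure(df, class = c("rc_sweep", "data.frame"))
}
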