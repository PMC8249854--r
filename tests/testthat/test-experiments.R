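small_poly_cfg <- function(n_test_instances = 2, ...)
  polynomial_config(M = 20, train_length = 3000, test_length = 1200,
                    n_test_instances = n_test_instances, transient = 500,
                    sprott_transient = 2000, network_seed = 5, ...)

test_that("a sweep records one row per grid point, deterministically", {
  cfg <- small_poly_cfg()
  sw <- sweep_parameter(cfg, "alpha", 0.3, seed = 2)
  expect_equal(nrow(sw), 1)
  expect_equal(sw$param_value, 0.3)
  expect_false(sw$diverged)
  expect_true(sw$error_fraction >= 0 && sw$error_fraction <= 1)
  expect_true(all(sw[paste0("entropy_", c("A", "B", "C", "D"))] >= 0))
  sw2 <- sweep_parameter(cfg, "alpha", 0.3, seed = 2)
  expect_equal(as.data.frame(sw), as.data.frame(sw2))
})

test_that("invalid parameter/family combinations are rejected", {
  expect_error(sweep_parameter(small_poly_cfg(), "gamma", c(0.01)),
               "not sweepable")
  expect_error(sweep_parameter(spiking_config(), "p1", c(-0.5)),
               "not sweepable")
})

test_that("unstable grid points are flagged, not fatal", {
  cfg <- polynomial_config(train_length = 4000, test_length = 1200,
                           n_test_instances = 1, sprott_transient = 2000)
  sw <- sweep_parameter(cfg, "alpha", c(0.3, 0.6), seed = 2)
  expect_false(sw$diverged[1])
  expect_true(sw$diverged[2])
  expect_true(is.na(sw$error_fraction[2]))
  expect_match(sw$message[2], "diverged")
})

test_that("entropy optimization picks the verified argmax with 4 runs per point", {
  cfg <- small_poly_cfg()
  grid <- c(0.05, 0.2, 0.35)
  opt <- optimize_entropy(cfg, "alpha", grid, seed = 3)
  expect_equal(opt$n_simulations, 4L * length(grid))
  expect_equal(opt$selected_value, grid[opt$selected_index])
  # oracle recomputation of the per-class entropies at every grid point
  for (gi in seq_along(grid)) {
    cfg_gi <- cfg; cfg_gi$alpha <- grid[gi]
    spec <- echoclass:::config_spec(cfg_gi)
    H <- vapply(1:4, function(ci) {
      cl <- c("A", "B", "C", "D")[ci]
      inst <- echoclass:::make_instance(spec, cl, cfg$train_length,
                                        echoclass:::sub_seed(3, ci, 0),
                                        echoclass:::config_settings(cfg_gi))
      run <- simulate_reservoir(spec, inst$drive, substeps = cfg$substeps)
      as.numeric(joint_permutation_entropy(
        run$states[(cfg$transient + 1):nrow(run$states), ], 4))
    }, 0)
    expect_equal(unname(unlist(opt$entropy_table[gi, 2:5])), H,
                 tolerance = 1e-12)
  }
  expect_equal(opt$selected_index,
               which.max(opt$entropy_table$H_mean))
  # a single-point grid returns that point
  one <- optimize_entropy(cfg, "alpha", 0.2, seed = 3)
  expect_equal(one$selected_value, 0.2)
})

test_that("the optimizer cost does not depend on the number of test instances", {
  grid <- c(0.1, 0.3)
  o1 <- optimize_entropy(small_poly_cfg(n_test_instances = 2), "alpha",
                         grid, seed = 3)
  o2 <- optimize_entropy(small_poly_cfg(n_test_instances = 50), "alpha",
                         grid, seed = 3)
  expect_identical(o1$n_simulations, o2$n_simulations)
})

test_that("sweep tables round-trip losslessly through CSV", {
  cfg <- small_poly_cfg()
  sw <- sweep_parameter(cfg, "sigma", c(0.4, 0.8), seed = 4)
  path <- file.path(tempdir(), "sweep.csv")
  jpath <- file.path(tempdir(), "sweep.json")
  write_sweep(sw, path, jpath)
  back <- read_sweep(path)
  for (cn in names(sw))
    expect_equal(back[[cn]], sw[[cn]], tolerance = 0, label = cn)
  conf <- jsonlite::read_json(jpath, simplifyVector = FALSE)
  expect_equal(length(conf), 2)
  unlink(c(path, jpath))
})
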