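test_that("adjacency construction hits the spectral radius exactly", {
  A <- build_adjacency(100, 0.5, 0.5, 0.5, seed = 1)
  expect_equal(max(Mod(eigen(A, only.values = TRUE)$values)), 0.5,
               tolerance = 1e-8)
  A0 <- build_adjacency(10, 0.5, 0, 0.8, seed = 2)
  expect_true(all(diag(A0) == 0))
  # with the offset, the diagonal is the (rescaled) offset, applied after
  # zeroing — one constant on the whole diagonal
  Aoff <- build_adjacency(10, 0.5, 0.5, 0.5, seed = 2)
  expect_true(all(abs(diff(diag(Aoff))) < 1e-14))
  expect_gt(diag(Aoff)[1], 0)
})

test_that("symmetric uniform fill has near-zero mean over seeds", {
  means <- vapply(1:10, function(s)
    mean(build_adjacency(100, 0.5, 0, 1.0, seed = s)), 0)
  expect_lt(abs(mean(means)), 0.01)
})

test_that("input weights are uniform in range and seeded", {
  w <- build_input_weights(100, 0, 1, seed = 4)
  expect_true(all(w >= 0 & w <= 1))
  w2 <- build_input_weights(100, -1, 1, seed = 4)
  expect_true(all(w2 >= -1 & w2 <= 1))
  expect_identical(w, build_input_weights(100, 0, 1, seed = 4))
})

test_that("reservoir specs are reproducible and serializable", {
  s1 <- tiny_spiking_spec(seed = 7)
  s2 <- tiny_spiking_spec(seed = 7)
  expect_identical(s1$adjacency, s2$adjacency)
  expect_true(all(s1$thresholds >= 1 & s1$thresholds <= 1.1))
  path <- file.path(tempdir(), "spec.json")
  write_reservoir_spec(s1, path)
  back <- read_reservoir_spec(path)
  expect_equal(back$adjacency, s1$adjacency, tolerance = 1e-14)
  expect_equal(back$input_weights, s1$input_weights, tolerance = 1e-14)
  expect_equal(back$params$T_C, s1$params$T_C)
  unlink(path)
})

test_that("the origin is an equilibrium of the undriven spiking network", {
  spec <- tiny_spiking_spec()
  run <- simulate_reservoir(spec, rep(0, 50),
                            initial_state = list(u = rep(0, 20),
                                                 v = rep(0, 20)))
  expect_true(all(run$states == 0))
  expect_true(all(run$aux == 0))
})

test_that("the reset empties the slow variable whenever u exceeds 0.5", {
  spec <- tiny_spiking_spec(seed = 5)
  tr <- integrate_sprott("B", NULL, 0.01, 3000, 2000, seed = 8)
  sp <- encode_spikes(normalize_unit(tr$x))
  run <- simulate_reservoir(spec, sp)
  fired <- run$states > 0.5
  expect_gt(sum(fired), 0)  # the reservoir actually spikes
  expect_true(all(run$aux[fired] == 0))
})

test_that("a single node with the gate held open saturates at u = 1", {
  # a negative threshold keeps g = 1 even through resets (v = 0 > phi), so
  # the fast variable follows du/dt = T_C (u - u^3) towards its stable
  # fixed point at 1
  spec <- reservoir_spec("spiking", M = 1, adjacency = matrix(0, 1, 1),
                         input_weights = 5, thresholds = -1, seed = 1)
  drive <- structure(list(values = rep(1L, 100), t_min = 10L, t_max = 100L),
                     class = "spike_train")
  run <- simulate_reservoir(spec, drive)
  expect_equal(unname(run$states[100, 1]), 1, tolerance = 1e-6)
})

test_that("spiking outputs stay bounded at the operating point", {
  spec <- reservoir_spec("spiking", M = 50, seed = 2)
  tr <- integrate_sprott("A", NULL, 0.01, 5000, 10000, seed = 3)
  run <- simulate_reservoir(spec, encode_spikes(normalize_unit(tr$x)))
  expect_true(all(abs(run$states) <= 2))
})

test_that("the undriven polynomial network rests at the origin", {
  spec <- tiny_poly_spec()
  run <- simulate_reservoir(spec, rep(0, 50))
  expect_true(all(run$states == 0))
})

test_that("a single linear node relaxes to the drive fixed point", {
  spec <- reservoir_spec("polynomial", M = 1, adjacency = matrix(0, 1, 1),
                         input_weights = 1,
                         params = polynomial_params(alpha = 0.3, p1 = -1,
                                                    p2 = 0, p3 = 0), seed = 1)
  run <- simulate_reservoir(spec, rep(2, 200), substeps = 10)
  expect_equal(unname(run$states[200, 1]), 2, tolerance = 1e-6)
})

test_that("the linear polynomial response matches the exact map", {
  # scalar r' = alpha (p1 r + W s), drive constant per unit step: the exact
  # step map is r -> e^a r + (b/a)(e^a - 1) with a = alpha p1, b = alpha W s
  alpha <- 0.3; p1 <- -0.8; W <- 1.3
  spec <- reservoir_spec("polynomial", M = 1, adjacency = matrix(0, 1, 1),
                         input_weights = W,
                         params = polynomial_params(alpha = alpha, p1 = p1,
                                                    p2 = 0, p3 = 0), seed = 1)
  s <- sin(seq(0, 6, length.out = 120))
  run <- simulate_reservoir(spec, s, substeps = 10)
  a <- alpha * p1
  r <- 0; exact <- numeric(120)
  for (t in seq_along(s)) {
    b <- alpha * W * s[t]
    r <- exp(a) * r + (b / a) * (exp(a) - 1)
    exact[t] <- r
  }
  expect_equal(unname(run$states[, 1]), exact, tolerance = 1e-7)
})

test_that("polynomial outputs stay bounded at the operating point", {
  spec <- reservoir_spec("polynomial", M = 100, seed = 11)
  tr <- integrate_sprott("B", NULL, 0.1, 21000, 10000, seed = 42)
  run <- simulate_reservoir(spec, tr$x)
  expect_true(all(abs(run$states) < 1e3))
})

test_that("runs are fully determined by spec, drive and settings", {
  spec <- tiny_poly_spec(seed = 9)
  drive <- sin(seq(0, 10, length.out = 300))
  r1 <- simulate_reservoir(spec, drive)
  r2 <- simulate_reservoir(spec, drive)
  expect_identical(r1$states, r2$states)
})
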