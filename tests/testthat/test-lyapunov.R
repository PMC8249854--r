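test_that("a pure linear contraction has exponent -1", {
  res <- lyapunov_spectrum(function(s) -s, function(s) matrix(-1, 1, 1),
                           state0 = 1, dt = 0.01, n_steps = 5000)
  expect_equal(unname(res$exponents), -1, tolerance = 1e-3)
})

test_that("the compiled Sprott path agrees with the generic harness", {
  ic <- c(0.3, 0.2, 0.1)
  fast <- lyapunov_spectrum_sprott("B", n_steps = 3e4, initial_state = ic,
                                   transient = 5000)
  slow <- lyapunov_spectrum(function(s) unname(sprott_derivative("B", s)),
                            function(s) {
                              x <- s[1]; y <- s[2]; z <- s[3]
                              matrix(c(0, z, y, 1, -1, 0, -y, -x, 0),
                                     3, 3, byrow = TRUE)
                            },
                            state0 = drop(as.matrix(integrate_sprott(
                              "B", ic, 0.01, 1, 5000)[1, 2:4])),
                            dt = 0.01, n_steps = 3e4)
  expect_equal(unname(fast$exponents), unname(slow$exponents),
               tolerance = 0.05)
})

test_that("the spectrum is stable across renormalization intervals", {
  a <- lyapunov_spectrum_sprott("B", n_steps = 2e5, seed = 21,
                                renorm_interval = 5)
  b <- lyapunov_spectrum_sprott("B", n_steps = 2e5, seed = 21,
                                renorm_interval = 50)
  expect_equal(unname(a$exponents), unname(b$exponents), tolerance = 0.05)
  expect_true(all(diff(a$exponents) <= 0))  # sorted descending
})

test_that("decoupled linear nodes have conditional exponent alpha * p1", {
  spec <- reservoir_spec("polynomial", M = 5, adjacency = matrix(0, 5, 5),
                         input_weights = rep(1, 5),
                         params = polynomial_params(alpha = 0.3, p1 = -0.4,
                                                    p2 = 0, p3 = 0), seed = 1)
  drive <- sin(seq(0, 50, length.out = 2000))
  lam <- largest_conditional_le(spec, drive, substeps = 10, seed = 2)
  expect_equal(as.numeric(lam), 0.3 * -0.4, tolerance = 1e-3)
})

test_that("driven reservoirs at the operating points are contracting", {
  tr <- integrate_sprott("A", NULL, 0.01, 6000, 10000, seed = 17)
  sp <- encode_spikes(normalize_unit(tr$x))
  spik <- reservoir_spec("spiking", M = 50, seed = 3)
  lam_s <- largest_conditional_le(spik, sp, seed = 5)
  expect_lt(as.numeric(lam_s), 0)
  trp <- integrate_sprott("A", NULL, 0.1, 6000, 10000, seed = 17)
  poly <- reservoir_spec("polynomial", M = 50, seed = 3)
  lam_p <- largest_conditional_le(poly, trp$x, seed = 5)
  expect_lt(as.numeric(lam_p), 0)
})

test_that("the conditional exponent is insensitive to the tangent seed", {
  tr <- integrate_sprott("A", NULL, 0.01, 5000, 10000, seed = 17)
  sp <- encode_spikes(normalize_unit(tr$x))
  spec <- reservoir_spec("spiking", M = 50, seed = 3)
  l1 <- as.numeric(largest_conditional_le(spec, sp, seed = 1))
  l2 <- as.numeric(largest_conditional_le(spec, sp, seed = 99))
  expect_lt(abs(l1 - l2) / abs(l1), 0.1)
})

test_that("Sprott spectra satisfy the trace identity", {
  res <- lyapunov_spectrum_sprott("C", n_steps = 5e5, seed = 31)
  expect_equal(sum(res$exponents), -1, tolerance = 0.02)
})
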