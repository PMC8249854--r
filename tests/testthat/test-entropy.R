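test_that("ordinal patterns rank window values with time-index tie-breaks", {
  expect_equal(ordinal_symbol(c(0.1, 0.3, -0.1, 0.2)), c(2L, 4L, 1L, 3L))
  expect_equal(ordinal_symbol(1:4), 1:4)
  expect_equal(ordinal_symbol(c(5, 5, 5, 5)), 1:4)
  expect_equal(ordinal_symbol(c(2, 1)), c(2L, 1L))
})

test_that("degenerate symbol distributions give the closed-form entropies", {
  x <- matrix(rep(1:40, 3), 40, 3)  # all nodes strictly increasing
  H <- joint_permutation_entropy(x, 4)
  expect_equal(as.numeric(H), 0)
  expect_equal(attr(H, "n_symbols"), 1L)
  # two joint symbols with equal frequency
  y <- matrix(rep(c(1, 2, 3, 4, 4, 3, 2, 1), 10), ncol = 1)
  expect_equal(as.numeric(joint_permutation_entropy(y, 4)), log(2))
})

test_that("the vectorized entropy matches brute-force symbol counting", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(40 * 3), 40, 3)
    expect_equal(as.numeric(joint_permutation_entropy(x, 4)),
                 bf_joint_permutation_entropy(x, 4), tolerance = 1e-12)
    expect_equal(as.numeric(joint_permutation_entropy(x, 3)),
                 bf_joint_permutation_entropy(x, 3), tolerance = 1e-12)
  }
})

test_that("permutation entropy is invariant under monotone transforms and bounded", {
  set.seed(10)
  x <- matrix(rnorm(200 * 4), 200, 4)
  H <- joint_permutation_entropy(x, 4)
  expect_equal(as.numeric(joint_permutation_entropy(exp(x), 4)),
               as.numeric(H), tolerance = 1e-12)
  expect_gte(as.numeric(H), 0)
  expect_lte(as.numeric(H), log(attr(H, "n_symbols")) + 1e-12)
})

test_that("sliding windows enumerate every offset", {
  set.seed(2)
  x <- matrix(rnorm(30), ncol = 1)
  H <- joint_permutation_entropy(x, 4, sliding = TRUE)
  expect_equal(attr(H, "n_windows"), 27L)
  expect_error(joint_permutation_entropy(x[1:3, , drop = FALSE], 4),
               "shorter")
})

test_that("unit-spaced points give the digamma-only entropy", {
  x <- cbind(1:30, 0)  # k = 1 neighbor distance is exactly 1 everywhere
  H <- nn_entropy(x, k_neighbors = 1, n_index_points = 30, normalize = FALSE)
  expect_equal(as.numeric(H), digamma(30) - digamma(1), tolerance = 1e-12)
})

test_that("nearest-neighbor entropy matches the exhaustive pairwise oracle", {
  set.seed(4)
  x <- matrix(rnorm(20 * 2), 20, 2)
  H <- nn_entropy(x, k_neighbors = 3, n_index_points = 20)
  expect_equal(as.numeric(H), bf_nn_entropy(x, 3), tolerance = 1e-12)
  # and on a wider cloud with the default scaling disabled
  H2 <- nn_entropy(x * 10, k_neighbors = 5, n_index_points = 20,
                   normalize = FALSE)
  expect_equal(as.numeric(H2), bf_nn_entropy(x * 10, 5, normalize = FALSE),
               tolerance = 1e-12)
})

test_that("duplicated points are excluded or rejected", {
  x <- matrix(rnorm(20), 10, 2)
  dup <- x[rep(1:10, each = 2), ]
  expect_error(suppressWarnings(nn_entropy(dup, k_neighbors = 1,
                                           n_index_points = 20)),
               "degenerate")
  some <- rbind(x, x[1:2, ])
  expect_warning(nn_entropy(some, k_neighbors = 1, n_index_points = 12,
                            seed = 1), "excluded")
})

test_that("entropy grows with window length on a reservoir run", {
  spec <- tiny_poly_spec(seed = 6)
  tr <- integrate_sprott("B", NULL, 0.1, 4000, 10000, seed = 13)
  run <- simulate_reservoir(spec, tr$x)
  H <- vapply(3:5, function(w)
    as.numeric(joint_permutation_entropy(run$states[501:4000, ], w)), 0)
  expect_true(all(diff(H) >= 0))
})
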