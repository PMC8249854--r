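# Small fixtures and independent brute-force oracles used across the suite.

tiny_spiking_spec <- function(M = 20, seed = 3, ...)
  reservoir_spec("spiking", M = M, seed = seed, ...)

tiny_poly_spec <- function(M = 20, seed = 3, ...)
  reservoir_spec("polynomial", M = M, seed = seed, ...)

# Brute-force joint permutation entropy: explicit window enumeration and
# dictionary counting, independent of the vectorized implementation.
bf_joint_permutation_entropy <- function(x, w) {
  x <- as.matrix(x)
  n_win <- nrow(x) %/% w
  counts <- new.env(hash = TRUE)
  for (iw in seq_len(n_win)) {
    rows <- ((iw - 1) * w + 1):(iw * w)
    key <- paste(vapply(seq_len(ncol(x)), function(m)
      paste(ordinal_symbol(x[rows, m]), collapse = "-"), ""),
      collapse = "|")
    counts[[key]] <- (counts[[key]] %||% 0) + 1
  }
  p <- unlist(as.list(counts)) / n_win
  -sum(p * log(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force k-th nearest-neighbor entropy with every point as an index
# point, via the full pairwise distance matrix.
bf_nn_entropy <- function(x, k, normalize = TRUE) {
  x <- as.matrix(x)
  if (normalize) {
    sds <- apply(x, 2, sd)
    sds[sds == 0] <- 1
    x <- sweep(x, 2, sds, "/")
  }
  D <- as.matrix(dist(x))
  diag(D) <- Inf
  eps <- apply(D, 1, function(row) sort(row)[k])
  digamma(nrow(x)) - digamma(k) + mean(log(eps))
}

# Closed-form ridge solution from the normal equations.
bf_ridge <- function(design, target, k) {
  p <- ncol(design)
  solve(crossprod(design) + k^2 * diag(p), crossprod(design, target))
}
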