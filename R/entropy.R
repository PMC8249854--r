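# Entropy statistics of the reservoir state: joint permutation entropy over
# ordinal patterns, and a nearest-neighbor (digamma) entropy estimate.

#' Ordinal pattern of a window
#'
#' Rank vector of the window values: entry `i` is the rank of the `i`-th
#' point, so the window `(0.1, 0.3, -0.1, 0.2)` gives `(2, 4, 1, 3)`.  Ties
#' are broken by time index (the earlier point ranks lower).
#'
#' @param window Numeric vector of length >= 2.
#' @return Integer permutation of `1:length(window)`.
#' @export
ordinal_symbol <- function(window) {
  if (length(window) < 2) stop_invalid("window must have length >= 2")
  as.integer(rank(window, ties.method = "first"))
}

# Vectorized per-node ordinal pattern ids over all windows at once.
# x: N x M matrix; starts: window start indices; w: window length.
# Returns an n_win x M integer matrix of pattern codes (base w+1 packing).
ordinal_codes <- function(x, starts, w) {
  slices <- lapply(seq_len(w) - 1L, function(k) x[starts + k, , drop = FALSE])
  code <- matrix(0L, length(starts), ncol(x))
  for (i in seq_len(w)) {
    r <- matrix(1L, length(starts), ncol(x))
    for (j in seq_len(w)) {
      if (j == i) next
      r <- r + if (j < i) (slices[[j]] <= slices[[i]])
               else (slices[[j]] < slices[[i]])
    }
    code <- code * (w + 1L) + r
  }
  code
}

#' Joint permutation entropy of a multivariate series
#'
#' Each node's series is divided into consecutive non-overlapping windows of
#' `window_length` points (a trailing partial window is discarded) and each
#' window is replaced by its ordinal pattern.  The tuple of all nodes'
#' simultaneous patterns is the reservoir symbol for that window; the
#' entropy is the Shannon entropy (natural log) of the observed symbol
#' distribution.  Although the joint symbol space is astronomically large,
#' common driving confines the reservoir to a handful of symbols, so the
#' distribution is held in a sparse table.
#'
#' @param node_series `N x M` matrix of node outputs, or a `reservoir_run`.
#' @param window_length Ordinal pattern length (default 4).
#' @param sliding Use overlapping (sliding) windows instead of the default
#'   consecutive partition; intended for sensitivity checks.
#' @return Entropy in nats, with attributes `n_symbols` (distinct joint
#'   symbols observed) and `n_windows`.
#' @export
joint_permutation_entropy <- function(node_series, window_length = 4,
                                      sliding = FALSE) {
  x <- if (inherits(node_series, "reservoir_run")) node_series$states
       else as.matrix(node_series)
  w <- as.integer(window_length)
  n <- nrow(x)
  if (n < w) stop_invalid("series length ", n, " is shorter than the window (", w, ")")
  starts <- if (sliding) seq_len(n - w + 1L)
            else (seq_len(n %/% w) - 1L) * w + 1L
  code <- ordinal_codes(x, starts, w)
  keys <- if (ncol(code) == 1L) as.character(code[, 1])
          else do.call(paste, c(as.data.frame(code), sep = "."))
  counts <- table(keys)
  p <- as.numeric(counts) / length(keys)
  structure(-sum(p * log(p)), n_symbols = length(counts),
            n_windows = length(keys))
}

#' Nearest-neighbor entropy of the reservoir state cloud
#'
#' Treats the rows of `node_series` as points in M dimensions (each
#' coordinate scaled by its standard deviation), draws `n_index_points`
#' seeded random index points, finds each index point's Euclidean distance
#' \eqn{\epsilon_n} to its `k`-th nearest neighbor (self excluded), and
#' returns \eqn{H_{nn} = \psi(N) - \psi(k) + \langle \ln \epsilon_n
#' \rangle} with \eqn{\psi} the digamma function.  Index points with a zero
#' `k`-th-neighbor distance (duplicated rows) are excluded from the mean
#' with a warning.
#'
#' @param node_series `N x M` matrix or `reservoir_run`.
#' @param k_neighbors Neighbor order `k` (default 10).
#' @param n_index_points Number of index points (default `min(N, 1000)`).
#' @param seed Seed for the index-point draw.
#' @param normalize Scale each coordinate by its standard deviation
#'   (default `TRUE`).
#' @return Entropy estimate (nats) with attributes `k`, `n_index_points`
#'   and `n_excluded`.
#' @export
nn_entropy <- function(node_series, k_neighbors = 10, n_index_points = NULL,
                       seed = NULL, normalize = TRUE) {
  x <- if (inherits(node_series, "reservoir_run")) node_series$states
       else as.matrix(node_series)
  n <- nrow(x)
  k <- as.integer(k_neighbors)
  if (k < 1) stop_invalid("k_neighbors must be >= 1")
  if (n <= k) stop_invalid("need more points than neighbors (N > k)")
  n_index_points <- n_index_points %||% min(n, 1000L)
  if (n_index_points > n) stop_invalid("n_index_points cannot exceed N")
  if (n_index_points < 1) stop_invalid("n_index_points must be >= 1")
  if (normalize) {
    sds <- apply(x, 2, sd)
    sds[sds == 0] <- 1  # constant coordinates carry no distance information
    x <- sweep(x, 2, sds, "/")
  }
  idx <- if (n_index_points == n) seq_len(n)
         else with_seed(seed, sort(sample.int(n, n_index_points)))
  sq <- rowSums(x^2)
  # squared distances from index points to all points via the Gram trick
  d2 <- matrix(sq, n_index_points, n, byrow = TRUE) + sq[idx] -
    2 * tcrossprod(x[idx, , drop = FALSE], x)
  d2[cbind(seq_len(n_index_points), idx)] <- Inf  # exclude self
  eps <- sqrt(pmax(vapply(seq_len(n_index_points), function(i)
    sort(d2[i, ], partial = k)[k], 0), 0))
  zero <- eps <= 0
  if (all(zero))
    stop_invalid("degenerate point set: all k-th neighbor distances are zero")
  if (any(zero))
    warning(sum(zero), " index point(s) with duplicated neighbors excluded")
  structure(digamma(n) - digamma(k) + mean(log(eps[!zero])),
            k = k, n_index_points = n_index_points, n_excluded = sum(zero))
}
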