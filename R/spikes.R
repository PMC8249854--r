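# Spike encoding: a normalized continuous signal is converted to a binary
# event series whose inter-spike interval tracks the signal amplitude.

#' Encode a normalized signal as a spike train
#'
#' Walks the signal with a read pointer `i0`: at each visit the next spike
#' period is `floor(s[i0] * (t_max - t_min)) + t_min` samples, a spike is
#' written at `i1 = i0 + period`, and the pointer jumps to `i1`.  The loop
#' stops when the pointer passes the end of the signal; a spike that would
#' fall beyond the last sample is not written.  Large signal values thus
#' produce long inter-spike intervals (up to `t_max`) and small values short
#' ones (down to `t_min`).
#'
#' @param norm_signal Numeric vector with all values in `[0, 1]`.
#' @param t_min,t_max Integer period bounds in samples (defaults 10 and 100).
#' @return A `spike_train`: list with binary `values` (0/1, same length as
#'   the input) and the period bounds `t_min`, `t_max`.
#' @export
encode_spikes <- function(norm_signal, t_min = 10, t_max = 100) {
  s <- as.numeric(norm_signal)
  if (anyNA(s) || any(s < 0 | s > 1))
    stop_invalid("norm_signal values must lie in [0, 1]")
  if (t_max <= t_min || t_min < 1)
    stop_invalid("need t_max > t_min >= 1")
  n <- length(s)
  sv <- integer(n)
  i0 <- 1L
  while (i0 < n) {
    period <- floor(s[i0] * (t_max - t_min)) + t_min
    i1 <- i0 + as.integer(period)
    if (i1 > n) break
    sv[i1] <- 1L
    i0 <- i1
  }
  structure(list(values = sv, t_min = as.integer(t_min),
                 t_max = as.integer(t_max)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  idx <- spike_indices(x)
  cat(sprintf("spike train: %d samples, %d spikes, period bounds [%d, %d]\n",
              length(x$values), length(idx), x$t_min, x$t_max))
  if (length(idx))
    cat("first spikes at:", paste(utils::head(idx), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.numeric.spike_train <- function(x, ...) as.numeric(x$values)

#' @export
length.spike_train <- function(x) length(x$values)

#' Indices of the spikes in a spike train
#' @param spikes A `spike_train`.
#' @return Integer vector of 1-based spike sample indices.
#' @export
spike_indices <- function(spikes) which(spikes$values == 1L)

#' Write / read a spike train as CSV
#'
#' Columns `index` (1-based) and `S_V`; period bounds go in a `<path>.json`
#' sidecar.
#'
#' @param spikes A `spike_train`.
#' @param path CSV file path.
#' @export
write_spike_train <- function(spikes, path) {
  write.csv(data.frame(index = seq_along(spikes$values), S_V = spikes$values),
            path, row.names = FALSE)
  jsonlite::write_json(list(t_min = spikes$t_min, t_max = spikes$t_max),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_spike_train
#' @export
read_spike_train <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  structure(list(values = as.integer(df$S_V), t_min = meta$t_min,
                 t_max = meta$t_max),
            class = "spike_train")
}
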