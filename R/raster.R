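#' Spike raster
#'
#' A spike raster is the record of (neuron, time) events of a simulation: a
#' data frame with integer column `neuron` and numeric column `time` (ms),
#' sorted by time with ties broken by neuron id.
#'
#' @param neuron Integer neuron ids.
#' @param time Spike times, ms.
#' @param n_neurons Optional size of the id space (recorded as an attribute).
#' @return A `data.frame` of class `spike_raster`.
#' @export
spike_raster <- function(neuron = integer(), time = numeric(), n_neurons = NULL) {
  neuron <- as.integer(neuron)
  time <- as.numeric(time)
  if (length(neuron) != length(time))
    stop_contract("neuron and time must have equal length")
  o <- order(time, neuron)
  r <- data.frame(neuron = neuron[o], time = time[o])
  class(r) <- c("spike_raster", "data.frame")
  attr(r, "n_neurons") <- if (is.null(n_neurons)) (if (nrow(r)) max(r$neuron) else 0L) else as.integer(n_neurons)
  r
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("spike raster: %d spikes, %d neuron ids", nrow(x), attr(x, "n_neurons")))
  if (nrow(x)) cat(sprintf(", t in [%g, %g] ms", min(x$time), max(x$time)))
  cat("\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Read / write spike rasters as two-column delimited text
#'
#' The on-disk format is plain text with two columns, `neuron` (integer id)
#' and `time` (ms), tab-separated with a header line. The writer guarantees
#' the file is sorted by time.
#'
#' @param raster A [spike_raster()].
#' @param path File path.
#' @return `read_spike_raster` returns a `spike_raster`;
#'   `write_spike_raster` returns `path` invisibly.
#' @export
write_spike_raster <- function(raster, path) {
  o <- order(raster$time, raster$neuron)
  utils::write.table(data.frame(neuron = raster$neuron[o], time = raster$time[o]),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_raster
#' @export
read_spike_raster <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("integer", "numeric"))
  spike_raster(d[[1]], d[[2]])
}

#' Compare two spike rasters by greedy per-neuron matching
#'
#' For every neuron id, spikes of `a` and `b` are matched greedily in time
#' order: the earliest unmatched pair within `match_window` ms is paired.
#' Reports matched and unmatched counts, the mean absolute time difference
#' of matched pairs, and the unmatched fraction
#' `(unmatched_a + unmatched_b) / (n_a + n_b)`.
#'
#' @param a,b [spike_raster()] objects over the same neuron id space.
#' @param match_window Maximum |time difference| for a match, ms.
#' @return A list of class `raster_comparison`.
#' @export
compare_rasters <- function(a, b, match_window = 1) {
  ids <- union(unique(a$neuron), unique(b$neuron))
  matched <- 0L
  abs_dt <- 0
  ua <- 0L
  ub <- 0L
  for (id in ids) {
    ta <- a$time[a$neuron == id]
    tb <- b$time[b$neuron == id]
    i <- 1L; j <- 1L
    while (i <= length(ta) && j <= length(tb)) {
      d <- ta[i] - tb[j]
      if (abs(d) <= match_window) {
        matched <- matched + 1L
        abs_dt <- abs_dt + abs(d)
        i <- i + 1L; j <- j + 1L
      } else if (d < 0) {
        ua <- ua + 1L; i <- i + 1L
      } else {
        ub <- ub + 1L; j <- j + 1L
      }
    }
    ua <- ua + length(ta) - i + 1L
    ub <- ub + length(tb) - j + 1L
  }
  total <- nrow(a) + nrow(b)
  structure(list(matched = matched, unmatched_a = ua, unmatched_b = ub,
                 n_a = nrow(a), n_b = nrow(b),
                 mean_abs_dt = if (matched) abs_dt / matched else NA_real_,
                 unmatched_fraction = if (total) (ua + ub) / total else 0),
            class = "raster_comparison")
}

#' @export
print.raster_comparison <- function(x, ...) {
  cat(sprintf("raster comparison: %d matched (mean |dt| = %.4g ms), %d + %d unmatched (fraction %.4g)\n",
              x$matched, x$mean_abs_dt, x$unmatched_a, x$unmatched_b, x$unmatched_fraction))
  invisible(x)
}
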