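#' Encoder configuration
#'
#' @param mode `"time"` (latency coding: at most one spike per pixel, with
#'   latency decreasing in intensity) or `"frequency"` (rate coding: a
#'   stochastic train per pixel with rate proportional to intensity).
#' @param duration Encoding window per sample, ms (conventionally 100 ms
#'   for time coding and 350 ms for frequency coding).
#' @param max_rate Rate of a full-intensity pixel in frequency mode, Hz.
#' @param intensity_threshold Pixel value at or below which no spike is
#'   emitted (time mode).
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(mode = c("time", "frequency"), duration = NULL,
                           max_rate = 63.75, intensity_threshold = 0) {
  mode <- match.arg(mode)
  if (is.null(duration)) duration <- if (mode == "time") 100 else 350
  if (duration <= 0) stop_contract("duration must be > 0")
  if (mode == "frequency" && max_rate <= 0) stop_contract("max_rate must be > 0")
  structure(list(mode = mode, duration = as.numeric(duration),
                 max_rate = as.numeric(max_rate),
                 intensity_threshold = as.numeric(intensity_threshold)),
            class = "encoder_config")
}

.check_pixels <- function(image) {
  if (any(!is.finite(image)) || any(image < 0) || any(image > 255))
    stop_contract("pixel values must lie in [0, 255]")
}

#' Latency (time) encoding of a grayscale image
#'
#' Each pixel above the intensity threshold emits exactly one spike at
#' latency `duration * (1 - p/255)`: brighter pixels spike earlier, a
#' full-intensity pixel at t = 0, and pixels at or below the threshold not
#' at all. Channel ids follow the column-major linearization of the image
#' matrix.
#'
#' @param image Numeric matrix of pixel values in `[0, 255]`.
#' @param config An [encoder_config()] with `mode = "time"`.
#' @return A [spike_raster()] with at most one spike per pixel, times in
#'   `[0, duration)`.
#' @export
time_encode <- function(image, config = encoder_config("time")) {
  .check_pixels(image)
  p <- as.vector(image)
  on <- which(p > config$intensity_threshold)
  spike_raster(on, config$duration * (1 - p[on] / 255), n_neurons = length(p))
}

#' Rate (frequency) encoding of a grayscale image
#'
#' Each pixel emits a homogeneous Poisson spike train over the encoding
#' window with rate `max_rate * p / 255` Hz. Seeded, hence reproducible.
#'
#' @inheritParams time_encode
#' @param config An [encoder_config()] with `mode = "frequency"`.
#' @param seed Optional RNG seed.
#' @return A [spike_raster()], times in `[0, duration)`.
#' @export
frequency_encode <- function(image, config = encoder_config("frequency"), seed = NULL) {
  .check_pixels(image)
  p <- as.vector(image)
  rate <- config$max_rate * p / 255 # Hz
  with_seed(seed, {
    counts <- stats::rpois(length(p), rate * config$duration / 1000)
    ids <- rep.int(seq_along(p), counts)
    spike_raster(ids, stats::runif(sum(counts), 0, config$duration),
                 n_neurons = length(p))
  })
}

#' Fixed-rate benchmark input generator
#'
#' Generates `n_inputs` independent spike trains at a stated mean rate, the
#' stimulus of the two-layer performance benchmarks (e.g. 200 channels at
#' 10 Hz for 10,000 ms gives 20,000 spikes). Three dialects are provided:
#' `"poisson"` draws homogeneous Poisson trains (total count is itself
#' Poisson); `"uniform"` places exactly `round(rate * duration / 1000)`
#' spikes per channel at uniform times, reproducing benchmark protocols
#' that state the total spike count exactly; `"regular"` emits per-channel
#' periodic trains with a random phase and Gaussian jitter of `jitter_sd`
#' ms.
#'
#' @param n_inputs Number of input channels.
#' @param rate Mean firing rate per channel, Hz.
#' @param duration Stimulus duration, ms.
#' @param seed Optional RNG seed.
#' @param dialect `"poisson"` (default), `"uniform"`, or `"regular"`.
#' @param jitter_sd Jitter standard deviation for the regular dialect, ms.
#' @return A [spike_raster()] with channel ids `1..n_inputs` and times in
#'   `[0, duration)`.
#' @export
benchmark_input <- function(n_inputs, rate, duration, seed = NULL,
                            dialect = c("poisson", "uniform", "regular"),
                            jitter_sd = 1) {
  dialect <- match.arg(dialect)
  if (n_inputs < 1) stop_contract("n_inputs must be >= 1")
  if (rate <= 0) stop_contract("rate must be > 0")
  with_seed(seed, {
    if (dialect == "poisson") {
      counts <- stats::rpois(n_inputs, rate * duration / 1000)
      ids <- rep.int(seq_len(n_inputs), counts)
      times <- stats::runif(sum(counts), 0, duration)
    } else if (dialect == "uniform") {
      k <- round(rate * duration / 1000)
      ids <- rep.int(seq_len(n_inputs), rep.int(k, n_inputs))
      times <- stats::runif(n_inputs * k, 0, duration)
    } else {
      period <- 1000 / rate
      ids <- integer(0)
      times <- numeric(0)
      for (i in seq_len(n_inputs)) {
        ti <- seq(stats::runif(1, 0, period), duration, by = period)
        ti <- ti + stats::rnorm(length(ti), 0, jitter_sd)
        ti <- ti[ti >= 0 & ti < duration]
        ids <- c(ids, rep.int(i, length(ti)))
        times <- c(times, ti)
      }
    }
    spike_raster(ids, times, n_neurons = n_inputs)
  })
}

#' Read IDX-format array files
#'
#' Parses the IDX container format used to distribute handwritten-digit
#' image and label sets: a big-endian magic number giving the element type
#' and rank, the dimension sizes, then the raw elements. Unsigned-byte
#' (0x08) and signed-byte, short, int, float and double element types are
#' supported.
#'
#' @param path Path to an IDX file (optionally gzip-compressed, `.gz`).
#' @return For rank-1 files, a vector; for rank-3 image files, a numeric
#'   array `c(n, rows, cols)`.
#' @export
read_idx <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (magic[1] != 0 || magic[2] != 0) stop_contract("not an IDX file: ", path)
  type <- as.integer(magic[3])
  rank <- as.integer(magic[4])
  dims <- readBin(con, "integer", rank, size = 4L, endian = "big")
  n <- prod(dims)
  data <- switch(as.character(type),
    "8" = as.integer(readBin(con, "raw", n)),
    "9" = readBin(con, "integer", n, size = 1L, signed = TRUE, endian = "big"),
    "11" = readBin(con, "integer", n, size = 2L, signed = TRUE, endian = "big"),
    "12" = readBin(con, "integer", n, size = 4L, endian = "big"),
    "13" = readBin(con, "numeric", n, size = 4L, endian = "big"),
    "14" = readBin(con, "numeric", n, size = 8L, endian = "big"),
    stop_contract("unsupported IDX element type: 0x", format(as.hexmode(type)))
  )
  if (rank == 1L) return(data)
  # IDX stores row-major; return an array indexed [item, row, col, ...]
  aperm(array(data, dim = rev(dims)), rev(seq_len(rank)))
}
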