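#' Define a neuron population
#'
#' A population is a group of LIF neurons sharing one parameter set and —
#' because dense layer-to-layer projections deliver every incoming spike to
#' every member — one common last-update time, the precondition for reusing
#' decay factors across the population.
#'
#' Direct lateral inhibition is a population attribute: when a member fires,
#' every sibling receives an instantaneous suppression at the same
#' timestamp and its predicted spike is re-derived. `"subtract"` lowers the
#' sibling potential by `w_inh` (clamped below at `v_reset`); `"reset"`
#' forces it to `v_reset`. The sibling conductance is left untouched in
#' both modes.
#'
#' @param name Population name (unique within a network).
#' @param n Number of neurons.
#' @param params A [neuron_params()].
#' @param inhibition `"none"`, `"subtract"`, or `"reset"`.
#' @param w_inh Suppression magnitude for `"subtract"` mode.
#' @param inhibit_clear_g Also clear the sibling conductance on suppression.
#'   With the default (`FALSE`) a suppressed neuron keeps its conductance
#'   and may recover and fire shortly after the winner; clearing it gives
#'   strict winner-take-all per input volley.
#' @param record Record this population's spikes in the output raster.
#' @return An object of class `population`.
#' @export
population <- function(name, n, params, inhibition = c("none", "subtract", "reset"),
                       w_inh = 0, inhibit_clear_g = FALSE, record = TRUE) {
  inhibition <- match.arg(inhibition)
  if (n < 1) stop_contract("population size must be >= 1")
  if (!inherits(params, "neuron_params")) stop_contract("params must be neuron_params()")
  structure(list(name = as.character(name), n = as.integer(n), params = params,
                 inhibition = inhibition, w_inh = as.numeric(w_inh),
                 inhibit_clear_g = isTRUE(inhibit_clear_g),
                 record = isTRUE(record)),
            class = "population")
}

#' Define a projection between layers
#'
#' A dense weight matrix from a source (the input channel set `"input"` or a
#' population name) to a target population; `weights[i, j]` connects source
#' neuron `i` to target neuron `j`. A plastic projection is updated by the
#' STDP rule during simulation.
#'
#' @param source `"input"` or a population name.
#' @param target A population name.
#' @param weights Numeric matrix, `n_source x n_target`.
#' @param plastic Apply STDP to this projection.
#' @param stdp An [stdp_params()] (required when `plastic`).
#' @return An object of class `projection`.
#' @export
projection <- function(source, target, weights, plastic = FALSE, stdp = NULL) {
  if (!is.matrix(weights)) stop_contract("weights must be a matrix (source x target)")
  if (plastic && !inherits(stdp, "stdp_params"))
    stop_contract("a plastic projection needs stdp_params()")
  structure(list(source = as.character(source), target = as.character(target),
                 weights = weights, plastic = isTRUE(plastic), stdp = stdp),
            class = "projection")
}

#' Assemble a spiking network
#'
#' @param n_input Number of external input channels (ids `1..n_input` in the
#'   input raster).
#' @param populations List of [population()] objects.
#' @param projections List of [projection()] objects.
#' @return An object of class `snn_network`. Recorded output neuron ids are
#'   global: populations are numbered consecutively in the order given, so
#'   the first population occupies ids `1..n1`, the second `n1+1..n1+n2`,
#'   and so on (input channels form a separate id space).
#' @export
snn_network <- function(n_input, populations, projections) {
  if (inherits(populations, "population")) populations <- list(populations)
  if (inherits(projections, "projection")) projections <- list(projections)
  names(populations) <- vapply(populations, function(p) p$name, character(1))
  if (anyDuplicated(names(populations))) stop_contract("population names must be unique")
  sizes <- vapply(populations, function(p) p$n, integer(1))
  for (pr in projections) {
    ns <- if (pr$source == "input") as.integer(n_input) else {
      if (!pr$source %in% names(populations))
        stop_contract("unknown projection source: ", pr$source)
      sizes[[pr$source]]
    }
    if (!pr$target %in% names(populations))
      stop_contract("unknown projection target: ", pr$target)
    nt <- sizes[[pr$target]]
    if (!all(dim(pr$weights) == c(ns, nt)))
      stop_contract("projection ", pr$source, "->", pr$target,
                    " weight matrix must be ", ns, " x ", nt)
  }
  offsets <- cumsum(c(0L, sizes))[seq_along(sizes)]
  names(offsets) <- names(populations)
  structure(list(n_input = as.integer(n_input), populations = populations,
                 projections = projections, offsets = offsets),
            class = "snn_network")
}

#' @export
print.snn_network <- function(x, ...) {
  cat(sprintf("spiking network: %d input channels, %d population(s)\n",
              x$n_input, length(x$populations)))
  for (p in x$populations)
    cat(sprintf("  %s: %d neurons (inhibition: %s)\n", p$name, p$n, p$inhibition))
  for (pr in x$projections)
    cat(sprintf("  %s -> %s [%d x %d]%s\n", pr$source, pr$target,
                nrow(pr$weights), ncol(pr$weights),
                if (pr$plastic) " plastic" else ""))
  invisible(x)
}

#' Two-layer fully connected benchmark network
#'
#' The standard performance-test configuration: `n` input channels fully
#' connected to `n` output LIF neurons. Two parameterizations are provided:
#' `"fixed"` uses unit conductance gain with weights drawn uniformly from
#' `(0, 0.3)`; `"scaled"` uses unit weights with gain `C = 1000 / (n * rate)`
#' so that the mean drive — and hence the output firing regime — is
#' independent of the network size and input rate.
#'
#' @param n Neurons per layer.
#' @param rate Input firing rate, Hz (used by the `"scaled"` gain).
#' @param weights `"fixed"` or `"scaled"` (see above).
#' @param params Optional [neuron_params()] override; defaults to the
#'   benchmark constants (`tau_v = 20`, `tau_g = 5`, `v_reset = 0`,
#'   `tau_theta = 1e7`, with `theta0 = 40, theta_inc = 0.5` for `"fixed"`
#'   and `theta0 = 100, theta_inc = 0.5` for `"scaled"`).
#' @param seed Seed for the weight draw (`"fixed"` mode).
#' @return An [snn_network()].
#' @export
benchmark_network <- function(n, rate = 10, weights = c("fixed", "scaled"),
                              params = NULL, seed = NULL) {
  weights <- match.arg(weights)
  if (weights == "fixed") {
    if (is.null(params))
      params <- neuron_params(tau_v = 20, tau_g = 5, C = 1, v_reset = 0,
                              theta0 = 40, theta_inc = 0.5, tau_theta = 1e7)
    W <- with_seed(seed, matrix(stats::runif(n * n, 0, 0.3), n, n))
  } else {
    if (is.null(params))
      params <- neuron_params(tau_v = 20, tau_g = 5, C = 1000 / (n * rate),
                              v_reset = 0, theta0 = 100, theta_inc = 0.5,
                              tau_theta = 1e7)
    W <- matrix(1, n, n)
  }
  snn_network(n_input = n,
              populations = list(population("out", n, params)),
              projections = list(projection("input", "out", W)))
}
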