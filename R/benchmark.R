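#' Run the two-layer scaling benchmark grid
#'
#' For each combination of layer size `N` and input rate `Fr`, builds the
#' fully connected two-layer network with size-compensated gain
#' `C = 1000 / (N * Fr)`, drives it with fixed-rate input for `duration`
#' ms, and records hardware-independent work counters. The cost of
#' event-driven simulation scales with spikes x fan-outs (the `deliveries`
#' column): with the input rate held per neuron, deliveries grow
#' quadratically in `N`. Wall-clock time is logged for information only
#' and is never a result.
#'
#' @param N Vector of layer sizes.
#' @param Fr Vector of input rates, Hz.
#' @param duration Simulated time per cell, ms.
#' @param learning Attach the STDP rule to the projection.
#' @param stdp [stdp_params()] used when `learning` (weights start at the
#'   benchmark value 1, so bounds are widened accordingly).
#' @param config An [engine_config()].
#' @param seed Base seed; each grid cell derives its own input seed.
#' @return A data frame with one row per (N, Fr) cell: spike counts,
#'   deliveries, decay/peak/filter counters, and elapsed seconds.
#' @export
run_benchmark <- function(N, Fr = 10, duration = 1000, learning = FALSE,
                          stdp = stdp_params(w_min = 0, w_max = 2),
                          config = engine_config(), seed = 1) {
  grid <- expand.grid(N = N, Fr = Fr)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    n <- grid$N[i]
    fr <- grid$Fr[i]
    net <- benchmark_network(n, rate = fr, weights = "scaled")
    if (learning) {
      net$projections[[1]]$plastic <- TRUE
      net$projections[[1]]$stdp <- stdp
    }
    inp <- benchmark_input(n, fr, duration, seed = seed + 7919L * i)
    el <- system.time(res <- simulate_event(net, inp, duration, config))[["elapsed"]]
    ct <- res$counters
    data.frame(N = n, Fr = fr, C = 1000 / (n * fr),
               input_spikes = nrow(inp), output_spikes = nrow(res$raster),
               deliveries = ct[["deliveries"]], decay_evals = ct[["decay_evals"]],
               filter_checks = ct[["filter_checks"]], peak_evals = ct[["peak_evals"]],
               bisections = ct[["bisections"]], elapsed_s = el)
  })
  do.call(rbind, rows)
}

#' Log-log scaling slope of benchmark work in network size
#'
#' @param bench A [run_benchmark()] result (single `Fr`).
#' @param column Work counter to regress, default `deliveries`
#'   (spikes x fan-outs).
#' @return Slope of `log(column)` on `log(N)`.
#' @export
scaling_slope <- function(bench, column = "deliveries") {
  unname(stats::coef(stats::lm(log(bench[[column]]) ~ log(bench$N)))[2])
}
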