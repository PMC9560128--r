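# YAML run configuration and run manifests.
#
# A single human-readable file describes a simulation: the network
# (populations, projections, input channel count), engine toggles, the run
# horizon, and seeds. Weight matrices are given either inline, as a
# `random` spec, or as a path to a delimited-text matrix relative to the
# config file.

#' Read a simulation configuration file
#'
#' Schema (YAML):
#' \preformatted{
#' n_input: 200
#' t_end: 10000
#' seed: 1
#' engine: {population: true, prefilter: true, lazy_threshold: false}
#' populations:
#'   - name: out
#'     size: 200
#'     params: {tau_v: 20, tau_g: 5, C: 1, v_reset: 0,
#'              theta0: 40, theta_inc: 0.5, tau_theta: 1.0e7}
#'     inhibition: none      # none | subtract | reset
#'     w_inh: 0
#' projections:
#'   - source: input
#'     target: out
#'     weights: {random: uniform, min: 0, max: 0.3}   # or {value: 1} or {file: w.tsv}
#'     plastic: false
#' input:                    # optional built-in stimulus
#'   kind: benchmark         # benchmark | file
#'   rate: 10
#'   duration: 10000
#' }
#'
#' @param path Path to the YAML file.
#' @return A list with `network` ([snn_network()]), `engine_config`,
#'   `t_end`, `seed`, and the raw `input` spec (or `NULL`).
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (field in c("n_input", "t_end", "populations", "projections"))
    if (is.null(cfg[[field]]))
      stop_contract("config ", path, ": missing required field '", field, "'")
  seed <- cfg$seed %||% NULL
  pops <- lapply(cfg$populations, function(p) {
    population(p$name, p$size, do.call(neuron_params, p$params %||% list()),
               inhibition = p$inhibition %||% "none",
               w_inh = p$w_inh %||% 0)
  })
  sizes <- stats::setNames(vapply(pops, function(p) p$n, integer(1)),
                           vapply(pops, function(p) p$name, character(1)))
  projs <- lapply(cfg$projections, function(pr) {
    ns <- if (pr$source == "input") cfg$n_input else sizes[[pr$source]]
    nt <- sizes[[pr$target]]
    w <- pr$weights
    W <- if (!is.null(w$file)) {
      as.matrix(utils::read.table(file.path(dirname(path), w$file), sep = "\t"))
    } else if (!is.null(w$random)) {
      with_seed(seed, matrix(stats::runif(ns * nt, w$min %||% 0, w$max %||% 1), ns, nt))
    } else if (!is.null(w$value)) {
      matrix(w$value, ns, nt)
    } else stop_contract("config ", path, ": projection needs weights: file/random/value")
    stdp <- if (isTRUE(pr$plastic)) do.call(stdp_params, pr$stdp %||% list())
    projection(pr$source, pr$target, W, plastic = isTRUE(pr$plastic), stdp = stdp)
  })
  eng <- cfg$engine %||% list()
  list(network = snn_network(cfg$n_input, pops, projs),
       engine_config = engine_config(
         enable_population = eng$population %||% TRUE,
         enable_prefilter = eng$prefilter %||% TRUE,
         enable_lazy_threshold = eng$lazy_threshold %||% FALSE),
       t_end = cfg$t_end, seed = seed, input = cfg$input)
}

#' Write a run manifest
#'
#' Every command-line run emits a manifest: the config snapshot, the seed,
#' the toggle states exactly as executed, the instrumentation counters,
#' and the output paths — enough to reproduce the run.
#'
#' @param path Output JSON path.
#' @param config_path Source config file.
#' @param engine_config The [engine_config()] executed.
#' @param seed Seed used.
#' @param counters [engine_counters()] of the finished run.
#' @param outputs Named list of output file paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config_path, engine_config, seed, counters, outputs) {
  jsonlite::write_json(list(
    config = config_path,
    seed = seed,
    toggles = list(population = engine_config$enable_population,
                   prefilter = engine_config$enable_prefilter,
                   lazy_threshold = engine_config$enable_lazy_threshold),
    counters = as.list(counters),
    outputs = outputs
  ), path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
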