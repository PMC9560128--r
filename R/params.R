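#' Leaky integrate-and-fire neuron parameters
#'
#' Constants of the conductance-based LIF model with an adaptive firing
#' threshold. The membrane potential `v` leaks with time constant `tau_v`
#' (ms) while integrating the excitatory conductance `g_E`, which itself
#' decays with time constant `tau_g` (ms). Each presynaptic spike of weight
#' `w` increases `g_E` instantaneously by `C * w`. On reaching the threshold
#' `v_th` the neuron emits a spike, `v` is reset to `v_reset`, `g_E` is
#' cleared, and the threshold is incremented by `theta_inc`; between spikes
#' `v_th` decays exponentially toward the baseline `theta0` with time
#' constant `tau_theta` (ms).
#'
#' `tau_g == tau_v` is rejected: the closed-form state update divides by
#' `tau_g - tau_v`, and that removable singularity is never needed in
#' practice (all standard configurations keep the two constants distinct).
#'
#' @param tau_v Membrane (voltage) leak time constant, ms. Must be > 0.
#' @param tau_g Conductance leak time constant, ms. Must be > 0 and
#'   different from `tau_v`.
#' @param C Dimensionless conductance gain applied to every synaptic weight.
#' @param v_reset Post-spike reset potential.
#' @param theta0 Adaptive-threshold baseline.
#' @param theta_inc Threshold increment added at each fire. Must be >= 0.
#' @param tau_theta Threshold decay time constant, ms. Must be > 0.
#'
#' @return An object of class `neuron_params`.
#' @examples
#' neuron_params(tau_v = 20, tau_g = 5, theta0 = 40)
#' @export
neuron_params <- function(tau_v = 20, tau_g = 5, C = 1, v_reset = 0,
                          theta0 = 40, theta_inc = 0.5, tau_theta = 1e7) {
  p <- list(tau_v = as.numeric(tau_v), tau_g = as.numeric(tau_g),
            C = as.numeric(C), v_reset = as.numeric(v_reset),
            theta0 = as.numeric(theta0), theta_inc = as.numeric(theta_inc),
            tau_theta = as.numeric(tau_theta))
  if (!is.finite(p$tau_v) || p$tau_v <= 0) stop_contract("tau_v must be > 0")
  if (!is.finite(p$tau_g) || p$tau_g <= 0) stop_contract("tau_g must be > 0")
  if (p$tau_g == p$tau_v)
    stop_contract("tau_g must differ from tau_v (closed forms divide by tau_g - tau_v)")
  if (p$theta_inc < 0) stop_contract("theta_inc must be >= 0")
  if (p$tau_theta <= 0) stop_contract("tau_theta must be > 0")
  structure(p, class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("LIF neuron parameters (times in ms):\n")
  cat(sprintf("  tau_v=%g  tau_g=%g  C=%g  v_reset=%g\n", x$tau_v, x$tau_g, x$C, x$v_reset))
  cat(sprintf("  threshold: theta0=%g  +%g per fire, decay tau_theta=%g\n",
              x$theta0, x$theta_inc, x$tau_theta))
  invisible(x)
}

#' Single-neuron dynamic state
#'
#' A snapshot of one neuron's dynamic variables: membrane potential `v`,
#' excitatory conductance `g_E`, current adaptive threshold `v_th`, and the
#' timestamp `t_last` (ms) of the last state update. Between events a valid
#' state satisfies `v < v_th`; a state at or above threshold must be resolved
#' into a spike immediately (see [fire_reset()]).
#'
#' @param v Membrane potential.
#' @param g_E Excitatory conductance (>= 0 when all weights are nonnegative).
#' @param v_th Current adaptive threshold.
#' @param t_last Time of last update, ms.
#' @return An object of class `neuron_state`.
#' @export
neuron_state <- function(v = 0, g_E = 0, v_th = 40, t_last = 0) {
  structure(list(v = as.numeric(v), g_E = as.numeric(g_E),
                 v_th = as.numeric(v_th), t_last = as.numeric(t_last)),
            class = "neuron_state")
}

#' @export
print.neuron_state <- function(x, ...) {
  cat(sprintf("neuron state @ t=%g ms: v=%g  g_E=%g  v_th=%g\n",
              x$t_last, x$v, x$g_E, x$v_th))
  invisible(x)
}

#' STDP parameters
#'
#' Constants of the pair-based spike-timing-dependent plasticity rule. When a
#' presynaptic spike at `t_pre` precedes a postsynaptic spike at `t_post`,
#' the weight is potentiated by `sigma_plus * exp(-(t_post - t_pre)/tau_plus)`;
#' when the presynaptic spike follows, the weight is depressed by
#' `sigma_minus * exp(-(t_pre - t_post)/tau_minus)`.
#'
#' Sign convention: `sigma_minus` is stored as a positive depression
#' *amplitude* and is subtracted from the weight, so depression is guaranteed
#' regardless of the sign the user supplies (its absolute value is used).
#' Pairing is nearest-spike only: traces keep the most recent pre/post spike
#' time per neuron. Exactly simultaneous pre/post spikes produce no update.
#'
#' @param sigma_plus Potentiation amplitude (> 0).
#' @param sigma_minus Depression amplitude; stored as `abs(sigma_minus)` and
#'   subtracted.
#' @param tau_plus Potentiation time constant, ms (> 0).
#' @param tau_minus Depression time constant, ms (> 0).
#' @param w_min,w_max Clip bounds applied after every update.
#' @return An object of class `stdp_params`.
#' @export
stdp_params <- function(sigma_plus = 0.01, sigma_minus = 0.01,
                        tau_plus = 20, tau_minus = 20,
                        w_min = 0, w_max = 1) {
  if (tau_plus <= 0 || tau_minus <= 0) stop_contract("STDP time constants must be > 0")
  if (w_min > w_max) stop_contract("w_min must be <= w_max")
  if (sigma_plus < 0) stop_contract("sigma_plus must be >= 0")
  structure(list(sigma_plus = as.numeric(sigma_plus),
                 sigma_minus = abs(as.numeric(sigma_minus)),
                 tau_plus = as.numeric(tau_plus), tau_minus = as.numeric(tau_minus),
                 w_min = as.numeric(w_min), w_max = as.numeric(w_max)),
            class = "stdp_params")
}

#' Event-engine configuration
#'
#' Toggles select how much work the engine does, never what it computes: all
#' combinations of `population` and `prefilter` produce bitwise-identical
#' spike rasters, and `lazy_threshold` produces rasters identical to within
#' a spike-time tolerance of 1e-6 ms (the threshold decay skipped between
#' flushes is of order `dt / tau_theta`).
#'
#' @param enable_population Reuse one pair of decay factors per population
#'   per update interval instead of evaluating them per neuron.
#' @param enable_prefilter Apply the cheap conductance bound before any peak
#'   computation; states failing the bound cannot fire and are skipped.
#' @param enable_lazy_threshold Defer the (negligible) exponential decay of
#'   the adaptive threshold to fire events instead of applying it at every
#'   state update.
#' @param record_spikes Record the output raster.
#' @param bisect_tol Bisection tolerance for spike times, ms.
#' @return An object of class `engine_config`.
#' @export
engine_config <- function(enable_population = TRUE, enable_prefilter = TRUE,
                          enable_lazy_threshold = FALSE, record_spikes = TRUE,
                          bisect_tol = 1e-9) {
  structure(list(enable_population = isTRUE(enable_population),
                 enable_prefilter = isTRUE(enable_prefilter),
                 enable_lazy_threshold = isTRUE(enable_lazy_threshold),
                 record_spikes = isTRUE(record_spikes),
                 bisect_tol = as.numeric(bisect_tol)),
            class = "engine_config")
}

#' Clock-driven simulator configuration
#'
#' @param dt Time step, ms (> 0).
#' @param integrator `"exact-exponential"` applies the closed-form decay over
#'   each step so temporal quantization is the only error source;
#'   `"forward-euler"` is the naive first-order update.
#' @return An object of class `clock_config`.
#' @export
clock_config <- function(dt = 0.1, integrator = c("exact-exponential", "forward-euler")) {
  dt <- as.numeric(dt)
  if (!is.finite(dt) || dt <= 0) stop_contract("dt must be > 0")
  structure(list(dt = dt, integrator = match.arg(integrator)),
            class = "clock_config")
}
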