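# Event-driven pair-based STDP.
#
# The rule acts on the most recent pre/post spike-time pair only
# (nearest-spike pairing): each source keeps its last presynaptic spike time
# and each target its last fire time. On a postsynaptic fire, all incoming
# weights with an earlier presynaptic spike are potentiated; on a
# presynaptic spike, all outgoing weights with an earlier postsynaptic fire
# are depressed. Missing spike times are encoded as -Inf (no update).

#' Potentiate incoming weights on a postsynaptic fire
#'
#' For each source `i` with recorded last presynaptic spike `t_pre[i]`
#' strictly before `t_post`, adds
#' `sigma_plus * exp(-(t_post - t_pre[i]) / tau_plus)` to `weights[i]` and
#' clips to `[w_min, w_max]`. Sources with no prior spike (`t_pre = -Inf`)
#' or a simultaneous spike are unchanged.
#'
#' @param weights Numeric vector: the weight column into the firing neuron
#'   (one entry per source).
#' @param t_pre Numeric vector of last presynaptic spike times, `-Inf` where
#'   none occurred.
#' @param t_post Fire time of the postsynaptic neuron, ms.
#' @param params An [stdp_params()].
#' @return The updated weight vector.
#' @export
stdp_on_post <- function(weights, t_pre, t_post, params) {
  sel <- is.finite(t_pre) & t_pre < t_post
  if (any(sel)) {
    weights[sel] <- clip(weights[sel] +
      params$sigma_plus * exp(-(t_post - t_pre[sel]) / params$tau_plus),
      params$w_min, params$w_max)
  }
  weights
}

#' Depress outgoing weights on a presynaptic spike
#'
#' For each target `j` with recorded last fire `t_post[j]` strictly before
#' `t_pre`, subtracts
#' `sigma_minus * exp(-(t_pre - t_post[j]) / tau_minus)` from `weights[j]`
#' and clips to `[w_min, w_max]`. Targets that never fired (`t_post = -Inf`)
#' or fired simultaneously are unchanged.
#'
#' @param weights Numeric vector: the weight row out of the spiking source
#'   (one entry per target).
#' @param t_post Numeric vector of last postsynaptic fire times, `-Inf`
#'   where none occurred.
#' @param t_pre Arrival time of the presynaptic spike, ms.
#' @param params An [stdp_params()].
#' @return The updated weight vector.
#' @export
stdp_on_pre <- function(weights, t_post, t_pre, params) {
  sel <- is.finite(t_post) & t_post < t_pre
  if (any(sel)) {
    weights[sel] <- clip(weights[sel] -
      params$sigma_minus * exp(-(t_pre - t_post[sel]) / params$tau_minus),
      params$w_min, params$w_max)
  }
  weights
}
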