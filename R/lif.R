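# Closed-form LIF mathematics.
#
# Between events the model is linear:
#   dv/dt   = -v/tau_v + g_E
#   dg_E/dt = -g_E/tau_g
# with exact solution
#   g_E(T+dt) = g_E(T) * exp(-dt/tau_g)
#   v(T+dt)   = v(T) * exp(-dt/tau_v)
#               + g_E(T) * K * (exp(-dt/tau_g) - exp(-dt/tau_v)),
#   K = tau_g*tau_v / (tau_g - tau_v).
# The extremum of v, if the trajectory rises at all, is at
#   t' = K * log(A),  A = (tau_g/tau_v) * (1 - (tau_g - tau_v)/(tau_g*tau_v) * v/g_E),
# and the peak value is v evaluated at t'. When g_E = 0, A <= 0, or t' <= 0
# the potential decays monotonically and the peak is the current v.

# Vectorized internals used by the engines ---------------------------------

.lif_coef <- function(p) p$tau_g * p$tau_v / (p$tau_g - p$tau_v)

# advance (v, g) by dt given precomputed decay factors fv, fg
.lif_advance <- function(v, g, fv, fg, coef) {
  list(v = v * fv + g * coef * (fg - fv), g = g * fg)
}

# peak offset t' and peak value for vectors v, g; returns list(t_prime, v_max)
# t_prime is -Inf in the monotone-decay regime (g == 0 or log argument <= 0
# or the stationary point lies in the past).
.lif_peak <- function(v, g, p) {
  coef <- .lif_coef(p)
  t_prime <- rep(-Inf, length(v))
  v_max <- v
  pos <- g > 0
  if (any(pos)) {
    a <- (p$tau_g / p$tau_v) * (1 - (p$tau_g - p$tau_v) / (p$tau_g * p$tau_v) * v[pos] / g[pos])
    tp <- rep(-Inf, sum(pos))
    ok <- a > 0
    tp[ok] <- coef * log(a[ok])
    t_prime[pos] <- tp
  }
  up <- is.finite(t_prime) & t_prime > 0
  if (any(up)) {
    fv <- exp(-t_prime[up] / p$tau_v)
    fg <- exp(-t_prime[up] / p$tau_g)
    v_max[up] <- v[up] * fv + g[up] * coef * (fg - fv)
  }
  list(t_prime = t_prime, v_max = v_max)
}

# conductance pre-filter bound: a neuron can only reach v_th in the future if
#   g_E >= v_th/tau_v + (v_th - v)/tau_g
.lif_prefilter <- function(v, g, v_th, p) {
  g >= v_th / p$tau_v + (v_th - v) / p$tau_g
}

# first upward crossing of v_th in (0, t_prime], vectorized bisection.
# Callers guarantee v < v_th and v_max >= v_th (so a root is bracketed).
.lif_bisect <- function(v, g, v_th, t_prime, p, tol = 1e-9, max_iter = 200L) {
  coef <- .lif_coef(p)
  lo <- numeric(length(v))
  hi <- t_prime
  f_hi_end <- TRUE # v is increasing on (0, t'], crossing bracketed
  iter <- 0L
  while (any(hi - lo > tol)) {
    iter <- iter + 1L
    if (iter > max_iter)
      stop_contract("spike-time bisection failed to converge in ", max_iter, " iterations")
    mid <- (lo + hi) / 2
    fv <- exp(-mid / p$tau_v)
    fg <- exp(-mid / p$tau_g)
    vm <- v * fv + g * coef * (fg - fv)
    below <- vm < v_th
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

# exact threshold relaxation toward baseline
.lif_theta_decay <- function(v_th, dt, p) {
  p$theta0 + (v_th - p$theta0) * exp(-dt / p$tau_theta)
}

# User-facing single-state operations --------------------------------------

#' Advance a neuron state by a quiescent interval
#'
#' Applies the exact closed-form solution of the membrane equations over an
#' interval `dt` during which no spike arrives and the neuron does not fire:
#' the conductance decays exponentially, the potential follows the
#' two-exponential response, and the adaptive threshold relaxes toward its
#' baseline. No spike is ever emitted by this operation.
#'
#' @param state A [neuron_state()].
#' @param dt Interval length, ms (>= 0).
#' @param params A [neuron_params()].
#' @return The advanced `neuron_state` with `t_last` moved forward by `dt`.
#' @examples
#' p <- neuron_params(tau_v = 20, tau_g = 5)
#' decay_state(neuron_state(v = 10), dt = 20, p) # pure e^-1 decay when g_E = 0
#' @export
decay_state <- function(state, dt, params) {
  if (dt < 0) stop_contract("dt must be >= 0")
  if (dt == 0) return(state)
  fv <- exp(-dt / params$tau_v)
  fg <- exp(-dt / params$tau_g)
  adv <- .lif_advance(state$v, state$g_E, fv, fg, .lif_coef(params))
  neuron_state(v = adv$v, g_E = adv$g,
               v_th = .lif_theta_decay(state$v_th, dt, params),
               t_last = state$t_last + dt)
}

#' Absorb one presynaptic spike
#'
#' A spike of weight `weight` increases the conductance instantaneously by
#' `C * weight`; the potential and threshold are unchanged. The state must
#' already be decayed to the spike's timestamp.
#'
#' @inheritParams decay_state
#' @param weight Synaptic weight (dimensionless).
#' @return The updated `neuron_state`.
#' @export
apply_spike <- function(state, weight, params) {
  state$g_E <- state$g_E + params$C * weight
  state
}

#' Peak of the future membrane-potential trajectory
#'
#' Computes, from the current state and absent any further input, the offset
#' `t_prime` (ms, relative to `state$t_last`) of the potential's extremum and
#' the peak value `v_max` reached there. In the monotone-decay regime (zero
#' conductance, or a stationary point at or before the present) `t_prime` is
#' reported as `-Inf` and `v_max` equals the current potential. `will_fire`
#' is `TRUE` iff `v_max >= v_th`.
#'
#' @inheritParams decay_state
#' @return A list of class `peak_result` with fields `t_prime`, `v_max`,
#'   `will_fire`.
#' @export
peak_voltage <- function(state, params) {
  pk <- .lif_peak(state$v, state$g_E, params)
  structure(list(t_prime = pk$t_prime, v_max = pk$v_max,
                 will_fire = pk$v_max >= state$v_th),
            class = "peak_result")
}

#' Conductance pre-filter: a necessary condition for future firing
#'
#' Returns `TRUE` iff `g_E >= v_th/tau_v + (v_th - v)/tau_g`. A `FALSE`
#' result guarantees the neuron cannot reach threshold without further
#' input, so the (more expensive) peak computation may be skipped. The bound
#' is necessary but not sufficient: passing states may still fail to fire.
#'
#' @inheritParams decay_state
#' @return Logical scalar.
#' @export
prefilter <- function(state, params) {
  .lif_prefilter(state$v, state$g_E, state$v_th, params)
}

#' Exact spike time by bisection
#'
#' Given a state whose predicted peak reaches threshold, locates the first
#' upward crossing of `v_th` within `(0, t_prime]` by bisection on the
#' closed-form trajectory. The potential is increasing on that bracket, so
#' the crossing is unique.
#'
#' @inheritParams decay_state
#' @param tol Bisection tolerance, ms.
#' @return Crossing time offset (ms, relative to `state$t_last`).
#' @export
spike_time_bisect <- function(state, params, tol = 1e-9) {
  pk <- peak_voltage(state, params)
  if (!pk$will_fire)
    stop_contract("spike_time_bisect requires a state whose peak reaches threshold")
  if (state$v >= state$v_th)
    stop_contract("state already at or above threshold; resolve the spike first")
  .lif_bisect(state$v, state$g_E, state$v_th, pk$t_prime, params, tol = tol)
}

#' Post-spike reset
#'
#' At fire time the potential is reset to `v_reset`, the conductance is
#' cleared, and the adaptive threshold (first relaxed over the elapsed
#' interval) is incremented by `theta_inc`.
#'
#' @inheritParams decay_state
#' @param t_fire Absolute fire time, ms (>= `state$t_last`).
#' @return The reset `neuron_state` with `t_last = t_fire`.
#' @export
fire_reset <- function(state, params, t_fire) {
  dt <- t_fire - state$t_last
  if (dt < 0) stop_contract("t_fire must be >= state$t_last")
  neuron_state(v = params$v_reset, g_E = 0,
               v_th = .lif_theta_decay(state$v_th, dt, params) + params$theta_inc,
               t_last = t_fire)
}

#' @export
print.peak_result <- function(x, ...) {
  cat(sprintf("peak: t'=%g ms, v_max=%g, will_fire=%s\n",
              x$t_prime, x$v_max, x$will_fire))
  invisible(x)
}
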