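# Event-driven simulation engine.
#
# The engine maintains, per population, a vector of predicted fire times
# (Inf = no prediction) that acts as the local priority queue: its minimum is
# the population's contribution to the global queue, and the global head is
# the minimum over all local heads and the cursor into the (pre-sorted)
# external input stream. Scheduling and invalidation are O(1) writes; there
# are no stale queue entries because a neuron owns exactly one slot.
#
# Event processing follows the classic three sub-steps: (a) advance the
# target population's state to the event time with closed-form decay
# factors (computed once per population when population computing is on,
# once per neuron otherwise); (b) absorb the spike into the conductance;
# (c) re-derive predictions — a cheap conductance pre-filter first (when
# enabled), the analytic peak for survivors, and bisection for the few
# states whose peak reaches threshold.
#
# Deterministic total event order: (time, population id, neuron index),
# with external input events preceding predicted fires at equal times.

#' Create an event-driven simulation engine
#'
#' Builds the mutable simulation state for `network`. The engine persists
#' across calls to [engine_run()], so stimuli can be presented sequentially
#' (as the training harness does) without resetting membrane state.
#'
#' @param network An [snn_network()].
#' @param config An [engine_config()].
#' @return An environment of class `event_engine`.
#' @export
event_engine <- function(network, config = engine_config()) {
  eng <- new.env(parent = emptyenv())
  eng$net <- network
  eng$cfg <- config
  eng$time <- 0
  eng$input_last <- rep(-Inf, network$n_input)
  eng$counters <- c(events_input = 0, events_fire = 0, deliveries = 0,
                    decay_evals = 0, theta_evals = 0, filter_checks = 0,
                    peak_evals = 0, bisections = 0)
  eng$out_t <- numeric(1024L)
  eng$out_id <- integer(1024L)
  eng$n_out <- 0L

  eng$projs <- lapply(network$projections, function(pr) {
    pe <- new.env(parent = emptyenv())
    pe$source <- pr$source
    pe$target <- pr$target
    pe$W <- pr$weights
    pe$plastic <- pr$plastic
    pe$stdp <- pr$stdp
    pe
  })

  eng$pops <- lapply(seq_along(network$populations), function(i) {
    p <- network$populations[[i]]
    pe <- new.env(parent = emptyenv())
    pe$name <- p$name
    pe$id <- i
    pe$n <- p$n
    pe$p <- p$params
    pe$coef <- .lif_coef(p$params)
    pe$v <- rep(p$params$v_reset, p$n)
    pe$gE <- numeric(p$n)
    pe$vth <- rep(p$params$theta0, p$n)
    pe$tth <- numeric(p$n)          # last time vth was exact (lazy mode)
    pe$t_last <- 0
    pe$pred <- rep(Inf, p$n)        # local priority queue
    pe$t_fire <- rep(-Inf, p$n)     # last fire time (post-synaptic trace)
    pe$inhibition <- p$inhibition
    pe$w_inh <- p$w_inh
    pe$inhibit_clear_g <- p$inhibit_clear_g
    pe$record <- p$record
    pe$offset <- network$offsets[[p$name]]
    pe$out_projs <- which(vapply(network$projections, function(pr) pr$source == p$name, logical(1)))
    pe$in_plastic <- which(vapply(network$projections,
                                  function(pr) pr$target == p$name && pr$plastic, logical(1)))
    pe
  })
  names(eng$pops) <- names(network$populations)
  class(eng) <- "event_engine"
  eng
}

#' @export
print.event_engine <- function(x, ...) {
  cat(sprintf("event engine @ t=%g ms, %d spikes recorded\n", x$time, x$n_out))
  invisible(x)
}

# advance a population's shared state to absolute time t
.advance_pop <- function(eng, pop, t) {
  dt <- t - pop$t_last
  if (dt < 0) stop_contract("cannot advance population into the past")
  if (dt == 0) return(invisible())
  p <- pop$p
  if (eng$cfg$enable_population) {
    fv <- exp(-dt / p$tau_v)
    fg <- exp(-dt / p$tau_g)
    eng$counters[["decay_evals"]] <- eng$counters[["decay_evals"]] + 2
  } else {
    dts <- rep(dt, pop$n)
    fv <- exp(-dts / p$tau_v)
    fg <- exp(-dts / p$tau_g)
    eng$counters[["decay_evals"]] <- eng$counters[["decay_evals"]] + 2 * pop$n
  }
  pop$v <- pop$v * fv + pop$gE * pop$coef * (fg - fv)
  pop$gE <- pop$gE * fg
  if (!eng$cfg$enable_lazy_threshold) {
    if (eng$cfg$enable_population) {
      fth <- exp(-dt / p$tau_theta)
      eng$counters[["theta_evals"]] <- eng$counters[["theta_evals"]] + 1
    } else {
      fth <- exp(-rep(dt, pop$n) / p$tau_theta)
      eng$counters[["theta_evals"]] <- eng$counters[["theta_evals"]] + pop$n
    }
    pop$vth <- p$theta0 + (pop$vth - p$theta0) * fth
  }
  pop$t_last <- t
  invisible()
}

# recompute predicted fire times for a whole population (sub-step c)
.predict_pop <- function(eng, pop) {
  p <- pop$p
  n <- pop$n
  v <- pop$v
  g <- pop$gE
  vth <- pop$vth
  pred <- rep(Inf, n)
  if (eng$cfg$enable_prefilter) {
    eng$counters[["filter_checks"]] <- eng$counters[["filter_checks"]] + n
    cand <- which(g >= vth / p$tau_v + (vth - v) / p$tau_g)
  } else {
    cand <- seq_len(n)
  }
  if (length(cand)) {
    eng$counters[["peak_evals"]] <- eng$counters[["peak_evals"]] + length(cand)
    pk <- .lif_peak(v[cand], g[cand], p)
    firing <- pk$v_max >= vth[cand]
    if (any(firing)) {
      fi <- cand[firing]
      already <- v[fi] >= vth[fi] # numerical edge: resolve immediately
      toff <- numeric(length(fi))
      if (any(!already)) {
        toff[!already] <- .lif_bisect(v[fi[!already]], g[fi[!already]],
                                      vth[fi[!already]], pk$t_prime[firing][!already],
                                      p, tol = eng$cfg$bisect_tol)
        eng$counters[["bisections"]] <- eng$counters[["bisections"]] + sum(!already)
      }
      pred[fi] <- pop$t_last + toff
    }
  }
  pop$pred <- pred
  invisible()
}

# deliver one spike from source index `si` of projection `pe` at time t
.deliver <- function(eng, pe, si, t) {
  pop <- eng$pops[[pe$target]]
  .advance_pop(eng, pop, t)
  w <- pe$W[si, ]
  pop$gE <- pop$gE + pop$p$C * w
  eng$counters[["deliveries"]] <- eng$counters[["deliveries"]] + pop$n
  if (pe$plastic)
    pe$W[si, ] <- stdp_on_pre(w, pop$t_fire, t, pe$stdp)
  .predict_pop(eng, pop)
  invisible()
}

# process one external input spike (channel i at time t)
.input_event <- function(eng, i, t) {
  eng$counters[["events_input"]] <- eng$counters[["events_input"]] + 1
  for (pe in eng$projs) if (pe$source == "input") .deliver(eng, pe, i, t)
  eng$input_last[i] <- t
  eng$time <- t
  invisible()
}

# process one predicted fire (neuron k of population `pop` at time t)
.fire_event <- function(eng, pop, k, t) {
  eng$counters[["events_fire"]] <- eng$counters[["events_fire"]] + 1
  .advance_pop(eng, pop, t)
  p <- pop$p
  if (pop$record && eng$cfg$record_spikes) {
    n <- eng$n_out + 1L
    if (n > length(eng$out_t)) {
      eng$out_t <- c(eng$out_t, numeric(length(eng$out_t)))
      eng$out_id <- c(eng$out_id, integer(length(eng$out_id)))
    }
    eng$out_t[n] <- t
    eng$out_id[n] <- pop$offset + k
    eng$n_out <- n
  }
  if (eng$cfg$enable_lazy_threshold) {
    # deferred flush: apply the decay skipped since the last exact value
    pop$vth[k] <- p$theta0 + (pop$vth[k] - p$theta0) * exp(-(t - pop$tth[k]) / p$tau_theta)
    pop$tth[k] <- t
    eng$counters[["theta_evals"]] <- eng$counters[["theta_evals"]] + 1
  }
  pop$vth[k] <- pop$vth[k] + p$theta_inc
  pop$v[k] <- p$v_reset
  pop$gE[k] <- 0
  # potentiate incoming plastic weights (pre-before-post pairs)
  for (pi in pop$in_plastic) {
    pe <- eng$projs[[pi]]
    tp <- if (pe$source == "input") eng$input_last else eng$pops[[pe$source]]$t_fire
    pe$W[, k] <- stdp_on_post(pe$W[, k], tp, t, pe$stdp)
  }
  pop$t_fire[k] <- t
  # downstream deliveries
  for (pi in pop$out_projs) .deliver(eng, eng$projs[[pi]], k, t)
  # direct lateral inhibition: instantaneous suppression of all siblings
  if (pop$inhibition != "none" && pop$n > 1L) {
    if (pop$inhibition == "subtract") {
      vnew <- pmax(pop$v - pop$w_inh, p$v_reset)
    } else {
      vnew <- rep(p$v_reset, pop$n)
    }
    vnew[k] <- pop$v[k]
    pop$v <- vnew
    if (pop$inhibit_clear_g) {
      gk <- pop$gE[k]
      pop$gE <- numeric(pop$n)
      pop$gE[k] <- gk
    }
  }
  .predict_pop(eng, pop)
  eng$time <- t
  invisible()
}

#' Schedule, inspect, and invalidate predicted spikes
#'
#' Low-level access to the engine's prediction queues, used mainly for
#' testing and instrumentation. `engine_schedule()` inserts (or replaces)
#' the predicted fire time of one neuron; scheduling into the simulated past
#' is a contract violation. `engine_invalidate_prediction()` removes a
#' neuron's prediction (a no-op if none exists). `engine_next_event()`
#' returns the global queue head among predictions without removing it;
#' `engine_pop_event()` removes and returns it. Ties are broken by
#' (population id, neuron index).
#'
#' @param eng An [event_engine()].
#' @param population Population name.
#' @param neuron Neuron index within the population.
#' @param time Absolute predicted fire time, ms.
#' @return `engine_next_event`/`engine_pop_event` return a list with
#'   `time`, `population`, `neuron`, or `NULL` if no prediction is pending.
#' @export
engine_schedule <- function(eng, population, neuron, time) {
  if (time < eng$time)
    stop_contract("cannot schedule an event into the past (t=", time,
                  " < now=", eng$time, ")")
  eng$pops[[population]]$pred[neuron] <- time
  invisible(eng)
}

#' @rdname engine_schedule
#' @export
engine_invalidate_prediction <- function(eng, population, neuron) {
  eng$pops[[population]]$pred[neuron] <- Inf
  invisible(eng)
}

#' @rdname engine_schedule
#' @export
engine_next_event <- function(eng) {
  best_t <- Inf
  best <- NULL
  for (pop in eng$pops) {
    k <- which.min(pop$pred)
    if (length(k) && pop$pred[k] < best_t) {
      best_t <- pop$pred[k]
      best <- list(time = best_t, population = pop$name, neuron = k)
    }
  }
  best
}

#' @rdname engine_schedule
#' @export
engine_pop_event <- function(eng) {
  ev <- engine_next_event(eng)
  if (!is.null(ev)) eng$pops[[ev$population]]$pred[ev$neuron] <- Inf
  ev
}

#' Run the event engine over an input spike stream
#'
#' Pops events in global time order — external input spikes interleaved
#' with predicted fires — until the queue is exhausted or the next event
#' lies beyond `t_end`. Input events at the same timestamp as a predicted
#' fire are processed first; simultaneous predictions resolve by
#' (population id, neuron index). The engine's clock is left at `t_end`, so
#' consecutive calls present stimuli sequentially.
#'
#' @param eng An [event_engine()].
#' @param input A [spike_raster()] of input-channel spikes (ids
#'   `1..n_input`); times must not precede the engine clock. Spikes after
#'   `t_end` are ignored.
#' @param t_end Absolute end time of this run, ms.
#' @return Invisibly, the [spike_raster()] of output spikes recorded during
#'   this call (global neuron ids).
#' @export
engine_run <- function(eng, input, t_end) {
  if (t_end < eng$time) stop_contract("t_end precedes the engine clock")
  in_t <- input$time
  in_id <- input$neuron
  if (length(in_t) && in_t[1] < eng$time)
    stop_contract("input spikes precede the engine clock")
  if (length(in_id) && (min(in_id) < 1L || max(in_id) > eng$net$n_input))
    stop_contract("input neuron ids must be in 1..n_input")
  ci <- 1L
  n_in <- length(in_t)
  pops <- eng$pops
  npop <- length(pops)
  first_rec <- eng$n_out + 1L
  t_prev <- -Inf
  repeat {
    t_in <- if (ci <= n_in) in_t[ci] else Inf
    best_t <- Inf
    best_pop <- NULL
    best_k <- 0L
    for (pop in pops) {
      k <- which.min(pop$pred)
      if (length(k) && pop$pred[k] < best_t) {
        best_t <- pop$pred[k]
        best_pop <- pop
        best_k <- k
      }
    }
    if (t_in <= best_t) {
      if (t_in > t_end) break
      stopifnot(t_in >= t_prev) # events must pop in nondecreasing time order
      t_prev <- t_in
      .input_event(eng, in_id[ci], t_in)
      ci <- ci + 1L
    } else {
      if (best_t > t_end) break
      stopifnot(best_t >= t_prev)
      t_prev <- best_t
      best_pop$pred[best_k] <- Inf
      .fire_event(eng, best_pop, best_k, best_t)
    }
  }
  eng$time <- t_end
  idx <- seq.int(first_rec, length.out = eng$n_out - first_rec + 1L)
  invisible(spike_raster(eng$out_id[idx], eng$out_t[idx],
                         n_neurons = sum(vapply(pops, function(p) p$n, integer(1)))))
}

#' Engine instrumentation counters
#'
#' Operation counts accumulated since engine creation: processed input and
#' fire events, spike deliveries (spikes x fan-outs), exponential
#' decay-factor evaluations, threshold-decay evaluations, pre-filter checks,
#' peak computations, and bisection solves. These are the hardware-
#' independent measure of simulation work: enabling the pre-filter reduces
#' `peak_evals`, enabling population computing reduces `decay_evals`, and
#' deferring threshold updates reduces `theta_evals`, all without changing
#' the spike output.
#'
#' @param eng An [event_engine()].
#' @return Named numeric vector.
#' @export
engine_counters <- function(eng) eng$counters

#' Extract the full recorded output raster
#'
#' @param eng An [event_engine()].
#' @return A [spike_raster()] of all spikes recorded since engine creation.
#' @export
engine_raster <- function(eng) {
  idx <- seq_len(eng$n_out)
  spike_raster(eng$out_id[idx], eng$out_t[idx],
               n_neurons = sum(vapply(eng$pops, function(p) p$n, integer(1))))
}

#' Extract a projection's current weight matrix
#'
#' @param eng An [event_engine()].
#' @param index Projection index in the network's projection list.
#' @return Numeric weight matrix (rows = sources, columns = targets).
#' @export
engine_weights <- function(eng, index = 1L) eng$projs[[index]]$W

#' One-shot event-driven simulation
#'
#' Convenience wrapper: builds an engine, runs it over `input` to `t_end`,
#' and returns the results.
#'
#' @param network An [snn_network()].
#' @param input A [spike_raster()] of input spikes.
#' @param t_end Simulation end time, ms.
#' @param config An [engine_config()].
#' @return A list of class `sim_result` with `raster` (output spikes),
#'   `counters` (see [engine_counters()]), `weights` (final weight matrices,
#'   one per projection), and `engine`.
#' @examples
#' net <- benchmark_network(20, seed = 1)
#' inp <- benchmark_input(n_inputs = 20, rate = 10, duration = 1000, seed = 2)
#' res <- simulate_event(net, inp, t_end = 1000)
#' res$raster
#' @export
simulate_event <- function(network, input, t_end, config = engine_config()) {
  eng <- event_engine(network, config)
  raster <- engine_run(eng, input, t_end)
  structure(list(raster = raster, counters = engine_counters(eng),
                 weights = lapply(eng$projs, function(pe) pe$W),
                 engine = eng),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("event-driven simulation: %d output spikes\n", nrow(x$raster)))
  cat("counters:\n")
  print(x$counters)
  invisible(x)
}
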