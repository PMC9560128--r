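# Deliberately simple clock-driven reference simulator.
#
# Fixed-step semantics, the standard ones the event engine is validated
# against: input spikes are binned to the step containing them (floor), all
# neurons are decayed every step, thresholds are tested once per step, and
# resets / lateral inhibition act at step granularity. Firing times are
# quantized to the step grid, so simulation error is purely temporal when
# the exact-exponential integrator is used. The step-granular inhibition
# reproduces the classic failure mode: two neurons crossing threshold in
# the same time slice both fire, where the event engine produces a single
# winner.

#' Run the clock-driven reference simulation
#'
#' @param network An [snn_network()] (same description the event engine
#'   accepts).
#' @param input A [spike_raster()] of input-channel spikes.
#' @param t_end Simulation end time, ms.
#' @param config A [clock_config()].
#' @return A list of class `sim_result` with the output `raster` (times on
#'   the step grid), final `weights`, and the integrator actually used.
#' @examples
#' net <- benchmark_network(20, seed = 1)
#' inp <- benchmark_input(20, 10, 1000, seed = 2)
#' clock_run(net, inp, 1000, clock_config(dt = 0.1))$raster
#' @export
clock_run <- function(network, input, t_end, config = clock_config()) {
  dt <- config$dt
  steps <- as.integer(ceiling(t_end / dt - 1e-9))
  exact <- config$integrator == "exact-exponential"

  pops <- lapply(seq_along(network$populations), function(i) {
    p <- network$populations[[i]]
    pr <- p$params
    pe <- new.env(parent = emptyenv())
    pe$name <- p$name
    pe$n <- p$n
    pe$p <- pr
    if (exact) {
      pe$fv <- exp(-dt / pr$tau_v)
      pe$fg <- exp(-dt / pr$tau_g)
      pe$fth <- exp(-dt / pr$tau_theta)
      pe$coef <- .lif_coef(pr)
    } else {
      pe$fv <- 1 - dt / pr$tau_v
      pe$fg <- 1 - dt / pr$tau_g
      pe$fth <- 1 - dt / pr$tau_theta
    }
    pe$v <- rep(pr$v_reset, p$n)
    pe$gE <- numeric(p$n)
    pe$vth <- rep(pr$theta0, p$n)
    pe$t_fire <- rep(-Inf, p$n)
    pe$inhibition <- p$inhibition
    pe$w_inh <- p$w_inh
    pe$inhibit_clear_g <- p$inhibit_clear_g
    pe$record <- p$record
    pe$offset <- network$offsets[[p$name]]
    pe
  })
  names(pops) <- names(network$populations)

  projs <- lapply(network$projections, function(pr) {
    pe <- new.env(parent = emptyenv())
    pe$source <- pr$source
    pe$target <- pr$target
    pe$W <- pr$weights
    pe$plastic <- pr$plastic
    pe$stdp <- pr$stdp
    pe
  })

  # input spikes binned by floor(time / dt)
  o <- order(input$time, input$neuron)
  in_id <- input$neuron[o]
  in_bin <- pmin(as.integer(floor(input$time[o] / dt)), steps - 1L)
  keep <- input$time[o] < t_end
  in_id <- in_id[keep]
  in_bin <- in_bin[keep]
  ci <- 1L
  n_in <- length(in_id)
  input_last <- rep(-Inf, network$n_input)

  out_t <- numeric(1024L)
  out_id <- integer(1024L)
  n_out <- 0L

  for (k in seq_len(steps)) {
    t_now <- k * dt # state time at the end of this step
    # (a) decay all populations over one step
    for (pop in pops) {
      pop$v <- pop$v * pop$fv + if (exact)
        pop$gE * pop$coef * (pop$fg - pop$fv) else pop$gE * dt
      pop$gE <- pop$gE * pop$fg
      pop$vth <- pop$p$theta0 + (pop$vth - pop$p$theta0) * pop$fth
    }
    # (b) deliver the input spikes binned to this step
    while (ci <= n_in && in_bin[ci] == k - 1L) {
      i <- in_id[ci]
      for (pe in projs) {
        if (pe$source != "input") next
        pop <- pops[[pe$target]]
        w <- pe$W[i, ]
        pop$gE <- pop$gE + pop$p$C * w
        if (pe$plastic) pe$W[i, ] <- stdp_on_pre(w, pop$t_fire, t_now, pe$stdp)
      }
      input_last[i] <- t_now
      ci <- ci + 1L
    }
    # (c) threshold test, resets, plasticity, step-granular inhibition
    for (pop in pops) {
      fired <- which(pop$v >= pop$vth)
      if (!length(fired)) next
      p <- pop$p
      if (pop$record) {
        need <- n_out + length(fired)
        while (need > length(out_t)) {
          out_t <- c(out_t, numeric(length(out_t)))
          out_id <- c(out_id, integer(length(out_id)))
        }
        out_t[(n_out + 1L):need] <- t_now
        out_id[(n_out + 1L):need] <- pop$offset + fired
        n_out <- need
      }
      for (pi in seq_along(projs)) {
        pe <- projs[[pi]]
        if (pe$plastic && pe$target == pop$name) {
          tp <- if (pe$source == "input") input_last else pops[[pe$source]]$t_fire
          for (kk in fired) pe$W[, kk] <- stdp_on_post(pe$W[, kk], tp, t_now, pe$stdp)
        }
      }
      pop$t_fire[fired] <- t_now
      # downstream deliveries from fired neurons (applied this same step)
      for (pe in projs) {
        if (pe$source != pop$name) next
        tgt <- pops[[pe$target]]
        add <- if (length(fired) == 1L) pe$W[fired, ] else colSums(pe$W[fired, , drop = FALSE])
        tgt$gE <- tgt$gE + tgt$p$C * add
      }
      pop$v[fired] <- p$v_reset
      pop$gE[fired] <- 0
      pop$vth[fired] <- pop$vth[fired] + p$theta_inc
      # all same-step crossers have already fired: inhibition only reaches
      # the remaining siblings — the time-slice failure mode by design
      if (pop$inhibition != "none" && length(fired) < pop$n) {
        others <- setdiff(seq_len(pop$n), fired)
        if (pop$inhibition == "subtract") {
          pop$v[others] <- pmax(pop$v[others] - length(fired) * pop$w_inh, p$v_reset)
        } else {
          pop$v[others] <- p$v_reset
        }
        if (pop$inhibit_clear_g) pop$gE[others] <- 0
      }
    }
  }
  idx <- seq_len(n_out)
  structure(list(raster = spike_raster(out_id[idx], out_t[idx],
                                       n_neurons = sum(vapply(pops, function(p) p$n, integer(1)))),
                 weights = lapply(projs, function(pe) pe$W),
                 dt = dt, integrator = config$integrator),
            class = "sim_result")
}
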