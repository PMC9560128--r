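test_that("queue operations order, tie-break, replace, and invalidate predictions", {
  p <- p41()
  net <- snn_network(2,
    list(population("a", 3, p), population("b", 3, p)),
    list(projection("input", "a", matrix(0.1, 2, 3)),
         projection("input", "b", matrix(0.1, 2, 3))))
  eng <- event_engine(net)

  # schedule then pop on an empty engine returns the same event
  engine_schedule(eng, "a", 2, 7.5)
  ev <- engine_pop_event(eng)
  expect_equal(ev, list(time = 7.5, population = "a", neuron = 2L))
  expect_null(engine_pop_event(eng))

  # equal times pop in (population id, neuron index) order
  engine_schedule(eng, "b", 1, 4)
  engine_schedule(eng, "a", 3, 4)
  engine_schedule(eng, "a", 1, 4)
  expect_equal(engine_pop_event(eng), list(time = 4, population = "a", neuron = 1L))
  expect_equal(engine_pop_event(eng), list(time = 4, population = "a", neuron = 3L))
  expect_equal(engine_pop_event(eng), list(time = 4, population = "b", neuron = 1L))

  # replacing a prediction with an earlier one reorders the global head
  engine_schedule(eng, "a", 1, 9)
  engine_schedule(eng, "b", 2, 5)
  expect_equal(engine_next_event(eng)$time, 5)
  engine_schedule(eng, "a", 1, 3) # supersedes the t=9 prediction
  expect_equal(engine_next_event(eng),
               list(time = 3, population = "a", neuron = 1L))

  # invalidation removes a prediction; a second invalidation is a no-op
  engine_invalidate_prediction(eng, "a", 1)
  expect_equal(engine_next_event(eng)$population, "b")
  engine_invalidate_prediction(eng, "a", 1)
  expect_equal(engine_next_event(eng)$population, "b")

  # scheduling into the past violates the contract
  eng$time <- 10
  expect_error(engine_schedule(eng, "a", 1, 9.5), "past")
})

test_that("run interleaves inputs and fires; empty input gives empty output", {
  b <- small_benchmark(10, seed = 5)
  expect_equal(nrow(simulate_event(b$net, spike_raster(), 1000)$raster), 0)

  res <- simulate_event(b$net, b$inp, 1000)
  expect_gt(nrow(res$raster), 0)
  expect_true(!is.unsorted(res$raster$time))
  expect_true(all(res$raster$time <= 1000))
  # conservation of causes: the first output spike cannot precede the
  # first input spike
  expect_gte(min(res$raster$time), min(b$inp$time))
})

test_that("a single strong input produces exactly one spike at the bisection time", {
  p <- neuron_params(tau_v = 20, tau_g = 1, C = 1, theta0 = 40,
                     theta_inc = 0.5, tau_theta = 1e7)
  net <- snn_network(1, list(population("out", 1, p)),
                     list(projection("input", "out", matrix(100, 1, 1))))
  res <- simulate_event(net, spike_raster(1, 5), 100)
  expect_equal(nrow(res$raster), 1)
  t_ref <- grid_crossing(0, 100, 40, 20, 1) # independent fine-grid scan
  expect_equal(res$raster$time, 5 + t_ref, tolerance = 1e-5)
  # a weak input (below the conductance bound) triggers no peak computation
  net2 <- snn_network(1, list(population("out", 1, p)),
                      list(projection("input", "out", matrix(0.5, 1, 1))))
  res2 <- simulate_event(net2, spike_raster(1, 5), 100)
  expect_equal(nrow(res2$raster), 0)
  expect_equal(unname(res2$counters["peak_evals"]), 0)
})

test_that("optimization toggles change work counters, never the spike raster", {
  b <- small_benchmark(25, seed = 6)
  grid <- expand.grid(pop = c(TRUE, FALSE), filt = c(TRUE, FALSE),
                      lazy = c(TRUE, FALSE))
  runs <- lapply(seq_len(nrow(grid)), function(i)
    simulate_event(b$net, b$inp, 1000,
                   engine_config(grid$pop[i], grid$filt[i], grid$lazy[i])))
  base <- runs[[which(grid$pop & grid$filt & !grid$lazy)]]
  expect_gt(nrow(base$raster), 0)
  for (i in seq_along(runs)) {
    r <- runs[[i]]$raster
    expect_equal(nrow(r), nrow(base$raster))
    expect_identical(r$neuron, base$raster$neuron)
    if (!grid$lazy[i]) {
      expect_identical(r$time, base$raster$time) # bitwise
    } else {
      # deferring threshold decay perturbs each crossing by at most
      # (v_th - theta0) * t / tau_theta / v'(t*), well under a microsecond
      expect_lt(max(abs(r$time - base$raster$time)), 1e-3)
    }
  }
  # population computing reuses decay factors; the pre-filter skips peaks
  pick <- function(pop, filt, lazy) runs[[which(grid$pop == pop & grid$filt == filt & grid$lazy == lazy)]]
  expect_lt(pick(TRUE, TRUE, FALSE)$counters[["decay_evals"]],
            pick(FALSE, TRUE, FALSE)$counters[["decay_evals"]])
  expect_lt(pick(TRUE, TRUE, FALSE)$counters[["peak_evals"]],
            pick(TRUE, FALSE, FALSE)$counters[["peak_evals"]])
})

test_that("deferred threshold updates save exponentials when firing is sparse", {
  # one neuron, several deliveries, a single fire: the eager path decays
  # the threshold at every update, the lazy path only at the fire
  p <- neuron_params(tau_v = 20, tau_g = 1, C = 1, theta0 = 40,
                     theta_inc = 0.5, tau_theta = 1e7)
  net <- snn_network(1, list(population("out", 1, p)),
                     list(projection("input", "out", matrix(30, 1, 1))))
  inp <- spike_raster(rep(1L, 6), c(1, 10, 20, 30, 40, 40.2))
  eager <- simulate_event(net, inp, 100, engine_config(enable_lazy_threshold = FALSE))
  lazy <- simulate_event(net, inp, 100, engine_config(enable_lazy_threshold = TRUE))
  expect_equal(nrow(eager$raster), nrow(lazy$raster))
  expect_lt(lazy$counters[["theta_evals"]], eager$counters[["theta_evals"]])
  expect_equal(unname(lazy$counters[["theta_evals"]]), nrow(lazy$raster))
})

test_that("population mode computes two decay factors per delivery, naive mode 2N", {
  n <- 200
  p <- p41()
  net <- snn_network(1, list(population("out", n, p)),
                     list(projection("input", "out", matrix(0.001, 1, n))))
  one_spike <- spike_raster(1, 10)
  pop_on <- simulate_event(net, one_spike, 20, engine_config(TRUE, TRUE))
  pop_off <- simulate_event(net, one_spike, 20, engine_config(FALSE, TRUE))
  expect_equal(unname(pop_on$counters["decay_evals"]), 2)
  expect_equal(unname(pop_off$counters["decay_evals"]), 2 * n)
  expect_equal(unname(pop_on$counters["deliveries"]), n)
})

test_that("every output spike has an input delivery since the neuron's last reset", {
  b <- small_benchmark(15, seed = 8)
  res <- simulate_event(b$net, b$inp, 1000)
  out <- res$raster
  for (k in unique(out$neuron)) {
    fires <- out$time[out$neuron == k]
    prev <- 0
    for (tf in fires) {
      # fully connected: any input spike in (prev, tf] is a delivery to k
      expect_true(any(b$inp$time > prev & b$inp$time <= tf))
      prev <- tf
    }
  }
})

test_that("direct lateral inhibition elects a single winner at exact times", {
  # two neurons driven to cross threshold 0.2 ms apart: the earlier one
  # fires and suppresses the later one before it can reach threshold
  p <- neuron_params(tau_v = 20, tau_g = 1, C = 1, theta0 = 40,
                     theta_inc = 0.5, tau_theta = 1e7)
  W <- matrix(c(100, 0, 0, 60), 2, 2) # channel i drives neuron i
  net_inh <- snn_network(2,
    list(population("out", 2, p, inhibition = "subtract", w_inh = 100)),
    list(projection("input", "out", W)))
  inp <- spike_raster(c(1L, 2L), c(5, 5))
  res <- simulate_event(net_inh, inp, 100)
  expect_equal(nrow(res$raster), 1)
  expect_equal(res$raster$neuron, 1L)

  # without inhibition both fire
  net_no <- snn_network(2, list(population("out", 2, p)),
                        list(projection("input", "out", W)))
  expect_equal(nrow(simulate_event(net_no, inp, 100)$raster), 2)

  # no two same-population spikes at the same timestamp under inhibition
  b <- small_benchmark(15, seed = 9, inhibition = "subtract", w_inh = 100)
  r <- simulate_event(b$net, b$inp, 1000)$raster
  expect_equal(anyDuplicated(r$time), 0)

  # inhibition in a one-neuron population is a no-op
  net1 <- snn_network(1,
    list(population("out", 1, p, inhibition = "subtract", w_inh = 100)),
    list(projection("input", "out", matrix(100, 1, 1))))
  expect_equal(nrow(simulate_event(net1, spike_raster(1, 5), 50)$raster), 1)
})

test_that("new input or inhibition revises a pending prediction", {
  p <- neuron_params(tau_v = 20, tau_g = 1, C = 1, theta0 = 40,
                     theta_inc = 0.5, tau_theta = 1e7)
  # second excitatory input moves the predicted spike earlier
  net <- snn_network(2, list(population("out", 1, p)),
                     list(projection("input", "out", matrix(c(60, 60), 2, 1))))
  res1 <- simulate_event(net, spike_raster(1L, 5), 100)
  t_single <- res1$raster$time
  res2 <- simulate_event(net, spike_raster(c(1L, 2L), c(5, 5.05)), 100)
  expect_equal(nrow(res2$raster), 1)
  expect_lt(res2$raster$time, t_single)
  # engine matches the clock-driven reference on both stimuli
  for (inp in list(spike_raster(1L, 5), spike_raster(c(1L, 2L), c(5, 5.05)))) {
    ck <- clock_run(net, inp, 100, clock_config(dt = 1e-3))
    evr <- simulate_event(net, inp, 100)$raster
    expect_equal(nrow(ck$raster), nrow(evr))
    expect_lt(max(abs(ck$raster$time - evr$time)), 5e-3)
  }
})

test_that("simulation state persists across sequential runs", {
  b <- small_benchmark(10, seed = 10)
  eng <- event_engine(b$net)
  r1 <- engine_run(eng, b$inp, 500)
  shifted <- spike_raster(b$inp$neuron, b$inp$time + 500)
  r2 <- engine_run(eng, shifted, 1000)
  expect_gte(min(r2$time), 500)
  full <- engine_raster(eng)
  expect_equal(nrow(full), nrow(r1) + nrow(r2))
  expect_error(engine_run(eng, b$inp, 1500), "precede")
})
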