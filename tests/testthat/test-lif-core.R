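test_that("decay_state reproduces the frozen RK4 reference values", {
  p <- neuron_params(tau_v = 20, tau_g = 5)
  s <- decay_state(neuron_state(v = 0, g_E = 5, v_th = 40), 5, p)
  # RK4 at step 1e-4 ms: v = 13.6973780633, g = 1.8393972059
  expect_equal(s$v, 13.6973780633, tolerance = 1e-8)
  expect_equal(s$g_E, 1.8393972059, tolerance = 1e-8)

  # dt = 0 is the identity
  s0 <- neuron_state(v = 3, g_E = 2, v_th = 41, t_last = 7)
  expect_identical(decay_state(s0, 0, p), s0)

  # pure exponential when g_E = 0
  s1 <- decay_state(neuron_state(v = 10), 20, p)
  expect_equal(s1$v, 10 * exp(-1), tolerance = 1e-12)
  expect_equal(s1$g_E, 0)

  expect_error(decay_state(s0, -1, p), "dt")
})

test_that("decay_state matches RK4 over randomized states and intervals", {
  p <- neuron_params(tau_v = 20, tau_g = 5, theta0 = 40)
  n <- 200
  st <- random_states(n, p, seed = 101)
  dt <- withr::with_seed(102, stats::runif(n, 0, 10 * p$tau_v))
  closed_v <- closed_g <- numeric(n)
  for (i in seq_len(n)) {
    s <- decay_state(neuron_state(st$v[i], st$g[i], st$v_th[i]), dt[i], p)
    closed_v[i] <- s$v
    closed_g[i] <- s$g_E
  }
  ref <- rk4_decay(st$v, st$g, dt, p$tau_v, p$tau_g) # vectorized over states
  expect_lt(max(abs(closed_v - ref$v) / pmax(abs(ref$v), 1e-6)), 1e-6)
  expect_lt(max(abs(closed_g - ref$g) / pmax(abs(ref$g), 1e-6)), 1e-6)
})

test_that("decay_state composes exactly (semigroup property)", {
  p <- neuron_params(tau_v = 20, tau_g = 5)
  st <- random_states(50, p, seed = 103)
  splits <- withr::with_seed(104, stats::runif(50, 0.05, 0.95))
  for (i in seq_len(50)) {
    s0 <- neuron_state(st$v[i], st$g[i], st$v_th[i])
    dt <- 15
    once <- decay_state(s0, dt, p)
    twice <- decay_state(decay_state(s0, dt * splits[i], p), dt * (1 - splits[i]), p)
    expect_equal(once$v, twice$v, tolerance = 1e-9)
    expect_equal(once$g_E, twice$g_E, tolerance = 1e-9)
    expect_equal(once$v_th, twice$v_th, tolerance = 1e-9)
  }
})

test_that("apply_spike bumps conductance by C * w and nothing else", {
  p <- neuron_params(tau_v = 20, tau_g = 5, C = 1)
  s <- apply_spike(neuron_state(v = 1, g_E = 2, v_th = 40), 0.3, p)
  expect_equal(s$g_E, 2.3)
  expect_equal(s$v, 1)
  expect_equal(s$v_th, 40)
  expect_identical(apply_spike(s, 0, p), s)
  # size-compensated gain: C = 1000/(N*Fr), N=100, Fr=10 -> C=1
  p2 <- neuron_params(tau_v = 20, tau_g = 5, C = 1000 / (100 * 10))
  expect_equal(apply_spike(neuron_state(), 1, p2)$g_E, 1)
})

test_that("peak_voltage matches the frozen grid-scan values and edge cases", {
  p <- neuron_params(tau_v = 20, tau_g = 5)
  pk <- peak_voltage(neuron_state(v = 0, g_E = 5, v_th = 40), p)
  # grid scan at 1e-4 ms: t' = 9.2420, v_max = 15.7490131236
  expect_equal(pk$t_prime, 9.2420, tolerance = 1e-4)
  expect_equal(pk$v_max, 15.7490131236, tolerance = 1e-8)
  expect_false(pk$will_fire)

  # no drive: peak is the current potential
  pk0 <- peak_voltage(neuron_state(v = 12, g_E = 0, v_th = 40), p)
  expect_equal(pk0$v_max, 12)
  expect_false(pk0$will_fire)
  expect_lte(pk0$t_prime, 0)

  # derivative non-positive at T (g <= v/tau_v): monotone decay
  pk1 <- peak_voltage(neuron_state(v = 20, g_E = 20 / 20, v_th = 40), p)
  expect_lte(pk1$t_prime, 0)
  expect_equal(pk1$v_max, 20)

  # a negative potential with weak drive relaxes toward zero from below:
  # no attained extremum, and the neuron can never reach a positive
  # threshold without further input
  pk2 <- peak_voltage(neuron_state(v = -4, g_E = 0.16, v_th = 40), p)
  expect_lte(pk2$t_prime, 0)
  expect_false(pk2$will_fire)
  expect_lt(max(v_trajectory(seq(0, 500, by = 0.01), -4, 0.16, p$tau_v, p$tau_g)), 0)
})

test_that("peak_voltage agrees with a dense grid scan on random states", {
  p <- neuron_params(tau_v = 20, tau_g = 5, theta0 = 40)
  st <- random_states(300, p, seed = 105)
  for (i in seq_len(300)) {
    pk <- peak_voltage(neuron_state(st$v[i], st$g[i], st$v_th[i]), p)
    ref <- grid_peak(st$v[i], st$g[i], p$tau_v, p$tau_g)
    expect_lt(abs(pk$v_max - ref$v_max) / max(abs(ref$v_max), 1e-6), 1e-6)
    if (pk$t_prime > 0) expect_lt(abs(pk$t_prime - ref$t), 1e-3)
  }
})

test_that("prefilter reduces to the stated bounds and never misses a firing state", {
  # v = v_th: condition reduces to g >= v_th / tau_v
  p <- neuron_params(tau_v = 20, tau_g = 5)
  expect_true(prefilter(neuron_state(v = 40, g_E = 40 / 20 + 1e-9, v_th = 40), p))
  expect_false(prefilter(neuron_state(v = 40, g_E = 40 / 20 - 1e-9, v_th = 40), p))

  # direct substitution: v=0, v_th=40, tau_v=20, tau_g=1 -> bound 42
  p2 <- neuron_params(tau_v = 20, tau_g = 1)
  expect_true(prefilter(neuron_state(v = 0, g_E = 50, v_th = 40), p2))
  expect_false(prefilter(neuron_state(v = 0, g_E = 41, v_th = 40), p2))

  # soundness sweep against the peak oracle (acceptance runs 1e5; this is
  # the fast per-commit version)
  st <- random_states(20000, p41(), seed = 106)
  pk <- spikesim:::.lif_peak(st$v, st$g, p41())
  fires <- pk$v_max >= st$v_th
  passes <- spikesim:::.lif_prefilter(st$v, st$g, st$v_th, p41())
  expect_equal(sum(fires & !passes), 0)
})

test_that("spike_time_bisect finds the grid-scan crossing and halves with tol", {
  p <- neuron_params(tau_v = 20, tau_g = 1)
  s <- neuron_state(v = 0, g_E = 100, v_th = 40)
  t_hat <- spike_time_bisect(s, p, tol = 1e-9)
  expect_equal(t_hat, 0.52033990, tolerance = 1e-6) # 1e-6 ms grid scan
  # convergence guarantee: the returned midpoint is within tol/2 of the
  # root, so halving tol halves the worst-case deviation
  ref <- 0.52033990
  for (tol in c(1e-2, 5e-3, 2.5e-3, 1.25e-3))
    expect_lt(abs(spike_time_bisect(s, p, tol = tol) - ref), tol / 2 + 2e-6)
  # root at bracket end: state whose peak exactly touches threshold
  pk <- peak_voltage(s, p)
  s2 <- neuron_state(v = 0, g_E = 100, v_th = pk$v_max)
  expect_equal(spike_time_bisect(s2, p), pk$t_prime, tolerance = 1e-6)
  # contract violation when the peak cannot reach threshold
  expect_error(spike_time_bisect(neuron_state(0, 1, 40), p), "peak")
})

test_that("fire_reset and threshold dynamics follow the adaptive-threshold rule", {
  p <- p41() # theta0 = 40, theta_inc = 0.5, tau_theta = 1e7
  s <- fire_reset(neuron_state(v = 40, g_E = 3, v_th = 40, t_last = 10), p, 10)
  expect_equal(s$v, 0)
  expect_equal(s$g_E, 0)
  expect_equal(s$v_th, 40.5)
  expect_equal(s$t_last, 10)
  # two rapid fires: increments add, decay negligible at tau_theta = 1e7
  s2 <- fire_reset(s, p, 10 + 1e-6)
  expect_equal(s2$v_th, 41, tolerance = 1e-9)
  # after tau_theta * ln 2 the excess over baseline halves
  s3 <- decay_state(s2, p$tau_theta * log(2), p)
  expect_equal(s3$v_th - p$theta0, (s2$v_th - p$theta0) / 2, tolerance = 1e-9)
  # threshold never undershoots the baseline
  s4 <- decay_state(s2, p$tau_theta * 50, p)
  expect_gte(s4$v_th, p$theta0)
})

test_that("parameter validation rejects degenerate time constants", {
  expect_error(neuron_params(tau_v = 0), "tau_v")
  expect_error(neuron_params(tau_g = -1), "tau_g")
  expect_error(neuron_params(tau_v = 5, tau_g = 5), "differ")
  expect_error(neuron_params(theta_inc = -0.1), "theta_inc")
  # formulas hold for either ordering of the time constants
  p_rev <- neuron_params(tau_v = 5, tau_g = 20)
  ref <- rk4_decay(2, 1, 10, 5, 20)
  s <- decay_state(neuron_state(v = 2, g_E = 1, v_th = 40), 10, p_rev)
  expect_equal(s$v, ref$v, tolerance = 1e-7)
  pk <- peak_voltage(neuron_state(v = 0, g_E = 5, v_th = 40), p_rev)
  gp <- grid_peak(0, 5, 5, 20)
  expect_equal(pk$v_max, gp$v_max, tolerance = 1e-6)
})
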