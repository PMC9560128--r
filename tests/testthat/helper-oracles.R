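# Independent oracles and fixture builders shared across test files.

# RK4 integration of the membrane ODEs (the reference the closed forms are
# validated against); vectorized over states.
rk4_decay <- function(v, g, dt, tau_v, tau_g, n_steps = 4000L) {
  h <- dt / n_steps
  f_v <- function(v, g) -v / tau_v + g
  f_g <- function(g) -g / tau_g
  for (i in seq_len(n_steps)) {
    k1v <- f_v(v, g);                 k1g <- f_g(g)
    k2v <- f_v(v + h/2*k1v, g + h/2*k1g); k2g <- f_g(g + h/2*k1g)
    k3v <- f_v(v + h/2*k2v, g + h/2*k2g); k3g <- f_g(g + h/2*k2g)
    k4v <- f_v(v + h*k3v, g + h*k3g);     k4g <- f_g(g + h*k3g)
    v <- v + h/6*(k1v + 2*k2v + 2*k3v + k4v)
    g <- g + h/6*(k1g + 2*k2g + 2*k3g + k4g)
  }
  list(v = v, g = g)
}

# closed-form trajectory used only through dense evaluation (grid scan),
# independent of the package's peak/bisection code paths
v_trajectory <- function(t, v0, g0, tau_v, tau_g) {
  coef <- tau_g * tau_v / (tau_g - tau_v)
  v0 * exp(-t / tau_v) + g0 * coef * (exp(-t / tau_g) - exp(-t / tau_v))
}

# two-stage grid scan for the peak: coarse bracket then 1e-4 ms refinement
grid_peak <- function(v0, g0, tau_v, tau_g, t_max = 60) {
  tc <- seq(0, t_max, by = 0.01)
  vc <- v_trajectory(tc, v0, g0, tau_v, tau_g)
  i <- which.max(vc)
  tf <- seq(max(0, tc[i] - 0.02), tc[i] + 0.02, by = 1e-4)
  vf <- v_trajectory(tf, v0, g0, tau_v, tau_g)
  j <- which.max(vf)
  list(t = tf[j], v_max = vf[j])
}

# first grid point at/above threshold (bisection oracle)
grid_crossing <- function(v0, g0, v_th, tau_v, tau_g, t_max = 10, by = 1e-6) {
  tt <- seq(0, t_max, by = by)
  vv <- v_trajectory(tt, v0, g0, tau_v, tau_g)
  tt[which(vv >= v_th)[1]]
}

# random states below threshold at given params; nonnegative potentials
# (the simulator's operating domain: resets and inhibition clamp at v_reset)
random_states <- function(n, params, seed) {
  withr::with_seed(seed, {
    v_th <- params$theta0 + stats::runif(n, 0, 5)
    list(v = stats::runif(n, 0, params$theta0 * 0.99),
         g = stats::rexp(n, rate = 1 / (params$theta0 / params$tau_v)),
         v_th = v_th)
  })
}

# small fully connected benchmark fixture (size-compensated gain, so it
# actually fires at any size)
small_benchmark <- function(n = 20, rate = 10, duration = 1000, seed = 1,
                            inhibition = "none", w_inh = 0) {
  params <- neuron_params(tau_v = 20, tau_g = 5, C = 1000 / (n * rate),
                          v_reset = 0, theta0 = 100, theta_inc = 0.5,
                          tau_theta = 1e7)
  net <- snn_network(n,
    populations = list(population("out", n, params,
                                  inhibition = inhibition, w_inh = w_inh)),
    projections = list(projection("input", "out", matrix(1, n, n))))
  inp <- benchmark_input(n, rate, duration, seed = seed)
  list(net = net, inp = inp, params = params, duration = duration)
}

p41 <- function() neuron_params(tau_v = 20, tau_g = 5, C = 1, v_reset = 0,
                                theta0 = 40, theta_inc = 0.5, tau_theta = 1e7)
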