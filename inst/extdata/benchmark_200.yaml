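# Two-layer 200-200 performance benchmark: 200 Poisson input channels at
# 10 Hz fully connected to 200 LIF output neurons, 10 s of simulated time.
n_input: 200
t_end: 10000
seed: 1
engine:
  population: true
  prefilter: true
  lazy_threshold: false
populations:
  - name: out
    size: 200
    params:
      tau_v: 20
      tau_g: 5
      C: 1
      v_reset: 0
      theta0: 40
      theta_inc: 0.5
      tau_theta: 1.0e7
    inhibition: none
projections:
  - source: input
    target: out
    weights: {random: uniform, min: 0, max: 0.3}
    plastic: false
input:
  kind: benchmark
  rate: 10
  duration: 10000
  dialect: poisson
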