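Package: spikesim
Title: Event-Driven Simulation of Spiking Neural Networks with Closed-Form
    Leaky Integrate-and-Fire Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An event-driven simulator for networks of conductance-based leaky
    integrate-and-fire neurons. Neuron state is advanced only at spike events
    using exact closed-form solutions of the membrane equations; future spikes
    are predicted analytically from the peak of the membrane-potential
    trajectory and located precisely by bisection. A cheap conductance
    pre-filter skips peak computations that cannot lead to a spike, and
    population-level updates reuse exponential decay factors across neurons
    that share an update interval. Includes event-driven spike-timing-dependent
    plasticity (STDP), adaptive firing thresholds, direct lateral inhibition
    with exact (sub-timestep) winner-take-all semantics, a deliberately simple
    clock-driven reference simulator for validation, latency and rate encoders
    for image data, IDX readers, a synthetic-digit generator, and an
    unsupervised digit-classification training harness.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
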