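---
title: "Event-driven simulation of LIF networks: models, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-driven simulation of LIF networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikesim)
```

## The neuron model and its closed forms

spikesim simulates conductance-based leaky integrate-and-fire neurons.
Between spikes the membrane potential $v$ and excitatory conductance $g_E$
obey the linear system

$$\frac{dv}{dt} = -\frac{v}{\tau_v} + g_E, \qquad
  \frac{dg_E}{dt} = -\frac{g_E}{\tau_g},$$

with all times in milliseconds. A presynaptic spike of weight $w$ steps
$g_E$ by $C\,w$ instantaneously and leaves $v$ untouched; when $v$ reaches
the threshold $v_{th}$ the neuron emits a spike, $v \leftarrow v_{reset}$,
$g_E \leftarrow 0$, and $v_{th}$ jumps by a fixed increment $\theta$ before
relaxing exponentially toward its baseline $\theta_0$ with time constant
$\tau_\theta$. The adaptive threshold is the model's only homeostatic
mechanism: it taxes recently active neurons so that others get to fire,
which is what drives specialization in the learning harness.

Because $g_E$ does not depend on $v$, the system solves in closed form.
Over a quiescent interval $\Delta t$,

$$g_E(T+\Delta t) = g_E(T)\,e^{-\Delta t/\tau_g}, \qquad
  v(T+\Delta t) = v(T)\,e^{-\Delta t/\tau_v}
  + g_E(T)\,\frac{\tau_g \tau_v}{\tau_g - \tau_v}
    \left(e^{-\Delta t/\tau_g} - e^{-\Delta t/\tau_v}\right).$$

`decay_state()` implements exactly this, plus the threshold relaxation.
The form requires $\tau_g \neq \tau_v$; the package rejects equality at
configuration time rather than carrying the removable-singularity limit
form that no standard parameterization needs. Both orderings
$\tau_g < \tau_v$ and $\tau_g > \tau_v$ are valid and tested. Closed forms
compose exactly — advancing by $a$ then $b$ equals advancing by $a+b$ to
within the last floating-point digit — which is what makes event-driven
simulation consistent regardless of how often a population is touched.

Setting the derivative of $v(T+t)$ to zero gives the time of the future
extremum,

$$t' = \frac{\tau_g \tau_v}{\tau_g - \tau_v}
  \ln\!\left[\frac{\tau_g}{\tau_v}
  \left(1 - \frac{\tau_g-\tau_v}{\tau_g\tau_v}\,
  \frac{v(T)}{g_E(T)}\right)\right],$$

and `peak_voltage()` evaluates the trajectory there. When $g_E = 0$, when
the logarithm's argument is non-positive, or when $t' \le 0$, the
potential can only decay (or, from a negative potential, relax toward zero
without ever crossing it); the peak is then reported as the current $v$
with sentinel $t' = -\infty$. A neuron whose peak reaches threshold fires
at the first upward crossing, located by bisection on $(0, t']$ — the
trajectory is increasing there, so the root is unique. The default
tolerance of $10^{-9}$ ms is far below any time difference the simulator
compares; bisection needs at most ~60 iterations for the horizons that
occur in practice, and the implementation caps at 200.

## The event loop

The engine maintains, per population, a vector of predicted fire times
whose minimum is that population's contribution to the global queue; the
global head is the minimum over local heads and a cursor into the
pre-sorted input stream. This flat array is the local priority queue:
scheduling and invalidation are single writes, the head lookup is a
vectorized `which.min`, and stale entries cannot exist because each neuron
owns exactly one slot. For populations up to a few hundred neurons this is
both simpler and faster in R than a binary heap with tombstones, and it
makes prediction invalidation — required whenever new input or inhibition
changes a neuron's future — trivially correct.

Processing one event has the classic three sub-steps: (a) advance the
target population to the event time with the closed forms; (b) add
$C\,w$ to each target's conductance; (c) re-derive predictions. Event
order is the lexicographic key (time, population id, neuron index), with
external input events preceding predicted fires at equal times; this makes
runs bit-for-bit reproducible across platforms. Input spikes are consumed
from a pre-sorted stream cursor rather than preloaded into the queue, so
arbitrarily long stimuli cost constant queue memory.

### Optimizations are observable as counters, not milliseconds

Wall-clock timing is hardware- and interpreter-bound, so the package
treats operation counts as the first-class measure of work
(`engine_counters()`): spike deliveries (spikes × fan-outs), decay-factor
evaluations, threshold-decay evaluations, pre-filter checks, peak
computations, and bisections. The three optimization toggles change only
these counters:

* **Population computing** (`enable_population`): a dense projection
  delivers every spike to every member, so all members share one update
  interval and the two decay factors are computed once per population
  (2 per delivery) instead of per neuron (2N). Because the factors are
  the same numbers either way, the rasters agree bitwise.
* **Pre-filtering** (`enable_prefilter`): integrating the membrane
  inequality $dv/dt \le g_E$ shows a neuron can reach $v_{th}$ only if
  $g_E \ge v_{th}/\tau_v + (v_{th} - v)/\tau_g$. The bound is necessary,
  never sufficient, so filtering skips peak computations without ever
  skipping a spike — the test suite sweeps $10^5$ random states against
  the analytic peak to confirm zero false negatives. Rasters again agree
  bitwise, since the filter only skips computations whose outcome is
  already known.
* **Lazy threshold updates** (`enable_lazy_threshold`): with
  $\tau_\theta = 10^7$ ms the per-event threshold decay factor differs
  from 1 by about $10^{-11}$ per delivery, so the eager per-update decay
  can be deferred to each neuron's own fire events. This is an
  approximation: predictions made between a neuron's fires use a
  threshold that is stale by up to $(v_{th}-\theta_0)\,T/\tau_\theta$.
  With shallow threshold crossings the induced spike-time shift reaches
  the order of $10^{-4}$ ms, so the package documents (and tests) raster
  agreement to $10^{-3}$ ms rather than bit-identity. Note also that the
  saving is regime-dependent: deferring pays when deliveries far outnumber
  fires, and can cost extra flushes when a population fires at nearly
  every update.

### Lateral inhibition

Direct lateral inhibition is a population attribute: when a member fires,
every sibling is suppressed at the same timestamp and re-predicted.
Two mechanisms are provided, `"subtract"` (membrane potential lowered by
`w_inh`, clamped below at $v_{reset}$; the default, with `w_inh` of the
order of $\theta_0$ giving near-reset suppression) and `"reset"` (hard
reset to $v_{reset}$). A separate switch, `inhibit_clear_g`, controls
whether the sibling conductance is also cleared. The package default
leaves $g_E$ untouched — suppression then delays rather than cancels a
strongly driven competitor — while the digit harness enables clearing to
obtain strict winner-take-all per input volley (see below). Because
suppression happens at exact spike times, a later-by-microseconds
competitor is reliably silenced; under a clock-driven scheme both
competitors fire whenever they cross within one time slice, and the test
suite demonstrates exactly this failure with a two-neuron race at
`dt = 1` ms.

## The clock-driven reference

`clock_run()` implements deliberately plain fixed-step semantics: inputs
are binned by `floor(t/dt)`, every neuron decays every step, thresholds
are tested once per step, and resets, plasticity, and inhibition act at
step granularity. With the `exact-exponential` integrator the per-step
state update uses the same closed forms, so the only error source is
temporal quantization — this isolates the accuracy argument for
event-driven simulation from integrator error. A `forward-euler`
integrator is included to show what first-order stepping adds: at coarse
steps it overshoots the trajectory and can emit spikes for stimuli whose
true peak never reaches threshold. Convergence (raster matching as
`dt` shrinks over 1.0, 0.1, 0.01 ms) is asserted in the acceptance suite
with a greedy per-neuron spike-matching report (`compare_rasters()`).

## Encoders and the benchmark stimulus

Images enter the network as spikes. Latency (time) coding emits at most
one spike per pixel at $t = D\,(1 - p/255)$ — bright pixels early, at most
784 spikes per 28×28 sample — while rate (frequency) coding draws a
Poisson train per pixel with rate proportional to intensity, roughly an
order of magnitude more spikes at conventional settings (100 ms / 350 ms
windows); this spike-count economy is the reason the learning harness
defaults to latency coding. The exact latency map is a package choice:
any decreasing map would do, and the tests rely only on the one-spike cap
and intensity ordering.

The two-layer performance benchmark drives $N$ input channels at rate
$F_r$ into $N$ fully connected LIF neurons. Two parameterizations are
built in: `"fixed"` (unit gain, weights uniform in (0, 0.3), baseline
threshold 40, $\tau_v = 20$, $\tau_g = 5$) and `"scaled"` (unit weights
with $C = 1000/(N F_r)$, baseline 100), whose size-compensated gain keeps
the output regime independent of $N$ and $F_r$ — that is what makes the
scaling study meaningful, with deliveries growing as $N^2$ at fixed rate.
The stimulus generator offers three dialects: Poisson trains, periodic
trains with jitter, and a fixed-count dialect placing exactly
$F_r \cdot T/1000$ spikes per channel at uniform times. The benchmark
protocol states its total spike budget exactly (20,000 spikes for
$N = 200$, 10 Hz, 10 s), so the benchmark drivers use the fixed-count
dialect; it removes the $\pm\sqrt{20000}$ total-count noise a Poisson
draw would add on top of the weight-draw variability. Single-run output
counts in the `"fixed"` benchmark still vary by roughly ±20% with the
weight draw — the output regime is fluctuation-driven, with each neuron's
threshold ratcheting until its attainable peak no longer clears it — so
headline counts are reported as means over 20 independent draws.

## The unsupervised digit harness

The harness wires 784 latency-coded inputs through a plastic dense
projection onto an output layer (400 neurons by default) with adaptive
thresholds and direct lateral inhibition, trains it with STDP for one
pass over synthetic digit images, then labels each output neuron by its
strongest class response and classifies held-out images by the
class-mean spike-count vote. Labeling and evaluation run each image in a
fresh engine with frozen weights and the trained thresholds, which makes
the assignment invariant to presentation order.

### What the synthetic digits emulate — and what they do not

`synth_digits()` draws procedural 28×28 glyphs: per-class stroke
stencils with comparable pixel mass (~100–140 lit pixels), a single
per-image stroke intensity uniform in $[0.7, 1]\times 255$, ±1 pixel
translation, and sparse background clutter (each background pixel lit
with probability 0.02). Like scanned digits, the images are mostly zero
and latency coding produces roughly 80–150 spikes per sample. Unlike
scanned digits there is no stroke-thickness or style variability, no
elastic deformation, and — because one intensity is shared by all stroke
pixels — each image arrives as a near-synchronous spike volley followed
by stragglers from the clutter. Passing the pipeline bars on this data
shows the machinery works end to end (specialization, receptive-field
formation, generalization across shifts, intensity and clutter); it does
not certify accuracy on handwriting, whose within-class variability is
far richer. IDX containers are supported (`read_idx()`) for users who
want to feed scanned-digit sets; no test depends on external data.

### Why the harness is parameterized the way it is

The output layer uses $\tau_v = 50$, $\tau_g = 5$, $v_{reset} = 0$,
$\theta_0 = 75$, $\theta = 2.5$, $\tau_\theta = 10^7$, initial weights
uniform in (0.45, 0.55), 100 ms samples with a 150 ms rest during which
state decays naturally (a hard-reset option exists). The remaining knobs
were set once, from the volley dynamics, and then frozen:

* **Conductance gain $C = 1$.** A volley through initial weights gives
  $g_E \approx 0.5 \times$ (lit pixels) $\approx 50{-}70$; the analytic
  peak is $\approx 3.9\,g_E$, comfortably above $\theta_0 = 75$ for every
  glyph class, so every presentation elects a winner. At $C = 0.5$ the
  sparsest class sat within a unit of threshold and entire classes could
  go silent.
* **Strict winner-take-all (`inhibit_clear_g = TRUE`, `w_inh` $=
  \theta_0$).** With sibling conductance retained, several runners-up
  re-fire within a few milliseconds of the winner (their $g_E$ alone
  peaks above threshold), and these cascade spikes dilute the class vote.
  Clearing $g_E$ makes each volley elect exactly one winner.
* **STDP amplitudes $\sigma_+ = 0.08$, $\sigma_- = 0.02$,
  $\tau_\pm = 20$ ms, $w \in [0, 1]$.** Specialization is a race between
  potentiation (which accelerates the current winner) and the threshold
  ratchet (+2.5 per win, which handicaps it). $\sigma_+$ must be large
  enough that a handful of wins forms a usable receptive field in a
  single desk-scale epoch, but the potentiation a winner picks up on
  pixels *shared with other classes* must stay below the ratchet
  handicap, or one neuron monopolizes every class. With ~5 shared pixels
  between the default glyphs, $\sigma_+ = 0.08$ satisfies both
  inequalities with margin; depression is kept at a quarter of
  potentiation so late in-sample arrivals do not erase the pattern being
  learned, while clutter pixels — which fire after the winner — are
  steadily pushed down.

The resulting dynamics are sequential monopolies: a neuron wins its class
until its threshold catches up with its potentiated drive, then retires
in favor of a fresh neuron. One epoch over 150 images per class trains a
handful of specialists per class; they dominate the labeling pass, so
responsive neurons are overwhelmingly ones with well-formed receptive
fields. This is the honest desk-scale picture: with strict WTA and a few
hundred presentations, the network learns a few strong prototypes per
class rather than hundreds of varied ones.

## Numerical choices and degenerate inputs

* Times are milliseconds throughout; all rasters are sorted by
  (time, neuron) and writers guarantee sortedness on disk.
* Bisection: tolerance $10^{-9}$ ms, cap 200 iterations, error on
  non-convergence (never observed; the cap is a guard).
* A state found at or above threshold during prediction (possible only
  through floating-point coincidence at a shared event time) is scheduled
  to fire immediately rather than bisected.
* Zero-length intervals skip the decay entirely, so repeated events at
  one timestamp cannot accumulate rounding error.
* Empty stimuli, empty populations of predictions, zero-weight spikes,
  sub-unit expected spike counts, and inhibition in singleton populations
  are all defined no-ops and covered by tests.
* `tau_g == tau_v` is rejected at construction; negative `dt`, events
  scheduled into the past, and inputs preceding the engine clock are
  contract errors.

## Problem sizes used by the test suite

The suite validates the closed forms on $10^4$ random states against RK4
integration (4,000 substeps each) and dense trajectory scans refined to
$10^{-4}$ ms; filter soundness on $10^5$ states; toggle transparency on a
50×50 benchmark over all eight toggle combinations; clock convergence and
the spike budget on the 200-200 benchmark (10 s, `dt` down to 0.01 ms);
scaling on $N \in \{50, 100, 200, 400\}$; and the full learning pipeline
at 784–400 with 150 training images per class and 50 held-out per class.
These sizes were chosen so the entire suite completes in a few minutes on
one CPU while still exercising every code path at realistic scale.

## Known limitations

* The closed forms, peak expression, and pre-filter are specific to this
  LIF parameterization; other neuron models would need their own
  derivations (the filter inequality generalizes to any model with a
  bounded drive term, but is not provided for any other model here).
* Conduction delays are not modeled; spikes act on their targets at the
  emission timestamp.
* Execution is single-threaded and the engine favors dense
  layer-to-layer projections; sparse connectivity works but forfeits the
  population-computing economy.
* There is no weight normalization: the adaptive threshold is the only
  homeostatic mechanism, and raising input rates far beyond the
  benchmark regimes can saturate weights at their clip bounds.
* The lateral-inhibition mechanism (subtraction vs reset, conductance
  clearing) is a modeling choice exposed in configuration; results that
  depend on WTA strictness should state which variant was used.
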