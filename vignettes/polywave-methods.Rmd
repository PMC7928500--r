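---
title: "Traveling waves and reward-modulated STDP: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Traveling waves and reward-modulated STDP: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polywave)
```

## The model

`polywave` simulates small excitatory spiking networks in which two slow
signals cooperate to teach a local synaptic rule about paths the rule cannot
see on its own: a *traveling wave* of elevated membrane noise that sweeps
over the synaptic graph, and a *global dopamine signal* with tonic and phasic
components.

### Membrane dynamics

Each neuron is a leaky integrate-and-fire unit,

$$\frac{dv_i}{dt} = \frac{v_0 - v_i + h_i + h_i^{ext} - h^{inh}}{\tau}
  + \sigma_i(t)\,\xi_i,$$

with resting potential $v_0 = -70$ mV, membrane time constant $\tau = 10$ ms,
spike threshold $-54$ mV and reset $-60$ mV. The recurrent drive $h_i$ decays
with $\tau_h = 5$ ms and jumps by $h_0 S_{ij}$ ($h_0 = 60$ mV) for each
presynaptic spike of $j$, delayed by $t_d = 2$ ms. A single global inhibitory
drive $h^{inh}$ (decay $\tau_{inh} = 5$ ms, increment $\beta$ per population
spike, delay 1 ms) controls the overall rate; there are no explicit
inhibitory neurons. Stimulated neurons receive a 200 Hz pulse train through
$h_i^{ext}$ during the first 250 ms of each trial; the default pulse
amplitude (25 mV, filtered through $\tau_h$) makes a resting neuron fire
once per pulse, so stimulated neurons fire at roughly the pulse rate.

### The wavefield

Up and down states are modelled as noise levels: each neuron carries a local
field $\psi_i$ (mV, clipped to $[-1, 100]$) obeying

$$\frac{d\psi_i}{dt} = \frac{g_i - \psi_i}{\tau_w}
 + \kappa_{in}\!\!\sum_{j \to i}\big[\psi_j(t-\delta t) - \psi_i(t) - \theta\big]_+
 - \kappa_{out}\!\!\sum_{i \to j}\big[\psi_i(t-\delta t) - \psi_j(t) - \theta\big]_+,$$

with $\tau_w = 200$ ms, propagation delay $\delta t = 20$ ms and threshold
$\theta = 0.001$. The same rectified gap of an edge feeds the postsynaptic
field and drains the presynaptic one, so activity diffuses *along the
synaptic graph*, not through space; sheet edges receive no influx because no
edges exist there, which makes the wave collapse at the boundary. The
printed coupling gains are read as rates, $\kappa_{in} = 0.2/\delta t =
0.01\,\mathrm{ms}^{-1}$ and $\kappa_{out} = 0.1/\delta t$, the only
dimensionally consistent reading. Stimulated neurons drive their field with
a staircase that accumulates $\eta$ every 5 ms during stimulation and drops
to $-5$ mV afterwards, which lets the wave die out: by the end of a 3 s
trial all fields are back near zero (asserted stochastically in the tests).

The field turns into noise through the influx coefficient
$\alpha_i = 5\tanh(\text{count}_i)$, where $\text{count}_i$ is the number of
distinct incoming neighbours whose delayed field has exceeded
$\psi_i + \theta$ at least once this trial (each neighbour counts once per
trial; the delta-function integral of the original counting rule is read as
this event counter). The noise level is $\sigma_i = \mathrm{clip}(\alpha_i
\psi_i + 3, 3, 6)$ mV: 3 mV is the downstate, 6 mV the upstate. In no-wave
control conditions every neuron instead gets one constant `sigma_const`,
calibrated per task so that the population firing rate matches the wave
condition within 10% (see below).

### Plasticity

Each edge keeps an eligibility trace $c_{ij} \in [-S_{max}/2, S_{max}/2]$
driven by an asymmetric STDP window with amplitude $\gamma = 9\times10^{-4}$,
time constant $\tau_{STDP} = 30$ ms and depression factor 1.05, and decaying
with $\tau_c = 1$ s. Weights change only through dopamine:

$$\frac{dS_{ij}}{dt} = c_{ij}\,(D_t + D_p)/\tau_s, \qquad 0 \le S_{ij} \le
S_{max} = 0.24,$$

with the single exception that edges with $c_{ij} < 0$ while $D_p < 0$ are
frozen (punishment does not deepen depression). The residual case
($c > 0$, $D_t + D_p < 0$) follows the plain product and may decrease the
weight. The update is applied every integration step, i.e. the continuous
form of the rule, not a per-trial batch.

**Trace convention.** The per-neuron spike trace $\bar f_i$ is implemented
as the literal exponential running average of the spike train: it decays
with $\tau_{STDP}$ and *gains 1* at each spike. For isolated spike pairs
this makes the window amplitude at zero lag exactly $\gamma$. The
alternative convention, resetting the trace *to* 1 at each spike, looks
equivalent at low rates but breaks the model during stimulation: a neuron
firing at 200 Hz then hits every outbound edge with the full 1.05-weighted
depression term once per spike while the potentiation term stays capped at
$\gamma$, so the stimulated neuron's outbound paths — the very paths the
model is supposed to grow — are systematically depressed. With the
accumulating trace both terms scale with rate and causal pre-to-post
correlations win, which is what the model's outbound strengthening relies
on. Coincident pre/post spikes in the same time step are evaluated with the
traces as they stood before either spike's increment, making the net
increment order-independent.

### Dopamine and novelty

The tonic level is $D_t = d_t \cdot \mathrm{Novelty}$ with $d_t = 0.003$
(zero in the conventional and wave-only conditions). The phasic level $D_p
\in [-0.3, 0.3]$ decays with $\tau_p = 200$ ms; whenever a target or
false-target neuron spikes at time $t$, $D_p$ receives, after a transmission
delay $t_p = 100$ ms, the increment $R(t)\,\Gamma_R(t)\,\mathrm{Novelty}$,
where $R$ is the task reward evaluated on the spike counts accumulated so
far in the trial (the only reading consistent with per-spike jumps and
per-trial counters), and $\Gamma_R$ equals $d_p$ from stimulus onset to
offset and decays with $\tau_d = 200$ ms afterwards. Pending increments are
discarded at the trial boundary.

Novelty starts at 1 (a new task), moves by $\mp 0.2$ after each
correct/wrong trial, and is clipped to $[0, 1]$: a consistently successful
network sees its dopamine — and therefore its learning — switch itself off.
In addition both $d_t$ and $d_p$ ramp linearly to zero over the final 20% of
trials (`decline_fraction`, a schedule the source material leaves
unspecified), freezing the network at the end of a run.

Rewards: Task 1 pays $1$ when the target out-spikes every false target and
$-0.5$ otherwise, gated by a strict total-count threshold of 5; Task 2 pays
$1$ for any target spike; Task 3 pays $\pm 1$ for a 5-spike margin between
the two output neurons. Success is $R > 0$ at trial end for Tasks 1 and 3
and a first-spike latency under 100 ms for Task 2.

## Numerical scheme

Integration is forward Euler–Maruyama at `dt = 0.1` ms. All delays ($t_d$,
$t_h$, $t_p$, $\delta t$, the pulse period) are exact multiples of `dt` and
use ring buffers. Pure exponential decays ($h$, $h^{ext}$, $h^{inh}$,
$\bar f$, $c$, $D_p$) use the exact per-step factor $e^{-dt/\tau}$, so
closed-form decay tests hold to machine precision; $v$ and $\psi$, whose
drives are state-dependent, use the Euler step. Within a step the order is:
wavefield, drives, membranes, plasticity traces, dopamine, weights; spikes
detected in a step apply their STDP events with traces decayed to the end of
that step's bin.

**Noise discretization.** The per-step noise increment is
`noise_gain * sigma * sqrt(dt) * N(0,1)`. The gain is a calibration
constant fixed at 0.5 by the model's own anchor: an isolated neuron at the
fixed upstate level $\sigma = 6$ mV must fire at roughly 5 Hz and be
essentially silent at the downstate level $\sigma = 3$ mV. With a unit gain
the same anchor gives ~53 Hz, so the bare convention is inconsistent with
the stated rates. The acceptance script recomputes both anchors.

Gaussian draws come from R's session RNG, one per neuron per step in index
order, which makes every trial bit-reproducible from `set.seed()` and lets
a pure-R reference stepper replay the identical trajectory; the test suite
holds the compiled core to that reference at tolerance $10^{-12}$ with
identical spike rasters.

## Task networks and the synthetic-data generators

All inputs are generated; there is no external data. Task 1 is an 11 × 11
lattice (100 µm spacing) with a central stimulated neuron, a bottom target
and three false targets; pairs within $200\sqrt2$ µm connect with
probability 0.5 in a uniformly random single direction (re-drawn for
isolated neurons, and the whole draw is repeated until the target is
reachable from the source). Task 2 is a 5 × 5 sheet with connection radius
$100\sqrt5$ µm, the stimulated neuron upper-left, the target bottom-left,
and a forced detour chain along the top, right and bottom boundary whose
weights start at three times the 0.04 base weight; the sheet extent and
detour route are inferred from the task's geometry and are config-overridable.
Task 3 is a feedforward XOR sheet: four stimulated inputs, 120 middle
neurons (strong 0.2 input from the nearest input, weak 0.1 from one random
other input, strong 0.2 projection to one random output), two outputs. The
strong/weak split matters: at the 200 Hz stimulated rate a middle neuron
driven through its strong input alone stays subthreshold while strong +
weak is suprathreshold, so only middles whose two inputs are both active
burst — the coincidence structure XOR needs.

What the generators do *not* emulate: heterogeneous neuron parameters,
conduction delays that scale with distance, structured (non-uniform)
connectivity, and any explicit inhibitory population. Passing tests
therefore show that the learning rule behaves as specified under the
model's idealized conditions, not that it would do so in biological data.

## Calibrated parameters

Three knobs are task-dependent (the rest of the configuration is fixed
across tasks): the inhibitory strength $\beta$, the phasic amplitude $d_p$
and the wave drive gain $\eta$. Their numeric values are not stated in the
source material, so the package fixes them by calibration against each
task's qualitative outcome, once, with these results:

| task | $\beta$ | $d_p$ | $\eta$ | `sigma_const` | trials |
|------|--------|-------|--------|----------------|--------|
| 1 (path reinforcement) | 1 | 0.3 | 8 | 4.875 | 80 |
| 2 (shortcut) | 0.3 | 0.2 | 6 | 5.0625 | 60 |
| 3 (XOR) | 1.5 | 0.04 | 0.8 | 4.125 | 100 |

`sigma_const` is the no-wave noise level produced by [calibrate_sigma()]:
the population rate of five stimulated, plasticity-off trials under the
wave condition is matched by bisection within 10%. (Matching against
*unstimulated* trials would be degenerate — without stimulation the wave
never starts and the match collapses to the 3 mV downstate.)

Why $d_p$ differs so much across tasks: punishment phases of the rule are
purely depressive (negative $D_p$ can only push weights down, since
negative-eligibility edges are frozen), while reward phases both potentiate
and depress. Task 3, whose reward is symmetric ($\pm 1$), therefore erodes
its own drive when $d_p$ is large; it needs a small phasic amplitude that
the tonic component can balance. Task 1's asymmetric reward (+1 / −0.5)
tolerates a much larger amplitude, and benefits from it because its
four-way competition needs a strong differential signal.

## Problem sizes and runtimes

The shipped defaults are the tasks' own protocols: 3 s trials at 0.1 ms
steps, 80/60/100 trials for Tasks 1/2/3. The test suite runs reduced
replication (5–10 seeds where aggregates are asserted); the acceptance
script uses 5 seeds × 10 s for the firing-rate anchors, 20 seeds for the
pre-learning latency and 10 full 60-trial runs for the post-learning
latency. A full Task 1 experiment takes on the order of half a minute on
one core with the compiled integrator.

## Known limitations

* Task 3's absolute XOR success at these desk-scale settings is moderate
  (roughly 0.3–0.4 under the wave conditions against ~0.05–0.1 for the
  no-wave controls in our runs): the wave/no-wave ordering is reproduced,
  but the model does not reach near-perfect XOR under the shipped
  calibration.
* Task 1's advantage over the conventional baseline builds in the second
  half of its 80-trial protocol; the conventional control is not "silent
  failure" but chance-level coin-flipping among the four candidate targets
  once its noise is rate-matched.
* The local field is phenomenological: it modulates only the noise level
  and has no feedback from membrane potentials, so statements about real
  cortical up/down states remain outside what these simulations can show.
* Learning dynamics are sensitive to the stimulated firing rate; the pulse
  amplitude default is part of the calibration and documented above rather
  than a free parameter to vary casually.
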