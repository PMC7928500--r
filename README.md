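# polywave

Spiking-network simulations of how **traveling waves of cortical up-states
help a reward-modulated STDP rule learn poly-synaptic paths** — chains of
synapses connecting neurons that share no direct connection.

A local pair-based plasticity rule cannot, by itself, associate distant
neurons: they are rarely active together before learning. `polywave`
implements a model in which two global signals fix this. A *wavefield*
$\psi_i$ diffuses along the synaptic graph with a 20 ms delay and converts
into per-neuron membrane-noise levels $\sigma_i = \mathrm{clip}(\alpha_i
\psi_i + 3,\,3,\,6)$ mV, sweeping an up-state (≈5 Hz firing at 6 mV noise)
outward from stimulated neurons into quiescent territory (≈0 Hz at 3 mV).
A *dopamine signal* converts STDP eligibility traces $c_{ij}$ into weight
change,

$$\frac{dS_{ij}}{dt} = c_{ij}\,(D_t + D_p)/\tau_s,$$

with a tonic, novelty-scaled component $D_t$ (reward-independent learning)
and a phasic component $D_p$ that jumps by $R \cdot \Gamma_R \cdot
\mathrm{Novelty}$, 100 ms after each target/false-target spike, where $R$
is the task reward. Eligibility follows the classic asymmetric window
(amplitude $\gamma = 9\times10^{-4}$, $\tau_{STDP} = 30$ ms, depression
factor 1.05) and weights are clipped to $[0, 0.24]$.

Three benchmark tasks are built in, each with ablation conditions
(±waves, ±tonic, ±phasic):

1. **Path reinforcement** — an 11×11 lattice; strengthen the poly-synaptic
   route from a stimulated centre to one bottom target against three false
   targets (reward +1 / punishment −0.5).
2. **Shortcut finding** — a 5×5 sheet with a strong 12-synapse detour and
   weak direct paths; learning should cut first-spike latency from the
   detour's >160 ms to under 100 ms via strengthened shortcuts.
3. **XOR** — a feedforward sheet (4 inputs, 120 middle, 2 outputs) in which
   only coincidently driven middle neurons burst; the rewarded output
   follows the XOR truth table.

The inner loop (membranes, drives, wavefield, traces, dopamine, weights) is
compiled (Rcpp); a pure-R reference stepper replays it bit-for-bit in the
test suite.

## Worked example: finding a shortcut

```r
library(polywave)
cfg <- pw_config(task = 2)        # calibrated task defaults
set.seed(1)
net <- build_task2(cfg)
print(net)
#> <polywave_network> task 2: 25 neurons, 83 edges
#>   roles: plain=23, stimulated=1, target=1

ex <- run_experiment(net, cfg, condition = "full")   # waves + tonic + phasic
print(ex)
#> <polywave_experiment> task 2, condition full, 60 trials
#>   success rate: 0.18 (last quarter: 0.40)

tail(ex$log[, c("trial", "R_end", "novelty", "latency_ms", "success")], 5)
#>    trial R_end novelty latency_ms success
#> 56    56     1     0.6       78.7    TRUE
#> 57    57     1     0.4       79.6    TRUE
#> 58    58     1     0.6      100.8   FALSE
#> 59    59     1     0.8      121.0   FALSE
#> 60    60     1     0.6       79.2    TRUE
```

Before learning the target's first spike arrives only via the strong detour
(median ≈ 270–400 ms across seeds); after 60 full-model trials the
strengthened direct paths deliver it in ≈ 79 ms here — under the 100 ms
success criterion. Success is intermittent by design: novelty feedback
switches learning off while the network performs and back on when it slips.
`run_replicates()` aggregates success curves over seeds (mean ± SEM),
`latency_index()` caps latencies at 300 ms for plotting,
`mean_weight_difference_map()` renders the directional weight change over
the sheet, and `path_strength_task3()` scores the XOR wiring.

The up/down-state anchor is directly checkable:

```r
isolated_neuron_rate(6, seeds = 1:3)   # upstate noise  -> 5.07 Hz
isolated_neuron_rate(3, seeds = 1:3)   # downstate      -> 0 Hz
```

A thin command-line front end lives in `inst/cli/polywave.R`:

```sh
Rscript inst/cli/polywave.R run --task 2 --condition full --seed 1 --out out/
Rscript inst/cli/polywave.R calibrate-sigma --task 2
Rscript inst/cli/polywave.R report --in out/
```

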