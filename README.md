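# mmonet

Simulation and analysis of **mixed-mode oscillations (MMOs)** in models of
the pre-Bötzinger complex (pre-BötC), the brainstem kernel circuit of the
inspiratory rhythm. In slices and in models, pre-BötC output alternates
large-amplitude (LA) population bursts with a quantised number of
small-amplitude (SA) bursts — quantal regimes written `1:N`. `mmonet` is for
computational neuroscientists who want to simulate, dissect and extend this
mechanism.

The package implements two models end to end:

* **A 100-neuron conductance-based network.** Single-compartment neurons
  with fast sodium, delayed-rectifier potassium, leak, and a persistent
  (slowly inactivating) sodium current `I_NaP` whose inactivation
  `h_NaP` (τ up to 6 s) is the slow variable pacing bursts:

      C dV/dt = −I_Na − I_NaP − I_K − I_L − I_SynE

  Heterogeneous excitability (leak reversal `E_L ~ N(−62, 0.93²)` mV,
  `ḡ_NaP ~ N(5, 0.5²)` nS), sparse directed Bernoulli connectivity
  (probability `p`, uniform weight `w`), spike-triggered exponential
  synapses, exponential-Euler integration at 0.1 ms.

* **A reduced 3-unit activity-based network.** High-, medium- and
  low-excitability units (HE/ME/LE), each a fast voltage plus `h_NaP`, with
  a piecewise-linear output `f(V)` standing for firing rate and all-to-all
  coupling `w·f(V_j)`. Small enough for full fast–slow phase-plane
  analysis: cubic V-nullclines, knees (folds), fixed points, and the
  curve of knees under synaptic drive.

Analysis tools cover population spike histograms, burst segmentation and
LA/SA classification, quantal `1:N` regime summaries, inter-burst-interval
statistics, per-neuron firing modes, burst-participation clustering, and
parameter-sweep grids — all tibble-in/tibble-out with `tidy()`, `glance()`
and `autoplot()`/`plot_*()` methods.

## Worked example

Quantal regimes of the reduced network:

```r
library(mmonet)

traj <- simulate_reduced(w = 2, duration = 350000, discard = 50000)
reduced_regime(traj)
#> # A tibble: 1 × 9
#>    n_la  n_sa n_per_la ratio_label stable la_freq_hz sa_freq_hz ibi_after_la ibi_after_sa
#>   <int> <int>    <int> <chr>       <lgl>       <dbl>      <dbl>        <dbl>        <dbl>
#> 1    36   107        4 1:4         TRUE        0.120      0.358        3021.        1793.
```

One LA burst per four network events (three SA bursts between LA pairs):
the `1:4` regime, with inter-burst intervals after LA bursts (3.02 s) longer
than after SA bursts (1.79 s) because network-wide excitation pushes every
unit's nullcline knee — and hence its burst-termination point — to deeper
`I_NaP` inactivation. At `w` = 1.7, 3 and 4 the same call returns `1:5`,
`1:2` and `1:1`.

The conductance-based network, uncoupled, splits into silent, bursting and
tonic neurons by excitability:

```r
net <- build_network(n = 100, w = 0, p = 0,
                     seed_population = 1, seed_topology = 101)
sim <- simulate_network(net, duration = 50000, discard = 20000, seed_init = 201)
table(neuron_burst_stats(sim)$mode)
#>
#>  bursting   silent    tonic
#>        41       30       29
plot_raster(sim)       # raster ordered by E_L
```

Coupled (`w = 2.5, p = 0.15`), the same population synchronises into MMOs;
`population_histogram()` + `segment_bursts()` + `classify_bursts()` then
quantify the LA/SA pattern, and `heatmap_sweep()` maps regimes over
`(w, p, ḡ_NaP)`. Phase-plane geometry for any unit:

```r
find_knees(e_l = -63.5, drive = 0)
#> # A tibble: 2 × 4
#>   kind      v     h drive
#>   <chr> <dbl> <dbl> <dbl>
#> 1 left  -56.7 0.613     0
#> 2 right -34.2 0.269     0
plot_phase_plane(e_l = -63.5, drives = c(0, 0.8, 1.6))
```

Experiment configs (YAML, defaults = the published parameter tables) and a
thin CLI live in `inst/extdata/` and `inst/cli/mmonet.R`:

```sh
Rscript inst/cli/mmonet.R simulate-reduced --set network.w=3 --out out/
```

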