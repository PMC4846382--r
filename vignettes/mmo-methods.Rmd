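---
title: "Models and methods: mixed-mode oscillations in heterogeneous excitatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: mixed-mode oscillations in heterogeneous excitatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mmonet)
```

# The scientific problem

The pre-Bötzinger complex (pre-BötC), the medullary kernel of the inspiratory
rhythm, produces *mixed-mode oscillations* (MMOs): population bursts of large
amplitude (LA) recurring after a quantised number of small-amplitude (SA)
bursts, in ratios such as 1:5 or 1:2. `mmonet` implements two models of this
phenomenon and the analysis pipeline that quantifies it:

* a **100-neuron conductance-based network** of excitatory neurons whose
  intrinsic bursting rests on the persistent sodium current `I_NaP`, with
  heterogeneous excitability and sparse random synaptic coupling, and
* a **reduced three-unit activity-based network** (high-, medium- and
  low-excitability units: HE, ME, LE) amenable to fast–slow phase-plane
  analysis.

The organising idea is that LA bursts are the cycles on which the
least-excitable neurons are recruited; their slow `I_NaP` de-inactivation sets
the number of SA cycles that must pass before an LA burst can occur.

# The conductance-based network

Each neuron obeys
$$C\,\dot V = -I_{Na} - I_{NaP} - I_K - I_L - I_{SynE},$$
with fast sodium ($\bar g_{Na} m_{Na}^3 h_{Na}$), persistent sodium
($\bar g_{NaP} m_{NaP} h_{NaP}$, reversal shared with $I_{Na}$),
delayed-rectifier potassium ($\bar g_K m_K^4$), leak, and excitatory synaptic
currents (units: nS·mV = pA, so no conversion factors). Gates follow
$\tau_x(V)\dot x = x_\infty(V) - x$ with sigmoid steady states and
cosh-shaped time constants; the potassium gate uses the classical
$\alpha/\beta$ rate form. `hh_gates()` and `hh_params()` hold every constant;
the slow variable is the `I_NaP` inactivation `h_NaP`
($\tau_{max} = 6000$ ms at $-60$ mV), which terminates bursts and paces
recovery.

Heterogeneity enters through two Gaussian draws per neuron
(`build_population()`): the leak reversal $E_L \sim \mathcal N(-62, 0.93^2)$
mV — the model's proxy for excitability — and
$\bar g_{NaP} \sim \mathcal N(5, 0.5^2)$ nS. The printed "±" spreads are read
as standard deviations (the source table does not say SD versus SEM; SD is
the conventional reading for population heterogeneity). Draws are
untruncated except that a non-positive conductance (probability
$\sim 10^{-23}$) is redrawn.

Connectivity (`build_connectivity()`) is directed Bernoulli over ordered
pairs with probability `p` and uniform weight `w`, no self-edges; the
synaptic equation indexes weights asymmetrically, so no symmetry is imposed.
Every spike from neuron *j* (an upward crossing of $-35$ mV) increments the
aggregate synaptic conductance of each target *i* by
$\bar g_{SynE} w_{ji}$ (0.05 nS × weight), and the aggregate decays with
$\tau_{SynE} = 5$ ms. Tracking this single decaying state is *exactly* the
double sum over the full spike history of single-exponential kernels — no
truncation window is involved (verified against the explicit sum in the test
suite at 1e-10).

## Integration

The network is advanced by exponential Euler at `dt = 0.1` ms: every
variable with kinetics $\dot x = (x_\infty - x)/\tau$ is updated by
$x \leftarrow x_\infty + (x - x_\infty)e^{-dt/\tau}$; the membrane equation
is rewritten with $\tau_V = C/\sum g$ and $V_\infty = \sum gE / \sum g$.

One sequencing choice matters and was made deliberately: **gates are
advanced first** (their $x_\infty, \tau$ evaluated at the step-start
voltage) **and the membrane step then uses the updated gate values** in its
conductance decomposition. With all coefficients frozen at the step start
instead, the default neuron collapses to single-spike oscillations at
`dt = 0.1` ms whose period is three times shorter than the converged one —
an integration artifact, not a model behaviour. The gates-first sequencing
is accurate at the production step: the uncoupled burst period changes by
0.6% between `dt = 0.1` and `dt = 0.01`, and by <1% against an adaptive
(lsoda) reference, both asserted in the tests. Synaptic increments from
spikes detected in one step are applied at the start of the next; no
synaptic delay is modelled, and the sub-step timing is far below the 10 ms
histogram resolution of all analyses.

Initial conditions (`initial_conditions()`) are drawn per neuron:
$V \sim U(-70, -50)$ mV, $h_{NaP} \sim U(0.2, 0.8)$, fast gates at their
steady state for the drawn voltage, zero synaptic conductance. These ranges
are a package choice (the source states only "physiologically realistic
ranges"); a 20 s discard makes all reported statistics insensitive to them.
Three independent seed streams (population, topology, initial conditions)
let each ingredient be re-randomised alone.

# Burst analysis

Population activity is summarised as spikes of all neurons per 10 ms bin
(`population_histogram()`). Burst *classification* is prescribed: a burst is
LA when its peak strictly exceeds 50 spikes/bin, otherwise SA; the
heat-map/sweep pipeline instead uses >20 spikes in a 100 ms sliding window
(`classify_bursts_windowed()`). Both rules coexist deliberately and each
pipeline applies its own. Burst *segmentation*, however, is not prescribed
anywhere; `segment_bursts()` uses maximal runs of bins at or above 5
spikes/bin, merging runs separated by less than 50 ms. Both thresholds are
exposed and echoed into every artifact. A peak of exactly 50 is SA ("more
than 50" read strictly).

Quantal regimes are labelled `1:N` with `N` the modal number of burst events
from one LA onset up to the next (`regime_summary()`); an LA followed by
three SA bursts per cycle is thus `1:4`. This convention reconciles the two
published caption usages ("three SA bursts … 1:4" and "two SA bursts … 1:2")
which are mutually inconsistent under an SA-count reading; the total-events
reading satisfies both. A regime is `stable` when at least five consecutive
LA-to-LA periods agree.

Per-neuron firing modes (`neuron_burst_stats()`) group a spike train into
bursts wherever an inter-spike interval exceeds 300 ms — chosen to sit well
between intra-burst intervals (tens of ms) and burst periods (seconds) — and
label a neuron silent (no spikes), tonic (a single gap-free group), or
bursting. Participation clustering (`cluster_by_participation()`) groups
neurons with identical burst-participation bit-vectors, which isolates the
cluster active only in LA bursts.

# The reduced model

Each unit carries a fast voltage and the slow `I_NaP` inactivation:
$$C\dot V_i = -\bar g_{NaP} m_\infty(V_i) h_i (V_i - E_{Na})
             - g_L (V_i - E_{L,i})
             - \textstyle\sum_{j \ne i} w f(V_j)\, \bar g_{SynE} (V_i - E_{SynE}),$$
$$\tau_h(V_i)\,\dot h_i = h_\infty(V_i) - h_i,$$
with the piecewise-linear output $f(V)$ rising from 0 at $-50$ mV to 1 at
0 mV (`output_function()`), representing the unit's normalised firing rate.
Leak reversals $(-54.5, -59.0, -63.5)$ mV make unit 1 a fast burster (HE),
unit 2 a slow burster (ME) and unit 3 silent (LE) when uncoupled.

No integration method is prescribed for this model; the package uses
fixed-step RK4 at `dt = 0.5` ms (`simulate_reduced()`), with convergence
asserted by halving the step (<1% period change) and against lsoda. The
default initial state (all units at $-60$ mV, $h = 0.6$) is an arbitrary
point off any unstable equilibrium; a 50 s discard precedes all analysis.

Activation events are maximal intervals with $f(V) > 0.05$
(`detect_cycles()`); the threshold is a package choice — small enough to
catch every genuine activation (which reach $f \approx 0.8$), large enough
to sit clear of numerical ripple on the silent branch — and is exposed in
the config. Overlapping unit events merge transitively into network events;
an event is LA exactly when the LE unit participates.

## Phase-plane geometry

Setting $\dot V = 0$ with the synaptic drive $d = \sum_j w f(V_j)$ frozen as
a parameter gives the cubic V-nullcline in closed form
(`v_nullcline_h()`); the h-nullcline is $h_\infty(V)$. The local maximum of
the V-nullcline (left knee) is the activation threshold and the local
minimum (right knee) the burst-termination point (`find_knees()`, bracketed
golden-section refinement to $10^{-9}$ mV). Excitatory input lowers the
nullcline and its knees — fast threshold modulation — which
`curve_of_knees()` samples over drive levels. The quasi-static freezing of
`d` mirrors how the source figures draw nullclines for discrete input
levels; the decaying-input band is rendered by sampling drives.

Fixed points are intersections of the two nullclines (`fixed_points()`,
grid bracketing plus `uniroot`, residuals $<10^{-8}$), each labelled by
branch and by linearised stability (trace/determinant of the 2×2 Jacobian —
a cross-check; branch position is the primary account). A stable point on
the hyperpolarised left branch means silence; a stable depolarised point
means tonic activity; an unstable middle-branch point, surrounded by a
relaxation orbit, means endogenous bursting (`classify_excitability()`).
Near the upper end of the bursting window the two knees merge toward a cusp
and branch labels degenerate, so the stable-point dichotomy uses the voltage
level relative to the output threshold $V_{min}$ rather than the branch
label. Simulation-based classification (`classify_reduced_neuron()`) labels
a run bursting when the late-window voltage oscillation exceeds 1 mV
peak-to-peak: at the tonic end the limit cycle shrinks continuously
(supercritical Hopf), so a small amplitude cut — measured on the final half
of the window, after slowly-decaying transients — reproduces the boundary
at the scan resolution. The geometric and simulation classifications are
cross-checked against each other over scans of $[-66, -50]$ mV in the test
suite, agreeing everywhere up to at most one grid step at the boundaries.

# Study conditions and problem sizes

The generator defaults *are* the study conditions: 100 neurons,
$E_L = -62 \pm 0.93$ mV, $\bar g_{NaP} = 5 \pm 0.5$ nS, `p = 0.15`,
`w` in $[0, 5]$, 50 s simulations at `dt = 0.1` ms with the first 10–20 s
discarded; reduced-model runs of 250–350 s at `dt = 0.5` ms with 50 s
discarded. The excitability scan uses a 0.1 mV grid over $[-66, -50]$ mV
and the weight scan a 0.05 grid over $[0, 2.5]$. Heat-map sweeps in the
tests use a 3×3 sub-grid of the published parameter plane; the full-plane
sweep is available through `heatmap_sweep()` at any resolution.

# What reproduces, and what does not

The reduced model reproduces the published phenomenology exactly:
conditional bursting over $E_L \in [-59.0, -53.9]$ mV against the published
$[-59.0, -53.8]$; quantal regimes 1:5, 1:4, 1:2, 1:1 at `w` = 1.7, 2, 3, 4;
longer HE inter-event intervals after LA than after SA events; the
LE-activation ⇔ LA-burst equivalence and the knee-crossing activation rule
on every analysed cycle.

Two published claims do **not** reproduce under converged integration of
the printed equations, and the package reports its computed values rather
than adjusting anything toward the printed ones:

* **LE emergence weight.** Independent 300 s runs per weight show the LE
  unit activating from `w ≈ 1.05` (confirmed by RK4 at two step sizes and
  by lsoda; no hysteresis under a continuation scan), against a published
  onset of 1.4. The LE inter-event period is ~21 s at `w = 1.05` and falls
  below ~10 s near `w = 1.4`, so the printed onset is consistent with a
  continuously-ramped scan whose per-weight observation window is shorter
  than the LE period below `w ≈ 1.4`.
* **Large-scale composition and strong-coupling behaviour.** The printed
  network equations, integrated convergently, give an intrinsic bursting
  window of roughly $[-62.3, -61.6]$ mV, hence ~35 silent neurons in the
  default uncoupled population rather than the published 49, and SA cluster
  bursts that are less sharply synchronised than the published histograms.
  At strong coupling (`w = 3`, `p = 0.24`) recurrent excitation sustains
  network firing with `h_NaP` fully inactivated, so lowering mean
  $\bar g_{NaP}$ does not extinguish activity on the published grid. These
  are properties of the equations as printed; the published figures were
  produced by a legacy fixed-step simulator whose discretisation details
  (to which single-neuron spike shape and hence network synchrony are
  sensitive) are not recoverable from the text.

The synthetic populations emulate heterogeneity in exactly two parameters;
real pre-BötC neurons vary in many more (morphology, additional currents
such as $I_{CAN}$, $I_h$, $I_{K(Ca)}$, synaptic kinetics), rhythm in slices
depends on extracellular potassium, and no inhibitory transmission is
modelled. Passing tests therefore certify the model's internal mechanics —
not that real pre-BötC MMOs arise this way.

# Known limitations

* The two-parameter heterogeneity means neuron "excitability order" is not
  strictly the $E_L$ order: the $\bar g_{NaP}$ spread blurs mode boundaries
  by a few neurons in any realisation.
* `heatmap_sweep()` classifies loosely-synchronised cluster bursts by the
  windowed rule only; spectral measures are out of scope.
* Nullclines are drawn under frozen drive; no numerical continuation of
  periodic orbits is attempted, and tangency weights are assessed by the
  user from the exported curves.
* The CLI covers the standard pipelines; programmatic use through the
  package functions is the primary interface.
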