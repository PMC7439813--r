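---
title: "Presynaptic inhibition as a rapid stabiliser of plastic recurrent networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Presynaptic inhibition as a rapid stabiliser of plastic recurrent networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(presynstab)
```

## The scientific problem

Hebbian plasticity on recurrent excitatory synapses is a positive feedback
loop: potentiation raises firing rates, which drives further potentiation.
Homeostatic mechanisms — here the sliding modification threshold of the
BCM rule — can in principle contain this loop, but only if they act fast
enough. Experimentally observed homeostasis operates over hours to days,
far slower than what the stability analysis of recurrent networks demands.
This package models a candidate resolution: *presynaptic inhibition*
mediated by GABA~B~ receptors. GABA spilling over from inhibitory synapses
suppresses neurotransmitter release at nearby excitatory terminals within
hundreds of milliseconds, multiplicatively scaling the effective recurrent
excitation by a release factor $p \in [0, 1]$. Because inhibitory activity
rises with excitatory activity, this constitutes a fast negative feedback
loop acting directly on the quantity that destabilises the network.

The package implements three tiers of the same circuit and the experiments
connecting them:

1. **Mean-field model** (`meanfield_params()`, `steady_state()`,
   `critical_timescale()`, `simulate_meanfield()`): two coupled population
   rates with closed-form fixed points and a linear stability analysis.
2. **Rate network** (`rate_net_params()`, `build_rate_network()`,
   `simulate_rate_network()`): 1024 excitatory + 256 inhibitory rate
   neurons, fixed-indegree random connectivity, a global release factor and
   the BCM rule with sliding threshold on all E→E synapses.
3. **Spiking network** (`spiking_params()`, `build_spiking_network()`,
   `simulate_spiking()`): current-based leaky integrate-and-fire neurons
   with per-neuron GABA accumulation, neuron-specific release factors and
   minimal triplet STDP with metaplastic long-term depression.

## The mean-field model

The excitatory and inhibitory population rates follow

$$\tau_E \dot r_E = -r_E + p\,w\,r_E - \tilde w_{EI} r_I + I, \qquad
  \tau_I \dot r_I = -r_I + \tilde w_{IE} r_E - \tilde w_{II} r_I,$$

with rates rectified and saturated at $r_\max = 200$ Hz, and the release
factor relaxing towards a monotonically decreasing transfer function $g$ of
the total weighted inhibitory activity,
$\tau_p \dot p = -p + g(\tilde w_{EI} r_I)$. With the inhibitory population
at its steady state $r_I = \tilde w_{IE} r_E / (1 + \tilde w_{II})$, the
inhibition recruited per unit excitatory rate collapses into a single
constant $w_I = \tilde w_{EI}\tilde w_{IE}/(1+\tilde w_{II})$ (equal to 1
at the default weights).

For the linear transfer $g(r) = [1 - \beta r]_+$ the excitatory fixed
point solves a quadratic; `steady_state()` takes its positive root (the
negative branch never yields positive rates). Three regimes emerge:

* without presynaptic inhibition ($g \equiv 1$) the rate
  $I/(1 - w + w_I)$ diverges as the recurrence $w$ approaches $1 + w_I$;
* with linear presynaptic inhibition the rate is finite for *every* $w$
  and saturates at $1/(\beta w_I)$ as $w \to \infty$ (`asymptotic_rate()`);
* for inputs strong enough that $p$ clips to zero,
  $I > (1+w_I)/(\beta w_I)$, the rate is the recurrence-independent
  $I/(1 + w_I)$; ties at the boundary go to this branch.

### Plasticity and the critical homeostatic timescale

Recurrent excitatory weights follow the BCM rule
$\tau_w \dot w = \frac{\eta w_0}{\kappa^3} r_E^2\!\left(r_E -
\bar r_E^2/\kappa\right)$ with sliding threshold driven by a low-pass rate
estimate, $\tau_c \dot{\bar r}_E = -\bar r_E + r_E$. The effective
plasticity timescale is $\tau_\mathrm{plast} = \tau_w/(\eta w_0) = 60$ s at
the defaults. Because the fast variables ($r_E$, $r_I$, $p$; tens of
milliseconds to half a second) equilibrate much faster than $w$ and
$\bar r_E$ (tens of seconds and up), the five-dimensional system reduces to
two slow variables on the fast manifold; `rate_sensitivity()` is the
derivative $dr_E/dw$ of that manifold, and `simulate_meanfield(mode =
"reduced_2d")` integrates the reduced system directly.

Linearising around the target-rate fixed point
$(r_E, \bar r_E) = (\kappa, \kappa)$ yields eigenvalues whose real parts
change sign at

$$\tau_c^\mathrm{crit} \;=\; \frac{\tau_w}{\Psi\kappa^4}, \qquad
  \Psi \;=\; \frac{\eta w_0}{\kappa^3}\,
  \frac{g(w_I\kappa)}{I - \frac{g'(w_I\kappa)}{g(w_I\kappa)}
        \,w_I\kappa\,(\kappa + w_I\kappa - I)}.$$

`psi_constant()`, `linearised_eigenvalues()` and `critical_timescale()`
implement this; the boundary case (zero real part) is conservatively
reported as unstable with a flag. Substituting $g \equiv 1$, $g' \equiv 0$
gives $\tau_c^\mathrm{crit} = \tau_\mathrm{plast}\, I/\kappa$: at the
reference operating point ($I = 0.5$ Hz, $\kappa = 5$ Hz) homeostasis must
run **ten times faster** than plasticity itself. With linear presynaptic
inhibition at $\beta = 0.05$/Hz the critical timescale rises from 6 s to
58.67 s — essentially the plasticity timescale:

```{r critical}
mf0 <- meanfield_params(transfer = transfer_spec("none"))
mf1 <- meanfield_params(transfer = transfer_spec("linear", beta = 0.05))
c(no_presyn = critical_timescale(mf0), beta_0.05 = critical_timescale(mf1))
```

An algebraic note: reordering the fixed-point condition at $r_E = \kappa$
gives $g(w_I\kappa)\,w\,\kappa = \kappa + w_I\kappa - I$, which converts
the expression above into the equivalent form
$\tau_c^\mathrm{crit} = \frac{\tau_\mathrm{plast}}{g(w_I\kappa)}
(I/\kappa - \kappa\, w\, g'(w_I\kappa)\, w_I)$ — the package asserts both
routes agree to machine precision, and that both reproduce the $g\equiv1$
limit exactly. The sign of the $I$ term in the substitution is fixed by
this consistency requirement.

## The rate network

The full network uses fixed indegrees (exactly $cN_E = 100$ excitatory and
$cN_I = 25$ inhibitory inputs per neuron, sampled without replacement, no
self-connections), per-synapse weights carrying the $1/(cN)$ scaling, noisy
background input to excitatory neurons redrawn each Euler step from
$\mathcal N(I, (0.1 I)^2)$ (a `"static"` per-neuron draw is available as a
configuration switch), and a *global* release factor driven by
$r_I^\mathrm{tot} = \sum_{j=1}^{N_I} w_{EI} r_I^j$. Since
$r_I^\mathrm{tot}$ is $1/c$ times the population-level quantity, the
transfer slope is multiplied by $c$ (`scale_transfer()`), making network
and mean-field transfer identical.

Two normalisation choices matter and are verified by tests:

* **Plasticity scaling.** The per-synapse BCM increment carries the same
  $1/(cN_E)$ indegree normalisation as the weights themselves, so the mean
  population weight $cN_E\langle w_{ij}\rangle$ obeys the population-level
  rule exactly. Without this factor, network plasticity would run $cN_E =
  100\times$ faster than the mean-field analysis, and the network could
  never match the theory it is initialised from.
* **Initialisation.** Networks start at the analytic fixed point:
  $r_E = \kappa$, $p^* = g(w_I \kappa)$, and per-synapse weights
  $w^* = (1 + w_I - I/\kappa)/(p^* c N_E)$, multiplied by ±10%
  multiplicative uniform jitter (set `init_jitter = 0` for a homogeneous
  network, which then replicates the mean-field model to $10^{-6}$ —
  a property test). Weights are clipped to $[0, 10\,w^*]$ with $w^*$
  frozen at its initial value.

With the homogeneous settings the network *is* the mean-field model;
heterogeneity (weight jitter, per-neuron noise) is what produces the broad
rate distributions and neuron turnover above the critical timescale.

### Dynamical regimes and their operational definitions

`classify_stability()` labels the final window (default the last 20%) of a
run: `"target"` when the population mean is within 10% of $\kappa$ *and*
the across-neuron SD stays below $\kappa$; `"runaway"` when the mean
exceeds $0.9\,r_\max$; `"fluctuating-low"` otherwise. The 10% tolerance
and window length are not dictated by the model; they were chosen to
separate the three regimes cleanly and are exposed as arguments.

Two empirical properties of the model are worth stating explicitly because
they shape the experiment protocols:

* **Runaway is transient under the literal dynamics.** Once rates pin at
  $r_\max$, the sliding threshold $\bar r^2/\kappa$ grows toward
  $r_\max^2/\kappa \gg r_\max$, and as soon as $\bar r$ exceeds
  $\sqrt{\kappa r_\max} \approx 31.6$ Hz the BCM rule depresses
  catastrophically, wiping the weights within milliseconds and leaving a
  frozen low-rate state. A sustained 200 Hz state is algebraically
  impossible in this model. Runaway runs therefore terminate at detection
  (`stop_on_runaway`: population mean at $\ge 0.95\,r_\max$ for 5
  sustained seconds), and "final rate" for such runs means the rate at
  termination — which is the saturated ceiling.
* **Slow instabilities take tens of minutes to express.** With presynaptic
  inhibition the maximal growth rate above threshold is
  $\Psi\kappa^4/(2\tau_w) \approx 1/117$ s⁻¹, so runs shorter than ~20
  simulated minutes label near-critical points as `"target"`. Scan grids
  in the packaged experiments put their unstable points well above
  threshold, and the headline bracket comparisons rest on grid points
  whose labels are insensitive to run length.
* **Relaxation oscillations at extreme recurrence.** For $w \gtrsim 8$
  (at $\beta = 0.05$) the 0.5 s lag of the release factor
  Hopf-destabilises the fast fixed point; the network then oscillates
  around the bounded steady state and its time-averaged rate exceeds the
  analytic curve, although it never pins at $r_\max$. Network/mean-field
  curve comparisons are therefore asserted on the dynamically convergent
  range ($w \le 5$), the saturation bound on the analytic curve itself.

## The spiking network

Membrane potentials follow
$\tau_m \dot V_i = V_R - V_i + I_E + I_I + I_\mathrm{ext}$ with threshold
$V_T = -50$ mV, reset $V_R = -70$ mV and a 5 ms absolute refractory period
(hence a 200 Hz ceiling). The linear membrane equation is advanced with a
4th-order Runge–Kutta step (currents held constant within the 0.1 ms
step); synaptic filters, GABA levels and release factors use forward
Euler, matching the integration scheme of the reference simulators for
this model class.

**Spike-delivery convention.** A spike through weight $w$ increments the
target's filtered current by $w$, so a projection's mean current is
$w \times \text{rate} \times \tau$; with the default weights this puts the
mean external drive at 20 mV — the fluctuation-driven regime. GABA uses
the complementary convention: each inhibitory spike deposits
$A_\mathrm{GABA}/\tau_I$ with $A_\mathrm{GABA} = 1/(cN_I)$, which makes
the time-averaged GABA level $C_\mathrm{GABA}$ numerically equal to the
afferent inhibitory rate in Hz — so the spiking $\beta$ lives on the same
scale as the rate-model $\beta$ (a property test asserts
$\langle C\rangle \approx r_I$ and the linearity
$\langle p_i\rangle = 1 - \beta\langle C_i\rangle$ away from clipping).
Release factors relax with $\tau_p = 300$ ms towards
$[1 - \beta C_\mathrm{GABA}]_+$ and gate excitatory input *onto excitatory
cells* at delivery time; inputs onto inhibitory cells are ungated.

**Plasticity.** The minimal triplet STDP rule: a presynaptic spike
depresses by $A^-_i(t)\, z^-_i$ and increments the presynaptic trace
$z^+_j$; a postsynaptic spike potentiates by $A^+ z^+_j z^\mathrm{slow}_i$
(the slow trace read before its own increment) and increments the two
postsynaptic traces. Metaplasticity scales depression with the square of a
per-neuron rate detector,
$A^-_i = \frac{A^+\tau^+\tau^\mathrm{slow}}{\tau^-\kappa}\bar r_i^2$,
where each own spike adds $1/\tau_c$ to $\bar r_i$ (so $\bar r$ is a rate
in Hz). At $\bar r = \kappa$ this definition balances potentiation and
depression exactly for independent Poisson firing at $\kappa$ — the
Monte-Carlo drift test. The trace conventions (decay-first, increments
after the plasticity reads) are the standard minimal-triplet choices; the
rule's full derivation lives in prior literature, and the detector is
initialised at $\kappa$ (configurable), consistent with starting the
network near its operating point. Weights are hard-clipped to
$[0, w_\max]$; synapses absent at initialisation never appear.

Within a simulation step the order is: decay of currents, GABA, release
factors and traces; RK4 membrane update and spike detection; external
Poisson delivery; plasticity (LTP reads, then LTD reads, then trace
increments); recurrent spike delivery.

## Experiments

* `scan_recurrence()` sweeps the mean E→E weight with plasticity off, for
  any of the three tiers (the mean-field version attaches the analytic
  curve). Without presynaptic inhibition the spiking curve jumps
  discontinuously to near the refractory ceiling; with $\beta = 0.1$ it
  rises gradually and stays far below it.
* `scan_homeostasis()` runs the plastic network across a $\tau_c$ grid,
  labels each point, and reports the bracket (largest `"target"`,
  smallest other) next to the analytic prediction.
* `rate_summary()` condenses per-neuron traces into a histogram, the mean
  temporal autocorrelation, and a turnover index — the Spearman rank
  correlation of per-neuron mean rates between two windows (rank-based
  because the above-critical rate distribution is long-tailed).
* `run_scenario()` exposes figure-level presets (`fig1_rate_curves`,
  `fig2_homeostasis_scan`, `fig3_input_sensitivity`, `fig4_spiking`,
  `s1_variants`, `s4_transfer_functions`, `s5_eigenvalues`) writing CSV +
  JSON artifacts with the fully resolved configuration logged.

## Numerical choices

* Forward Euler at 1 ms for the rate tiers (0.1 ms, RK4 membrane for the
  spiking tier); rates clipped to $[0, r_\max]$ and $p$ to $[0,1]$ every
  step.
* Closed forms are used wherever they exist. Numeric steady states use a
  safeguarded bracketing root solve on the fixed-point residual (tolerance
  $10^{-12}$); plain damped fixed-point iteration is provably
  non-convergent here for large recurrence (the iteration map's slope at
  the fixed point grows linearly in $w$), so the circuit-motif variants,
  which need a genuinely two-dimensional solve, use adaptively damped
  iteration whose relaxation halves on divergence.
* Background noise in the rate network is generated by a dedicated
  xoshiro256++ / Box–Muller stream seeded from the R RNG: statistically
  equivalent to the base generator and reproducible from `set.seed()`,
  at a fraction of the per-step cost.
* All randomness flows from one top-level seed through named substreams
  (connectivity, jitter, background noise, external Poisson spikes), so
  changing one consumer never perturbs the others.

## Problem sizes in the packaged checks

The test suite runs the full-size rate network (1024 + 256 neurons) with
10-simulated-minute grid points for the critical-timescale comparison and
15-minute runs for the maintenance and runaway checks; the spiking sweeps
use a reduced 1000 + 250 network at 10 s per grid point. These sizes were
chosen so the entire suite exercises every tier end-to-end at full
parameter fidelity; the mean-field results are size-independent, and the
reduced spiking network keeps the external drive at the full-size
operating point by retaining all 2000 external units.

## What the synthetic conditions do and do not show

All inputs are self-generated (random connectivity, Gaussian background
noise, Poisson external spikes) under the stationary parameter tables the
models define. Passing tests therefore demonstrate internal consistency of
the three tiers and of theory versus simulation — not robustness to
structured stimuli, correlated inputs, conductance-based synapses,
synaptic delays, spatially organised connectivity, or interneuron
diversity, none of which are modelled. The release factor is a
population-level (rate tier) or neuron-level (spiking tier) scalar;
synapse-specific release modulation and short-term plasticity are outside
scope. Above the critical timescale the fluctuating regime is reported
descriptively (rate statistics, turnover); no attempt is made to
characterise it as chaotic.
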