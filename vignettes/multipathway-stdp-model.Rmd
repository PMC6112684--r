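---
title: "A multi-pathway, activity-dependent calcium model of STDP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-pathway, activity-dependent calcium model of STDP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(calstdp)
```

## The model

`calstdp` simulates spike-timing-dependent plasticity (STDP) at a synapse
where several independent calcium-dependent signaling pathways — for
example an endocannabinoid (eCB) pathway and an NMDA-receptor (NMDAR)
pathway at the cortico-striatal synapse — jointly determine the change in
synaptic strength, and where each pathway's LTP and LTD mechanisms can
*inactivate* once the total calcium that has flowed through the synapse
exceeds a mechanism-specific level.  The distinguishing consequence is that
the plasticity measured after 10 pairings can differ in sign and mechanism
from the plasticity measured after 100, so an STDP "curve" at a fixed
pairing number is an incomplete description of the synapse.

Each pathway $\alpha$ carries a bistable efficacy $\rho_\alpha \in [0,1]$:

$$\mathrm{d}\rho_\alpha =
  \frac{1}{\tau}\Big[-\rho_\alpha(1-\rho_\alpha)(\rho_* - \rho_\alpha)
  + \gamma^p_\alpha (1-\rho_\alpha)\,A^p_\alpha(t)
  - \gamma^d_\alpha \rho_\alpha\,A^d_\alpha(t)\Big]\mathrm{d}t
  + \frac{\sigma}{\tau}\sqrt{A^p_\alpha(t) + A^d_\alpha(t)}\;\mathrm{d}W_\alpha$$

(see *Noise convention* for why the diffusion carries $1/\tau$).  The gates
$A^x_\alpha(t) \in \{0,1\}$ open while the instantaneous calcium
concentration $c(t)$ exceeds the mechanism's threshold
$\theta^x_\alpha$.  The cubic term makes $\rho = 0$ (depressed) and
$\rho = 1$ (potentiated) stable and $\rho_*$ unstable, so after a protocol
every efficacy settles into one of the two basins and the outcome is
summarized by the switch fractions $U_\alpha$ (depressed-start ensemble
found potentiated) and $D_\alpha$ (potentiated-start ensemble found
depressed).

Calcium is a sum of decaying exponentials (time constant $\tau_{Ca}$):
every postsynaptic spike adds an impulse $C_{post}$, every presynaptic
spike an impulse $C_{pre}$ delayed by $D$ (possibly negative).  The package
never grids the trace: `ca_value()`, `ca_integral()` and `ca_time_above()`
are exact closed forms, and the simulator consumes them exactly (see
*Numerics*).

### Activity-dependent thresholds

Each mechanism's threshold depends on the cumulative calcium
$I(t) = \int c(s)\,\mathrm{d}s$, a simple proxy for receptor
desensitization, calcium-store depletion and homeostasis (conceptually
related to the sliding threshold of the BCM rule, but local to one synapse
and driven by calcium rather than firing rate):

* **piecewise** (the default): $\theta^x_\alpha = \theta^x_{\alpha,0}$
  while $I(t) < \mu^x_\alpha$, and $+\infty$ afterwards — the mechanism
  switches off for good;
* **exponential**: $\theta^x_\alpha = \theta^x_{\alpha,0} +
  \exp\!\big((I(t) - \mu^x_\alpha)/\epsilon\big)$, a smooth version in
  which inactivation completes over a window of order $\epsilon$ of
  cumulative calcium.

In the fully-relaxing regime (low pairing frequency) each pairing
contributes a fixed amount $A\,\tau_{Ca}$ of cumulative calcium ($A$ = the
summed impulse amplitudes of one pairing), so an inactivation level $\mu$
corresponds to a pairing count $n = \lceil \mu / (A\,\tau_{Ca}) \rceil$
(`inactivation_pairing()`).  For the cortico-striatal preset this gives the
model's three regimes at 1 Hz: eCB-LTP active through pairing 14
($\mu^p_e = 6$), NMDAR-LTP through pairing 74 ($\mu^p_n = 32$), eCB-LTD
throughout.

**Pairing-resolution bookkeeping.**  In the piecewise model the simulator
freezes each mechanism's inactivation state at pairing boundaries: a
mechanism stays responsive through the pairing during which $I$ crosses
$\mu$ and is off from the next pairing on.  This matches the per-pairing
reading of $\mu$ above and makes the stochastic simulator and the
mean-field solution (whose phases change at whole pairing times $T n$)
agree exactly.  Evaluating the threshold against the instantaneous integral
instead would truncate part of the crossing pairing's drive — about 17% of
pairing 14's LTP for the cortico-striatal preset — which shifts ensemble
means by several ensemble standard deviations at regime boundaries.  The
exponential model, which has no sharp crossing, uses the instantaneous
integral.

### The macroscopic readout

Experiments measure one number per protocol — the relative change in
response size — produced by many synapses with an unknown initial mix of
potentiated and depressed states.  The package follows the ratio readout:
the macroscopic change of pathway $\alpha$ is $H(U_\alpha / D_\alpha)$ with
the sigmoid

$$H(r) = a + \frac{b}{1 + e^{-s(r - d)}},$$

whose coefficients are fixed in closed form by $H(0) = \mathrm{LTD}^\star$,
$H(1) = 1$ and $H(\infty) = \mathrm{LTP}^\star$ (`h_coefficients()`;
requires $e^s > \Delta = (\mathrm{LTP}^\star - \mathrm{LTD}^\star) /
(\mathrm{LTP}^\star - 1)$).  Because the ratio is scale-free, the ensemble
size cancels and no assumption on the initial potentiated fraction is
needed.  Pathways are conditionally independent given the calcium trace, so
the total change is the product $\prod_\alpha H(U_\alpha/D_\alpha)$
(`total_change()`).  Two conventions close the definition:

* $U = D = 0$ (nothing switched): the pathway contributes a neutral factor
  1 — the unique choice that leaves an unstimulated synapse unchanged;
* $D = 0 < U$: the ratio is $+\infty$ and the factor is
  $\mathrm{LTP}^\star$, forced by the $H(\infty)$ boundary condition.

The second convention makes $H$ *cliff-like*: a single potentiated synapse
out of 1000, with none depressed, already yields the maximal factor.  This
is a property of the readout, not of the implementation, and it is the
lens through which several results below should be read.

Pharmacological blockade of a pathway is represented by dropping its factor
from the product (`total_change(sim, included = ...)`); the underlying
efficacies are unchanged, so blockade analyses reuse the same simulation.

### Noise convention

The published form of the gated noise term is typographically ambiguous,
but the closed-form coefficients of the mean-field solution pin it down:
the homogenized Ornstein–Uhlenbeck diffusion is written in the same
$X/\tau$ pattern as the drift coefficients, i.e.
$\sigma_e = \sigma\sqrt{\eta^d + \eta^p}/\tau$ per period.  The package
therefore uses

$$\text{noise on } \mathrm{d}\rho =
  \frac{\sigma}{\tau}\sqrt{A^p(t) + A^d(t)}\;\mathrm{d}W,$$

i.e. the variance grows at rate $\sigma^2/\tau^2$ (per gate) while gates
are open.  The alternative reading $(\sigma/\sqrt{\tau})\sqrt{A^p + A^d}\,
\mathrm{d}W$ was checked quantitatively and rejected: with the
cortico-striatal parameters it makes the ensemble spread so large that
potentiated stragglers survive into the silent regime, the readout cliff
saturates, and the characteristic no-plasticity window around 40 pairings
disappears entirely.  Under the adopted convention the closed-form solution
reproduces all three regimes.

### Mean-field solution

At low pairing frequency calcium relaxes to baseline between pairings,
every pairing opens each gate for the same exact durations $\eta^p, \eta^d$
(computed by `ca_time_above()` on a single-pairing trace), and the
linearized dynamics is an Ornstein–Uhlenbeck process with
piecewise-constant coefficients: per phase
$\alpha = -(\Gamma^p + \Gamma^d)/\tau$, $\beta = \Gamma^p/\tau$ with
$\Gamma^x = \gamma^x \eta^x / T$, and diffusion variance rate
$\sigma^2(\eta^p + \eta^d)/(T\tau^2)$; phases split at the inactivation
times $T n_x$ (`ou_phases()`).  Mean and variance propagate exactly across
any number of phases (`ou_mean_var()`), and the switch probabilities are
Gaussian tail probabilities through the error function
(`ou_switch_probs()`).  `analytic_stdp()` packages this as a drop-in
replacement for `simulate_stdp()`.

By default the analytic engine rounds its probabilities to the measurement
resolution of the reference ensemble (`round(p * N)/N`): the closed form
stands in for an N-synapse experiment, and a probability below $1/(2N)$ is
not observable in one.  Pass `resolution = Inf` for raw probabilities.

The mean-field validity precondition is enforced: if the calcium residual
between pairings exceeds $10^{-6}$ of one pairing's impulse sum the
analytic functions refuse and direct to the simulator.  No high-frequency
closed form is attempted.

**Accuracy boundary.**  The linearization drops the cubic term.  Between
gate openings the cubic drift slowly pushes efficacies away from $\rho_*$
(at most $\approx 0.05/\tau$ per second), which biases the true ensemble
mean by up to $\sim$0.01–0.02 over a 100 s protocol.  Wherever the mean
sits within a few ensemble standard deviations of $\rho_*$ at readout —
the ensemble SD is only 0.003–0.007 under the adopted noise convention —
the closed form and the simulator can disagree on whether a handful of
synapses switch, and the readout cliff can turn that into a large
difference in total change.  Concretely, at $\Delta t = -20$ ms and 100
pairings the analytic NMDAR switch probability is 0.018 while the simulator
(and a linearized simulator run confirms the cubic term is the whole
explanation) gives exactly 0, i.e. totals of 3.475 vs 1.0.  Away from such
knife edges the two engines agree to Monte-Carlo accuracy.

## Parameters

All times are seconds internally; config files accept `ms`/`s` suffixes.
The tunable parameters, with the cortico-striatal defaults:

| parameter | meaning | default (cortico-striatal) |
|---|---|---|
| $C_{pre}, C_{post}$ | calcium impulse per pre-/postsynaptic spike (dimensionless concentration) | 7, 17.1 |
| $\tau_{Ca}$ | calcium decay constant | 18 ms |
| $D$ | presynaptic calcium influx delay | 10 ms |
| $\gamma^p_\alpha, \gamma^d_\alpha$ | LTP/LTD rates (dimensionless, scaled by $1/\tau$) | eCB: 290, 250; NMDAR: 50, 0 |
| $\theta^x_{\alpha,0}$ | base calcium thresholds | eCB: 6 (LTP), 13.5 (LTD); NMDAR: 5.8 |
| $\mu^x_\alpha$ | cumulative-calcium inactivation levels (concentration·s) | eCB-LTP: 6; NMDAR-LTP: 32; others $\infty$ |
| $\tau$ | efficacy time constant | 165 s |
| $\rho_*$ | bistability midpoint | 0.5 |
| $\sigma$ | noise intensity | 1 |
| $\mathrm{LTP}^\star, \mathrm{LTD}^\star, s$ | readout caps and slope | 3.475, 0.55, 0.7 |
| $\epsilon$ | exponential-threshold sharpness | 1 |

The six shipped presets (`stdp_preset()`) are YAML configs under
`inst/extdata/presets/`, documented field by field, and `read_model_config()`
accepts user edits of the same schema.  The value 3.475 is a decimal-comma
reading (3,475) — consistent with $\mathrm{LTD}^\star = 0.55$ and with the
observed plasticity magnitudes — and the remaining unassigned scalar of the
readout block (0.7 for the cortico-striatal column) is the sigmoid slope
$s$, verified by $H(0) = \mathrm{LTD}^\star$ and $H(1) = 1$.  Scenario 3's
corrupted delay entry is set to 10 ms, shared with scenario 2, with which it
shares every other calcium parameter.

## Protocols

`stdp_protocol()` builds pair and triplet protocols.  Pairing $k$ anchors
its (first) presynaptic spike at $k/F$ — the anchor is a free convention
that only shifts the global time origin — and $\Delta t = t_{post} -
t_{pre}$ offsets the postsynaptic spike ($\Delta t < 0$: post before pre).
Triplets follow $\Delta t_i = t_{post} - t_{pre,i}$ (pre–post–pre,
$\Delta t_1 < \Delta t_2$) and $\Delta t_i = t_{post,i} - t_{pre}$
(post–pre–post, $\Delta t_1 > \Delta t_2$); coincident-spike diagonals are
excluded by the constructors.  At frequency $F$ only timings modulo $1/F$
are distinguishable, so sweeps fold $\Delta t$ into $(-1/2F, 1/2F]$
(`fold_dt()`).  Frequencies above 40 Hz emit a validity warning: there the
calcium trace stops relaxing at all and the model's outcome is dominated by
the readout caps rather than by spike timing.

## Numerics

* **Integration.**  Euler–Maruyama with the reference discretization:
  window $[-1, 101]$ s and 102000 steps ($\mathrm{d}t \approx 1$ ms;
  204000 steps for the scenario presets) for the standard 100-pairing, 1 Hz
  protocol; for other protocols the window end defaults to 1.5 s (rounded
  up) after the last spike and the step count keeps the same steps-per-second.
* **Exact gate occupancy.**  Within each Euler step the simulator uses the
  *exact* open time of every gate, from closed-form threshold crossings of
  the calcium trace, rather than evaluating the Heaviside gate at the step
  midpoint.  Gate durations of 4–30 ms per pairing would otherwise be
  quantized at the 1 ms step, a bias of order 2–3% in the drive per pairing
  — several ensemble standard deviations at regime boundaries.  With exact
  occupancy, halving the step changes switch fractions by less than
  Monte-Carlo error even at the sharpest transition (a tested invariant).
  The noise increment of a step has variance $(\sigma/\tau)^2$ times the
  step's open time.  The exponential threshold model, whose gate condition
  varies continuously within a step, uses midpoint evaluation.
* **Ensembles and classification.**  Two ensembles of N synapses (default
  1000) start at $\rho = 0$ and $\rho = 1$; both see the same calcium but
  independent noise, per pathway.  Snapshots are classified against
  $\rho_*$, which equals basin-of-attraction classification because the
  post-protocol dynamics is noiseless and bistable.  Per-pairing snapshots
  are taken just before the next pairing's first spike; all pairing counts
  therefore share one realization and are correlated, exactly as when one
  long protocol is probed at increasing pairing numbers.  Efficacies are
  never clipped: the cubic drift restores excursions outside $[0,1]$.
* **Ties and boundaries.**  Gate activation is closed at equality
  ($c \ge \theta$), a measure-zero choice fixed for reproducibility.
  Exponential-threshold overflow is short-circuited to an inactive gate
  beyond $700\,\epsilon$ of excess cumulative calcium.
* **Randomness.**  Everything derives from one integer seed
  (`sim_settings(seed = )`); grid drivers give run $i$ the seed
  `seed + i - 1`, and the frequency sweep gives replicate $r$ of point $i$
  the seed `seed + (i-1) * replicates + r - 1`.  Identical seeds give
  byte-identical outputs.

## Phase classification

`classify_phases()` is a deterministic surrogate for classifying
establishment curves by eye: pairing counts with total change above
$1 + \delta$ are potentiating, below $1 - \delta$ depressing; runs shorter
than `min_run` pairings merge into their longer neighbor; the label
concatenates the surviving polarities (`PD`, `PP`, `PPD`, `PDP`, ...).  The
defaults $\delta = 0.1$ and `min_run = 5` are this package's choices — the
original classification was visual and published only category percentages
— and both are exposed on the API and the CLI and recorded in output
metadata.  The same band constants (`plasticity_bands`: LTP above 1.15, LTD
below 0.90, neutral within $\pm 0.1$) operationalize all figure-level
statements in the test suite.  Default triplet grids span ±35 ms with 20
values per axis, configurable and logged; the tests use coarser grids.

## What the presets emulate, and what passing tests do not show

The presets *are* the study conditions: deterministic spike timing, a
shared single-compartment calcium trace, exactly two initial efficacy
states, stationary parameters.  Real recordings add jittered spike times,
heterogeneous synapse parameters, graded initial states, GABAergic
switching of the STDP polarity, and rundown — none of which the generator
emulates.  Passing tests therefore validate the model's internal
consistency and its agreement with the published regime structure, not its
fit to any particular recording.  Known behavioral boundaries, measured
with this package and worth knowing before use:

* The fitted cortico-striatal pre-post LTD window extends to about
  $\Delta t = +55$ ms; timing-independence ("no plasticity for large
  $|\Delta t|$") holds from roughly ±60 ms outward.
* Scenario 3 at 1 Hz / 100 pairings carries a narrow LTP pocket near
  $\Delta t = +5$ ms (total change 2.0): pathway A's LTP and LTD are almost
  exactly balanced there (ensemble mean $0.5008$ after 100 pairings) and
  the readout cliff amplifies the sliver of potentiated synapses.  Both
  engines agree on it; it is a property of the printed scenario-3
  parameters under this package's conventions.
* Scenario 2's 30 Hz LTP, the discriminating experiment against
  scenario 1, expresses at pairings 17–22 depending on the folded timing —
  a tight race between the ensemble mean crossing $\rho_*$
  ($t \approx 0.65$–$0.75$ s) and the pathway-A LTP inactivating
  ($\approx$ pairing 22).  By pairing 22 every folded timing shows LTP;
  at exactly 20 pairings the pre-post side may not yet.  Scenario 1 shows
  no LTP at any tested frequency or count.
* The scenarios' symmetric LTD at 100 pairings / 1 Hz occupies roughly
  $|\Delta t| \lesssim 15$ ms; outside the LTD lobe nothing switches and
  the total change is exactly 1.

## Problem sizes used by the shipped tests

The test-suite simulations use the reference ensemble (N = 1000) for the
regime, agreement, blockade and scenario checks, 11-point timing grids at
5 ms spacing, three pairing-count probes (13, 40, 100), N = 10$^4$ for the
distributional Kolmogorov–Smirnov check of the linearized ensemble, and
smaller toy models (N = 200) for structural unit tests — sizes chosen so
the whole suite exercises every claim at full ensemble resolution while
remaining a routine local run.  Monte-Carlo comparisons use three binomial
standard errors (with the factor $\sqrt 2$ when two independent runs are
compared), and cross-engine totals use three SDs of a parametric binomial
bootstrap (K = 400) of the analytic probabilities.
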