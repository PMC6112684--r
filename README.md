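# calstdp

Multi-pathway, activity-dependent calcium models of spike-timing-dependent
plasticity (STDP), for computational neuroscientists who want to ask not
just *what* plasticity a pairing protocol induces, but *how it is
established* as the number and frequency of pairings grow.

Classical calcium-based synapse models assume one plasticity mechanism
with fixed thresholds, and therefore predict that plasticity emerges
monotonically with the number of pairings.  Real synapses — the
cortico-striatal synapse is the motivating example — use several
signaling pathways (endocannabinoid, NMDAR) whose LTP/LTD mechanisms
activate at different calcium levels and *inactivate* after enough
cumulative calcium has passed.  The result is non-monotonic plasticity:
an early endocannabinoid LTP for ~10–25 post-pre pairings, a silent
window around 40, and a slower NMDAR LTP re-emerging past ~75 pairings,
with eCB LTD building up monotonically on the pre-post side.

## The model

Each pathway α carries a bistable efficacy ρ_α ∈ [0, 1]:

    dρ_α = (1/τ) [ −ρ_α(1−ρ_α)(ρ∗−ρ_α)
                   + γᵖ_α (1−ρ_α) Θ[c(t) − θᵖ_α(∫c)]
                   − γᵈ_α ρ_α     Θ[c(t) − θᵈ_α(∫c)] ] dt
           + (σ/τ) √(Θᵖ + Θᵈ) dW_α

where c(t) is a shared sum-of-exponentials calcium trace (impulses C_pre
after each presynaptic spike, delayed by D, and C_post after each
postsynaptic spike; decay τ_Ca), and each threshold θˣ_α jumps to infinity
(or grows as θ₀ + exp((∫c − μ)/ε)) once the cumulative calcium exceeds the
mechanism's inactivation level μˣ_α.  Ensembles of N synapses started
depressed and potentiated yield switch fractions U_α and D_α, and the
measured change in synaptic strength is the product over pathways of the
sigmoid readout H(U_α/D_α), with H(0) = LTD★, H(1) = 1, H(∞) = LTP★.
A piecewise Ornstein–Uhlenbeck mean-field solution reproduces the
simulated switch fractions in closed form at low pairing frequency.
See the vignette (`vignettes/multipathway-stdp-model.Rmd`) for the full
account, including the noise-convention analysis and known accuracy
boundaries.

## Worked example

```r
library(calstdp)

model    <- stdp_preset("corticostriatal")
protocol <- stdp_protocol("pair", dt = -0.010, freq = 1, n_pairings = 100)
sim      <- simulate_stdp(model, protocol, sim_settings(seed = 1))

subset(as.data.frame(tidy(sim)), pairing %in% c(13, 40, 100))
#>  pairing pathway     U D     h total_change
#>       13     eCB 0.825 0 3.475        3.475
#>       13   NMDAR 0.000 0 1.000        3.475
#>       40     eCB 0.000 0 1.000        1.000
#>       40   NMDAR 0.000 0 1.000        1.000
#>      100     eCB 0.000 0 1.000        3.475
#>      100   NMDAR 0.992 0 3.475        3.475

classify_phases(total_change(sim))
#> <phase_label> PP (delta=0.1, min_run=5)
#>   polarity  from    to
#> 1 neutral      1    12
#> 2 P           13    25
#> 3 neutral     26    66
#> 4 P           67   100
```

Reading the numbers: at 13 post-pre pairings (Δt = −10 ms) 82.5% of the
depressed-start eCB ensemble has potentiated and none has depressed, so
the eCB factor saturates at H(∞) = LTP★ = 3.475 while the NMDAR pathway is
still silent — the early eCB-LTP.  By pairing 40 the eCB-LTP has
inactivated (it switches off at pairing 14; the stragglers decay) and
nothing is potentiated: no plasticity.  By pairing 100 the slow NMDAR
pathway has potentiated (99.2% switched) — the late NMDAR-LTP.  The
establishment curve is classified `PP`: potentiation, silence,
re-potentiation, with boundaries at pairings 13/25 and 67.

The same objects drive the rest of the toolkit: `analytic_stdp()` (closed
form), `total_change(sim, included = "NMDAR")` (pathway blockade),
`stdp_heatmap()`, `frequency_sweep()`, `triplet_map()` (experiment
drivers), `autoplot()` on any of them, and `read_model_config()` /
`write_model_config()` for user-edited YAML parameter files (six presets
ship in `inst/extdata/presets/`).

A command-line interface wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec","calstdp",package="calstdp"))')" \
  simulate --preset corticostriatal --dt -10ms --freq 1 --npairings 100 --seed 7 --out run1
```

writes `run1.csv` (long-format results) and `run1.json` (a manifest with
the resolved model, protocol, settings and seed, sufficient to reproduce
the run bit-for-bit).

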