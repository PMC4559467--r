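# drivernet

Balanced-state networks of leaky integrate-and-fire neurons can
*self-organize*: when excitatory-excitatory (E-E) and
inhibitory-excitatory (I-E) synapses follow spike-timing-dependent
plasticity (STDP) and each excitatory cell's total incoming excitatory
weight is held fixed by a homeostatic rule, an initially homogeneous
random network develops a long-tailed weight distribution, and a small
group of **driver neurons** — cells whose mean outgoing E-E weight sits
in the extreme upper tail — emerges, fires far above the population
rate, forms a densely connected subnetwork, and can trigger
population-wide rate elevations with as few as two synchronous spikes.
`drivernet` implements this model end to end for computational
neuroscientists: the clock-driven simulator, the plasticity rules, the
experiment protocols, the spike-train and weight statistics, and the
mean-field theory that explains the mechanism.

## The model in brief

Subthreshold dynamics
`τ_m dV/dt = −(V − E_L) + I_e − I_i` with τ_m = 20 ms, E_L = −60 mV,
threshold −50 mV, reset −60 mV, refractory period 2 ms; current-based
exponential synapses (τ_e = 5 ms, τ_i = 10 ms) calibrated so a
unit-weight EPSP peaks at 0.16 mV and a unit-weight IPSP at −2.25 mV.
The reference network is 4000 excitatory + 1000 inhibitory cells,
connection probability 0.02, all cells depolarized by a constant 11 mV.
Plasticity: additive all-to-all STDP at E-E synapses
(A₊ = 10⁻³, A₋ = 1.05·A₊, τ = 20 ms, amplitudes scaled by the maximal
weight 20), Hebbian inhibitory STDP at I-E synapses (A₊/A₋ = 4, maximal
weight 5), and postsynaptic weight normalization every 100 ms (or,
alternatively, slow synaptic scaling `dw/dt = −γ(ν−ν₀)w²`).

The mean-field module carries the closed-form results: the delay one
inhibitory spike imposes on the next postsynaptic spike,
`d_w = w/(ν₀ ΔV)`; the stationary inhibitory weight
`w_stat = ν₀ τ ΔV log(A₊/A₋)`; the resulting partially-compensating
rate map; and a semi-analytic estimate of the average STDP drift on an
excitatory synapse as a function of its weight, whose single
negative-to-positive sign change is the instability that lets
fast-firing cells turn into drivers.

## Worked example

```r
library(drivernet)

# plastic transient at reduced scale: 800 E + 200 I, p = 0.02,
# 30 minutes of biological time (about 1.5 minutes of wall clock)
spec <- experiment_spec(seed = 7)
res  <- run_transient_to_equilibrium(spec)

w <- res$topology$edges$ee$w
mean(w)                                  # 0.9999965  (pinned at 1)
var(w)                                   # 7.598745   (grown from 0)
mean((w - mean(w))^4) / var(w)^2 - 3     # 16.92      (heavy tail)

drv <- detect_drivers_percentile(res$topology, 0.005)
drv$drivers                              # 129 190 244 266
rates <- firing_rates(res$spikes, c(res$state$t - 1e5, res$state$t))
mean(rates[drv$drivers + 1])             # 29.9 Hz
mean(rates[1:800])                       # 11.8 Hz
```

The normalization pins the mean E-E weight at exactly 1 while the
variance grows by orders of magnitude; the four cells in the top 0.5%
of mean outgoing weight fire at about 2.5 times the population rate.
On the full 4000-cell network the same pipeline reproduces the ~5 Hz
asynchronous irregular state (ISI CV ≈ 0.87) and, after the ~5 h
transient, the long-tailed weight distribution whose middle part is
fitted by `fit_powerlaw_mle()`.

A command-line front end is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/drivernet.R", package="drivernet"))')" \
    reduced --seed 7 --outdir run1
```

with subcommands `simulate`, `stimulate`, `analyze`, `theory`,
`reduced` and `ensemble`.

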