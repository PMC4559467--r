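---
title: "Model and methods: self-organizing balanced networks in drivernet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: self-organizing balanced networks in drivernet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`drivernet` simulates a classical balanced-state network of leaky
integrate-and-fire (LIF) neurons with current-based synapses.  The
subthreshold membrane potential obeys

$$\tau_m \frac{dV}{dt} = -(V - E_L) + I_e^{syn} - I_i^{syn},$$

with $\tau_m = 20$ ms and leak $E_L = -60$ mV.  When $V$ crosses the
threshold $V_{thres} = -50$ mV a spike is emitted and $V$ is clamped at
$V_{reset} = -60$ mV for the refractory period $\tau_{ref} = 2$ ms.
Synaptic currents are exponential traces: each presynaptic spike of
weight $w$ increments the postsynaptic trace by $w$, and the trace decays
with $\tau_e = 5$ ms (excitation) or $\tau_i = 10$ ms (inhibition).  The
current normalization factors are $c_e = 1$ mV and $c_i = -9$ mV, so a
unit-weight excitatory synapse produces an EPSP peaking at $\approx 0.16$
mV and a unit-weight inhibitory synapse an IPSP peaking at $-2.25$ mV
(`psp_peak_amplitude()` gives the closed form).

A sign remark: the printed membrane equation combined with a *negative*
$c_i$ would, read literally, make inhibition depolarizing.  The package
resolves the sign through the unambiguous IPSP calibration ($-2.25$ mV at
$w = 1$): the inhibitory current enters with hyperpolarizing effect and
magnitude $|c_i| = 9$ mV.  Similarly, the maximal EPSP implied by linear
scaling of the unit calibration is $20 \times 0.157 = 3.15$ mV; we treat
the unit-weight calibrations as authoritative.

The reference network has 4000 excitatory (E) and 1000 inhibitory (I)
cells, each ordered pair of distinct cells connected independently with
probability $p = 0.02$ in all four classes (E-E, E-I, I-E, I-I),
mono-synaptically.  Every cell is driven by a constant depolarization of
11 mV (relaxation target $E_L + 11$ mV, i.e. 1 mV below threshold), which
puts the static network into the asynchronous irregular regime at a mean
excitatory rate near 5 Hz with ISI coefficients of variation near 1.  An
equivalent per-cell Poisson drive (2200 Hz through unit-weight synapses,
matching the mean current of the constant drive) is available for
experiments that need input noise.

## Plasticity

Three rules act simultaneously:

* **Excitatory STDP (E-E)** — all-to-all exponential-kernel pairing.
  A pairing with $t_{post} - t_{pre} > 0$ potentiates by
  $A_+ e^{-\Delta t / \tau_+}$; a pairing with $\Delta t \le 0$ (zero lag
  included) depresses by $A_- e^{\Delta t/\tau_-}$.  For the additive rule
  $A_+ = 10^{-3}$, $A_- = 1.05 A_+$, $\tau_\pm = 20$ ms, and the
  amplitudes are multiplied by the maximal weight ($w_e^{max} = 20$) to
  obtain their effective values.  The kernel integral is slightly
  negative, so uncorrelated activity depresses.
* **Inhibitory STDP (I-E)** — the same Hebbian kernel shape with
  $A_- = 10^{-3}$, $A_+ = 4 A_-$ (positive integral, $w_i^{max} = 5$):
  inhibition onto strongly firing cells grows, a self-limiting negative
  feedback because each inhibitory PSP delays the next postsynaptic spike.
* **Homeostasis (postsynaptic, E-E)** — either multiplicative weight
  *normalization* every 100 ms, rescaling each excitatory cell's incoming
  E-E weight vector so its sum equals in-degree $\times 1$ exactly, or slow
  synaptic *scaling* $dw/dt = -\gamma (\nu - \nu_0) w^2$
  ($\gamma = 10^{-6}$, $\nu_0 = 0$, one step per 50 ms, rate estimated over
  a trailing 100 s window).

E-I and I-I synapses stay fixed.  Weights are clipped to
$[0, w^{max}]$ after every event.  Online traces implement the all-to-all
pairing exactly (the test suite checks equality with a brute-force
double-loop over all spike pairs); within one time step the postsynaptic
trace is incremented before depression-on-pre is applied, so coincident
spikes take the depression branch.

Starting from uniform weights ($w = 1$ everywhere), the plastic network
develops a long-tailed E-E weight distribution whose mean is pinned at 1
by the normalization while its variance grows.  A small set of *driver
neurons* — the top 0.5% of excitatory cells by mean outgoing E-E weight,
or alternatively all cells more than 3 SD above the mean — accumulates
disproportionately strong outgoing synapses, fires well above the
population rate, and forms a more densely connected subnetwork than
random cell groups.

## Numerical scheme

The `(V, g_e, g_i)` subsystem is linear, so each step of length
`dt = 0.1` ms uses the exact propagator (matrix exponential in closed
form); for an isolated neuron the trajectory matches the analytic
solution to better than $10^{-6}$ mV, and simulated single PSPs match the
closed-form peak within 1%.  Thresholds are checked after the update;
emitted spikes are delivered to their targets at the end of the step, so
synaptic transmission takes effect one step later (an effective delay of
`dt`, which is also the default $\tau_{syn}$ of the mean-field trigger
term).  Refractory cells integrate synaptic traces normally; only their
potential is clamped.  Burst stimulation adds a strong constant current
(default 1000 mV equivalent) during 0.5 ms pulses separated by 2 ms gaps,
guaranteeing one threshold crossing per pulse from any subthreshold
state.

The simulation core is C++ (via Rcpp) with lazily decayed eligibility
traces; all randomness flows through R's RNG, so every run is
bit-reproducible given its seed.  `derive_seed()` hashes a master seed
with a component tag so that, e.g., regenerating the drive does not
perturb the topology stream.

## Experiment protocols and their scales

`run_transient_to_equilibrium()` drives the plastic network until the
Kolmogorov-Smirnov distance between consecutive E-E weight snapshots
(default spacing 300 s at reduced scale, 600 s at full scale) falls below
0.01 or the duration budget ends, with a divergence guard at a sustained
100 Hz mean rate.  The full-scale transient takes roughly five hours of
biological time; the package's *reduced study condition* — used
throughout the test suite — is 800 E + 200 I cells at $p = 0.02$ with 30
minutes of biological time.

The reduced condition preserves the qualitative self-organization (long
tails, high-rate driver cells, denser driver subnetworks) but not every
full-scale contrast, and the vignette is explicit about which is which:

* At 800 cells the mean E in-degree is 16 and cells share a much larger
  fraction of inputs than at full scale, so spike correlations are
  several-fold stronger and the network sits at a higher rate
  ($\sim 12$ Hz instead of 5 Hz).  Noise-driven weight divergence then
  occurs in *every* topology variant.  Two full-scale contrasts are
  consequently not reproduced at this scale, and their acceptance checks
  document that as expected failures: the no-inhibitory-STDP twin is not
  strictly less clustered, and the homogeneous-in-degree network's weight
  distribution is concentrated relative to its twin only by a factor
  $\sim 2$, not the near-delta concentration seen at full scale.
* Homogeneous-in-degree experiments use the full-scale in-degrees
  (80 excitatory, 20 inhibitory per cell) rather than scaled-down ones:
  this keeps every cell's input statistics — and hence the
  fluctuation-driven $\sim 5$ Hz regime — at reference values, and makes
  the 10%-pruning experiment meaningful (10% of 4 inhibitory synapses
  would round to zero removed).
* The fan-in competition setup (80 Poisson inputs onto one cell, ten of
  them fast) uses a 9 mV background drive: the postsynaptic relaxation
  target is then 1 mV below threshold, as in the balanced network, and
  input-driven (causal) pairings decide the competition.  With a
  suprathreshold drive the cell fires regardless of its inputs and every
  plastic synapse decays — fast inputs fastest — which inverts the
  outcome; this is a regime boundary worth knowing about.

Stimulation probing (`run_driver_stimulation()`) freezes the weights,
runs an exponentially distributed washout (mean 2 s) before each trial,
requires all targets to be non-refractory at onset, and reports the
trial-averaged excitatory PSTH and the post/pre rate ratio over 100 ms
windows.

## Mean-field theory

For a reduced pair of integrate-and-fire cells joined by an inhibitory
delta synapse under the Hebbian inhibitory rule (nearest-neighbour
pairing), one inhibitory spike of weight $w$ delays the next postsynaptic
spike by $d_w = w / (\nu_0 (V_{thres} - V_{rest}))$, and the averaged
update has the unique root

$$w_{stat}(\nu_0) = \nu_0 \, \tau \, (V_{thres} - V_{rest}) \,
  \log(A_+/A_-),$$

depending only on the amplitude ratio (4 here).  The package verifies
both the algebraic root (residual $< 10^{-12}$) and the simulated pair:
with the effective amplitudes the weight relaxes with a time constant of
roughly $\Delta V / (\nu_{inh} A_-) \approx 400$ s, so the simulated
grids use runs of a few thousand seconds; stationary weights then agree
with the closed form to within a few percent, with the expected
saturation near the weight cap at high rates.  The resulting rate map
$\nu(\nu_0) = \nu_0 / (1 + \tau \nu_{inh} \log(A_+/A_-))$ compensates
increased drive only partially — the contraction property that lets
under-inhibited cells keep firing faster.

For an excitatory delta synapse of frozen weight $w$ between two
Poisson-driven LIF cells, the expected STDP change per presynaptic spike
is estimated as

$$\langle \Delta w \rangle(w) = \nu \int_0^\infty P(T)\,
  \Delta w\big(T, \Delta t_{2B}(w)\big)\, dT
  \;+\; P_{fire}(w)\, A_+ e^{-\tau_{syn}/\tau_+},$$

where $T$ is the postsynaptic ISI (modelled as inverse-Gaussian),
$\Delta t_{2B}(w) = \Delta r / (r (r + \Delta r))$ is the average
backward shift of the next postsynaptic spike computed from the fitted
linear rate increase $\Delta r(w)$, and
$P_{fire}(w) = \int_{V_{thr}-w}^{V_{thr}} P(V)\, dV$ is the probability
that a presynaptic spike triggers the postsynaptic cell directly.  The
leading factor $\nu$ makes the pair term a per-presynaptic-spike
quantity (length-biased interval sampling).  $P(V)$ can be taken from
simulation or from the stationary diffusion approximation
(`membrane_distribution()`), and the two agree to KS distance $< 0.05$
under the reference drive; `lif_rate_diffusion()` supplies the matching
first-passage rate.

Two practical notes from validating this estimate against the
frozen-weight Monte Carlo (`run_two_neuron_excitatory_dw()`):

* Under the reference input (1650 delta synapses at 1 Hz, 0.5 mV each)
  the postsynaptic cell is *drift*-driven: $\nu \approx 49$ Hz with ISI
  CV $\approx 0.26$.  An inverse-Gaussian shape $\lambda$ in the range
  $[0.5/\nu, 1/\nu]$ implies CV $\ge 1$ and misrepresents this; the
  estimate itself varies by under 5% of its scale across that range, but
  a moment-fitted $\lambda = \mu^3/\mathrm{Var}(T)$ (returned as
  `lambda_fit`) is the recommended choice.
* The estimate reproduces the qualitative structure exactly — negative
  drift at $w = 0$ and a single sign change to positive drift, the
  instability behind driver formation — and its trigger term matches the
  Monte Carlo trigger statistics to a few percent.  Its *curve-level*
  accuracy in this fast-firing regime is $\sim 30\%$ at large $w$:
  the formula omits the depression pairing of the triggering spike
  itself ($-P_{fire} A_- E[e^{-T/\tau}]$, available via
  `trigger_depression = TRUE`) while also over-crediting near-threshold
  pairings through its uniform-position assumption; the two biases
  partially cancel and neither variant tracks the Monte Carlo within its
  sampling error everywhere.  The corresponding acceptance check is left
  failing by design rather than widened.

## Statistics

Driver detection ranks excitatory cells by mean outgoing E-E weight
(cells without outgoing E-E edges are excluded; ties break towards lower
ids).  Shuffle surrogates permute weights over the fixed edge set,
destroying plasticity-induced correlations while preserving the weight
multiset; clustering shows as the original top quantiles exceeding the
surrogate band.  Synchrony-triggered averages use 1 ms bins, collapse
events closer than one half-window to the first, and drop events whose
window leaves the recording.

The power-law fitter performs continuous maximum likelihood for a
truncated density $C x^{-\alpha}$ on $[x_{min}, x_{max}]$, with the top
5% of the sample trimmed first (the fitted $x_{max}$ is the trim bound)
and $x_{min}$ chosen by KS minimization over a quantile grid; it reports
the (negative) density exponent, both bounds, and the KS distance.
Parameter recovery on synthetic Pareto samples is within $\pm 0.05$ at
$n = 10^5$.  The log-normal fitter is plain MLE on logs with zeros
excluded and reported.

## Reproducibility and file formats

Spike rasters are TSV (`time_ms`, 0-based `neuron_id`, with a header
comment carrying the population sizes and duration); topologies are
MatrixMarket coordinate files, one per connection class with 1-based
class-local indices, plus a plain-text sidecar with sizes and optional
torus positions.  Explicit zero weights survive the round trip.  A run
manifest (YAML) stores the configuration snapshot, master and derived
seeds and MD5 checksums of all outputs.  The command-line front end in
`inst/cli/drivernet.R` exposes `simulate`, `stimulate`, `analyze`,
`theory`, `reduced` and `ensemble` subcommands over these functions.

## Known limitations

* No conduction delays beyond the one-step transmission, no multapses,
  no conductance-based synapses, homogeneous neuron parameters.
* The partly and fully multiplicative STDP variants implement standard
  functional forms (additive LTP with weight-proportional LTD; both
  factors weight-dependent) and are validated qualitatively only.
* Full-scale claims (power-law exponent $-1.92$ with
  $x_{min} = 0.205$, the 25 Hz driver-group rate, the
  $12.14 \pm 2.65$ driver-subnetwork connection count) require the
  5-hour, 5000-cell transient and are supported through configuration
  but not re-verified by the test suite; the reduced condition checks
  the qualitative counterparts listed above.
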