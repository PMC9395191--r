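---
title: "Inhibitory switch dynamics in a two-layer cortical rate model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inhibitory switch dynamics in a two-layer cortical rate model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microswitch)
```

## The model

`microswitch` implements a firing-rate model of a layered visual-cortex
microcircuit with eight neuronal populations: pyramidal cells (PYR) and
three inhibitory interneuron classes — parvalbumin- (PV), somatostatin-
(SST) and vasoactive-intestinal-polypeptide-positive (VIP) cells — in each
of a superficial (L2/3) and a deep (L5) layer. Each population is a single
Wilson–Cowan rate unit:

$$\tau \frac{dr}{dt} = -r + \varphi(W r + I_{\mathrm{ext}}) + \eta,
\qquad \varphi(x) = \frac{a\,x}{1 - e^{-x/b}},$$

where $r$ is the vector of population rates (Hz), $\tau$ the per-population
time constants (ms), $W$ the signed effective connectivity matrix
(row = target, column = source, so circuit input is $Wr$ and silencing a
cell type's outputs zeroes its column), $I_{\mathrm{ext}}$ the external
drive (Hz) and $\eta$ i.i.d. Gaussian noise of standard deviation
$\sigma$. The transfer $\varphi$ rectifies smoothly: it vanishes for
strongly negative input, passes through $ab$ at $x = 0$ (the removable
singularity, evaluated by its limit) and grows linearly with slope $a$ for
large input. The whole matrix is multiplied by a global coupling scalar
$G$, which stands in for the unknown absolute population sizes behind each
empirically measured pairwise weight; the interesting dynamical regimes of
the bundled circuit live at $G$ of order $10^2$.

### Parameters and defaults

| parameter | meaning | default | unit |
|---|---|---|---|
| `tau` | population time constant | 10 (all populations) | ms |
| `a` | transfer slope | 1 | – |
| `b` | transfer threshold scale | 1 | Hz |
| `sigma` | rate-noise SD | 0.01 | Hz |
| `dt` | Euler step | 0.1 | ms |
| `G` | global coupling | sweep variable | – |
| PYR drive | constant external input | 5 | Hz |

The flat 10 ms default for `tau` is a neutral placeholder: population time
constants are data, not theory, and cell-type-specific values can be
passed as a named vector. The experiments that probe time-constant
dependence (`time_constant_sweep()`) hold three classes at 10 ms and vary
the fourth. A constant 5 Hz drive to PYR cells keeps the LFP proxy
readable even when inhibition is strong; it is applied by every experiment
unless stated otherwise.

### Numerical scheme

Integration is forward Euler at `dt = 0.1` ms, implemented in compiled
code. The noise enters the discrete update exactly as written above —
inside the $dt/\tau$ increment, one i.i.d. draw per population per step,
with **no** $\sqrt{dt}$ rescaling. At the reference step this is a
well-defined discrete process; users who want step-size-invariant noise
can set `sqrt_dt_noise = TRUE` in `model_params()` for the Euler–Maruyama
convention. Initial rates are zero unless a warm start is supplied. Rates
are not clipped at zero by default: $\varphi \ge 0$ and linear decay keep
noise-free trajectories non-negative, and at $\sigma = 0.01$ stochastic
excursions below zero are of order $10^{-3}$ Hz. If any rate leaves the
finite range (possible with strong recurrent excitation) the simulation
raises a structured `microswitch_divergence` condition reporting the
blow-up time.

Recorded traces hold block means over each recording interval (default
1 ms, i.e. a 1 kHz trace): the block mean acts as an anti-alias boxcar for
the spectral analysis. The exact terminal state is kept separately so warm
starts are not affected by the averaging.

## Connectivity construction

`build_corrected_matrix()` turns raw pairwise tables — connection
probability and mean PSP amplitude over morphologically defined cell
types, plus per-type prevalence — into the 8×8 effective matrix:
element-wise product of amplitude and probability; sign assignment by
source class; each interneuron source row weighted by its relative
prevalence; all inhibitory rows scaled by 0.2 (pyramidal cells outnumber
interneurons roughly five to one); morphological types merged onto the
eight populations by summing (basket + chandelier → superficial PV;
basket + shrub + horizontally elongated → deep PV; bitufted → VIP with
superficial targets, bipolar → VIP with deep targets). Summing applies to
both source and target subtypes: each merged population is a single rate
unit, so inputs onto its subtypes accumulate. Prevalence is applied per
morphological type before merging, which is equivalent to applying a
per-class factor after merging and makes the synthetic decomposition
exactly invertible. The full matrix is used as built — weak connections
are never masked.

Raw tables are oriented source-rows × target-columns (the natural
orientation of pairwise recording tables); the build transposes to the
model's target-row convention at the end. The corrected matrix CSV
round-trips bit-exactly (17 significant digits).

## The synthetic circuit

When the empirical tables are not supplied, `generate_matrix()` builds a
surrogate matrix carrying the structural motifs the analysis depends on:

* recurrent PV inhibition is the strongest entry of the matrix, deep
  stronger than superficial;
* recurrent SST connections are entirely absent;
* SST is mutually inhibitory with both PV and VIP in each layer — the two
  winner-take-all substrates of the switch;
* strong descending PYR excitation (superficial → deep);
* translaminar SST projections (deep → superficial by default; the
  ascending direction can be enabled, and the translaminar experiments
  default to driving the deep layer so the default direction carries the
  effect);
* VIP output confined to its functional layer, with a weak VIP → PV
  connection alongside the dominant VIP → SST projection;
* sparse random background weights on the remaining permitted entries
  (seeded; motif entries are deterministic).

The default magnitudes were calibrated once, before the test suite was
frozen, to place the circuit in the oscillatory, switch-capable regime for
$G \in [100, 500]$ with all time constants equal: a PYR–PV loop satisfying
the oscillation condition $\sqrt{w_{EI} w_{IE}} > (w_{II} + w_{EE})/2$ at
saturated transfer slopes (so the PV/VIP-dominated state carries a visible
gamma rhythm), recurrent PYR excitation just below the stability bound
$w_{EE} < w_{EI} w_{IE} / w_{II}$ (so strong coupling does not explode),
and an SST pathway strong enough to contain and eventually dominate the
circuit as $G$ grows. These defaults are a calibration of the generator,
committed as the package fixture (`inst/extdata/`, file name prefixed
`synthetic_`); they are not empirical data, and none of the quantitative
spectral values obtained on this fixture should be read as predictions for
the empirical circuit. The generator also emits a decomposed set of raw
tables whose `build_corrected_matrix()` output reproduces the generated
matrix exactly, so the whole correction pipeline is exercised without the
empirical supplement.

## LFP proxy and spectra

The LFP of each layer is approximated by its PYR population rate. Spectra
are estimated with DPSS (Slepian) multitapers — time-bandwidth product 3,
5 tapers — on non-overlapping 2048-sample segments of the 1 kHz trace,
averaged over tapers, segments and trials, restricted to 1–250 Hz,
smoothed with a 5-bin moving average and normalised to unit power over the
band. Segmented averaging (rather than tapering one 20 s record) keeps the
taper eigenproblem small and trades frequency resolution (~0.5 Hz, ample
for peaks at 10–150 Hz) for variance reduction. The first 500 ms of each
trial are discarded as transient. Each segment is demeaned, so the DC
component never masquerades as low-frequency power.

A "visible oscillation peak" is operationalised as a local maximum of the
normalised spectrum that (i) lies at or above 10 Hz, (ii) is the maximum
of its ±7-bin neighbourhood, (iii) exceeds 1.5× the band-median power, and
(iv) exceeds 1.15× a wide (±100-bin) moving-average background. Rule (iv)
distinguishes genuine resonance bumps from the smoothly decaying
colored-noise spectrum that any leaky rate unit produces: points on a
monotone shoulder do not rise above their own local trend, while real
peaks — even broad high-gamma bumps — do. Reliable rejection of noise-only
spectra needs the trial averaging the protocols prescribe (~15 or more
trials); with a handful of trials, estimator wiggles can sporadically pass.
All four thresholds are configurable; they are an interpretation of
"visible", not measured quantities.

## Switch metrics

Input–response curves are traced with warm-started noise-free sweeps:
at each input value the circuit settles for 2 s and the terminal rates
initialise the next grid point, ascending then descending (the descending
branch starts from the high-input state). Warm starting is what makes
coexisting attractors observable.

Ultrasensitivity is quantified by fitting the Hill equation
$y(x) = c + d\,x^n / (k^n + x^n)$ to the SST response curve by
least squares, with the amplitude $d$ signed (negative for the decreasing
SST curves — the data are never mirrored, so $n$ keeps its meaning). The
fit is multi-started over $n \in \{0.5, 1, 2, 4, 8, 16\}$ with box
constraints ($k$ within the swept range ×[0.01, 100], $n \in (0, 50]$,
$|d| \le 10\times$ the response range); flat or poorly fit curves return a
quality flag rather than an error. Raw rates are fitted, not normalised
ones. Hysteresis $h$ is the summed absolute difference between the
ascending and descending SST curves over the grid, reported per layer and
summed: the wording of "the SST cells in superficial and deep layers" is
ambiguous between the two, so both are emitted.

On the bundled circuit the VIP→SST switch develops hysteresis at
$G \approx 150$ while the PV→SST switch stays purely ultrasensitive until
$G \approx 650$: VIP, lacking self-inhibition, holds SST down once it has
won, whereas driven PV is self-limited by its own strong recurrent
inhibition. The Hill exponent grows monotonically with $G$ for both
switches and pegs at the fit bound once the transition is effectively
discontinuous.

## Experiment battery

Every experiment is a registered protocol (`list_protocols()`,
`run_protocol()`) returning tidy tables with full seed provenance; a thin
command-line wrapper (`inst/cli/microswitch`) drives the registry from
YAML configs. Defaults follow the reference protocol — 50 trials × 20 s,
$\sigma = 0.01$, rates averaged over the full duration — and every size is
an argument. The test suite and the acceptance script run reduced sizes
(typically 8–16 trials × 8 s, G grids of 4–5 points, 2 Hz input steps),
chosen so the qualitative claims they check are stable under the seed;
the methods are identical at full size.

Notable defaults decided here:

* `time_constant_sweep()` applies no extra SST drive, so its low-input
  state is the spontaneous SST-dominated regime in which the PYR–SST loop
  is active (an SST time constant can only influence a rhythm SST
  participates in). Its high-input state (VIP drive 12 Hz at $G = 300$)
  sits just past the switch point, where the PV-dominated gamma is most
  visible.
* `translaminar_propagation()` defaults to $G = 100$, where the opposite
  layer's PYR population is near threshold and translaminar release is
  measurable.
* The "SST-enhanced" background is +5 Hz to both SST populations; the
  VIP/PV background states are +40 Hz to the respective populations in
  both layers.
* Feedforward/feedback input-weight vectors are user configuration, not
  package constants: no empirical defaults are shipped, and
  `input_weighted_drive()` refuses to run without a vector.

## What the synthetic fixture does and does not show

Passing tests on the generated matrix demonstrate that the machinery —
correction pipeline, integrator, spectral estimator, switch metrics,
experiment protocols — reproduces the qualitative phenomenology that
follows from the motif structure: rise-then-fall of the spontaneous peak
frequency with $G$; slow/strong rhythms under PV silencing versus
fast/weak rhythms under SST silencing; monotone growth of $n_H$ with $G$;
hysteresis appearing above a coupling threshold, earlier for the VIP
switch than the PV switch; a frequency jump between SST- and
PV/VIP-dominated states that persists with all time constants equal, with
power changing in the opposite direction; role inversion when the PV and
SST self-connections are exchanged; and translaminar state propagation
dominated by the SST projection. Absolute rates, frequencies and onset
couplings depend on the weights and therefore differ from what the
empirical tables would give; nothing here validates those numbers. Two
further caveats: in the strongly SST-dominated high-$G$ states of this
fixture the PYR populations can be driven to effective silence, where the
LFP proxy carries only noise; and in the swapped-self-connection circuit
VIP drive suppresses SST and PYR but leaves PV near its zero-input rate
rather than below it — both are weight-dependent details, not properties
of the method.

## Worked example

```{r example, eval = FALSE}
library(microswitch)

C <- default_circuit()          # calibrated synthetic 8x8 matrix, G = 1
check_motifs(C)

# spontaneous activity and LFP peaks across coupling
res <- spontaneous_g_sweep(C, G_values = c(50, 100, 250, 500),
                           duration = 8000, n_trials = 8, seed = 1)
res$peaks

# the VIP -> SST switch at G = 300
sw <- switch_sweeps(C, G_values = 300, switch = "vip",
                    input_grid = seq(0, 60, by = 2))
sw$fits          # Hill parameters per layer
sw$hysteresis    # h per layer and total
```
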