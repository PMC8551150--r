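---
title: "Models and methods behind oscmotifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oscmotifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscmotifs)
```

oscmotifs simulates cortical-like circuits of three cell classes — excitatory
regular-spiking cells (RS, pyramidal-like), fast-spiking interneurons (FS,
PV-basket-like) and low-threshold-spiking interneurons (LTS, SOM-Martinotti-
like) — across every wiring pattern the LTS population can adopt, and
characterizes the oscillatory regime each (motif, input) combination settles
into. This vignette explains the model, the analysis pipeline, the free
parameters and the design decisions, so results can be interpreted and the
package extended.

## Neuron model

Each cell follows the two-variable quadratic integrate-and-fire dynamics

$$\frac{dV}{dt} = 0.04V^2 + 5V + 140 - U + I, \qquad
  \frac{dU}{dt} = a\,(bV - U),$$

with a reset: when $V \ge 30$ mV the cell spikes, $V \leftarrow c$ and
$U \leftarrow U + d$. $V$ is in mV, time in ms; currents are dimensionless.
Both derivatives are evaluated at the pre-step state and advanced by one
forward-Euler step of 0.2 ms (no sub-stepping); spike detection happens after
the update, and the reset is applied before any observer reads the state —
except the LFP sample, which sees spiking neurons at the 30 mV threshold
value (configurable via `lfp_clip`).

Cell-type parameters (see `default_cell_types()`):

| type | a | b | c | d | $\tau_\text{syn}$ (ms) | w (mean ± SD) |
|------|------|------|-------|-------|-----|---------|
| RS   | 0.020 | 0.20 | $-65 + 15r^2$ | $8 - 6r^2$ | 2 | $1 \pm 0.5$ |
| FS   | U(0.10, 0.18) | U(0.15, 0.20) | $-65$ | 2 | 3 | $-2 \pm 1$ |
| LTS  | U(0.020, 0.025) | U(0.20, 0.25) | $-65$ | 2 | 6 | $-2 \pm 1$ |

The RS heterogeneity ($r \sim U(0,1)$, i.e. Beta(0.5, 1) for $c$ scaled to
$[-65, -50]$ and Beta(1, 0.5) for $d$ scaled to $[2, 8]$) is the classic
squared-uniform construction that interpolates between regular spiking and
chattering behaviour. Initial conditions are $V_0 \sim U(-80, -70)$ mV and
$U_0 = bV_0 + d$. The additive $d$ term in $U_0$ is deliberate (it matches
the procedure the model family documents); because $U$ relaxes toward $bV$
within a few hundred milliseconds of burn-in it has no effect on analysed
dynamics. The conventional $U_0 = bV_0$ is available via
`init_state(..., u0_rule = "bv")`.

## Synapses and connectivity

A presynaptic spike at time $t_s$ contributes
$w\,H(t - t_s - t_\text{delay}) \exp(-(t - t_s - t_\text{delay})/\tau)$ to
each of its targets, with a global 1 ms delay (a 5-step buffer at
dt = 0.2 ms, initialized to zero) and a decay constant set by the
*presynaptic* type: 2 ms for RS (AMPA-like), 3 ms for FS and 6 ms for LTS
(GABA-like, slower for Martinotti-type synapses). The simulator implements
this as one recursively decaying trace per presynaptic type per target; a
unit test proves the recursion equal to direct kernel convolution.

Connectivity is random without spatial structure. Directed type-pair
probabilities (post row, pre column): RS ← RS/FS/LTS 5/30/40%; FS ←
10/30/20%; LTS ← 10/20/0%. LTS cells never touch each other, and autapses
are excluded (the standard convention; the probability tables are silent on
the diagonal). Weights are drawn independently per synapse from the
presynaptic type's normal distribution, untruncated — a small fraction of
"inhibitory" draws are positive, faithful to the stated distribution;
`clip_sign = TRUE` is available. Full circuits have 800 RS + 100 FS + 100
LTS cells; the two-cell circuits have 800 RS + 200 of one interneuron type.

## The 20 motifs

All motifs keep the four RS/FS connections (RS→RS, RS→FS, FS→RS, FS→FS).
Motif I is the two-cell RS-FS circuit and motif II the two-cell RS-LTS
circuit (RS→RS, RS→LTS, LTS→RS). The 18 three-cell motifs cross three
factors: the LTS input regime (external drive only / local RS→LTS excitation
only / both), the LTS inhibition target ({FS}, {RS} or {RS, FS}), and the
presence of FS→LTS inhibition. `enumerate_motifs()` numbers them
column-major (regimes run down each column) with columns ordered
({FS}, no FS→LTS), ({FS}, with), ({RS}, with), ({RS,FS}, with),
({RS,FS}, no), ({RS}, no). This ordering pins the motifs that are
unambiguous from their described dynamics — IV/V and VII/VIII are the
LTS→FS disinhibition motifs without/with external drive, IX and XII the
external-only motifs with FS→LTS — while the remaining numerals are a
convention. The numeral ↔ topology map is data, not code: edit the list
returned by `enumerate_motifs()` (or its JSON form from `motifs_to_json()`)
to re-map numerals, and build arbitrary topologies directly with
`motif_spec()`.

## External inputs and noise

Every neuron receives an independent Poisson spike train through the same
synaptic kernel with $C = 1$, $w = 1$, $\tau = 2$ ms. Counts are drawn per
0.2 ms bin (exact at any rate, unlike Bernoulli thinning); the canonical
input grid spans 0–5000 Hz in 250 Hz steps for the RS and FS populations.
Two defaults are free choices, fixed once and exposed in the configuration:

* **External LTS drive.** Motifs with external LTS input receive a fixed
  2000 Hz Poisson drive — comfortably above the LTS activation threshold
  (≈1250 Hz for an isolated cell) and in the middle of the grid scale. The
  regime boundaries of LTS-driven behaviours shift with this choice; all
  LTS-drive-dependent analyses in this package state their rate explicitly.
* **Noise.** $I_\text{noise} = I_\text{offset} + I_t(t)$ with the per-step
  part $I_t \sim N(0, 1)$ at every step for every neuron, and the static
  per-neuron offset drawn from $N(0, 1)$ — the offset's scale is otherwise
  unconstrained, and matching the per-step SD keeps both noise sources
  comparable.

Piecewise-constant schedules (`drive_spec(..., schedule = )`) add rate or
current offsets to one population on half-open windows, supporting
step-current switching protocols.

## Simulation and LFP

`run_simulation()` integrates 2300 ms at dt = 0.2 ms; analysis functions
discard the first 300 ms. Currents accumulate in a fixed order — recurrent
synaptic traces, then background drive, then noise — and enter the voltage
equation additively. The LFP proxy is the mean membrane voltage over **all**
neurons, with spiking neurons clipped at 30 mV in that sample; the raw
pre-reset overshoot is available with `lfp_clip = FALSE`. Everything is a
pure function of the seed: cell parameters, wiring, weights, initial
conditions and noise offsets come from R's RNG, and the per-step Poisson and
Gaussian streams from a dedicated compiled RNG (xoshiro256++), both seeded
with the same integer. Repeats derive child seeds from a master seed so that
repeat *r* keeps its connection pattern and noise across drive conditions —
the protocol that makes input-grid maps comparable.

## Spectral analysis

The post-burn-in LFP is low-pass decimated to 500 Hz (all analysis bands lie
at or below 150 Hz; an 8-pole zero-phase anti-alias filter at 80% of the
target Nyquist precedes subsampling) and its power spectral density is
estimated with a single full-window multitaper: NW = 3, five DPSS tapers
computed in-package from the standard tridiagonal commuting eigenproblem and
cached. Peaks are the PSD argmax over the full analysis range (2–150 Hz),
the low band (2–30 Hz) and the high band (30–150 Hz); ties break toward the
lower frequency.

Phase-amplitude coupling uses the weighted phase-locking factor: (1) the
low-band phase signal — zero-phase 2nd-order Butterworth 2–30 Hz, mean
subtraction, Hilbert transform, normalized to unit norm; (2) the high-band
envelope — zero-phase 4th-order Butterworth 30–150 Hz, mean subtraction,
Hilbert magnitude over the analytic signal's norm; (3) the absolute inner
product of the two, bounded in [0, 1] by Cauchy–Schwarz. PAC is only
reported when both band peaks carry at least 1 dB/Hz (10·log10 of the PSD in
mV²/Hz — the LFP's natural units; the asynchronous-regime noise floor sits
well below this while clear oscillations sit well above, so the absolute
reference is usable as stated), the high peak exceeds 40 Hz, and the high
peak is not within 10% of twice the low peak (the harmonic exclusion needs
an explicit tolerance; 10% is narrow enough to keep genuinely nested rhythms
such as 8 & 45 Hz).

## Spike analysis

Firing rates divide total spikes by population size and window length,
counting silent cells. Burst fractions chain consecutive spikes of a neuron
with inter-spike intervals ≤ 10 ms into events; the fraction is
bursts/(bursts + singles), averaged over neurons with at least 2 spikes.
Spike phases come from the LFP filtered with a zero-phase 2nd-order
Butterworth, 10 Hz-wide band centred on the full-spectrum peak frequency
(band edges are clamped to stay inside (0, Nyquist) for peaks near the
analysis floor). The phase trace is computed on a 1 kHz decimated LFP and
the *unwrapped* phase is linearly interpolated at spike times — at 5 kHz the
narrow normalized bands would sit close to the filter's numerical stability
limit, and interpolation of the unwrapped phase is more accurate than any
nearest-sample lookup (quantization at 100 Hz would reach 36° even at
1 kHz). Phase 0 is the positive LFP peak, ±π the trough.

The pairwise phase consistency is the unbiased pairwise form
$\mathrm{PPC} = \tfrac{2}{N(N-1)} \sum_{i<j} \cos(\theta_i - \theta_j)$,
computed in O(N) via $(|\sum_t e^{i\theta_t}|^2 - N)/(N(N-1))$. (A printed
variant of this measure normalizes by $1/N$, which is dimensionally
inconsistent with the pairwise definition the measure's originators give;
the unbiased form is used here, with the O(N²) sum kept as a test oracle.)
Spikes are uniformly subsampled to at most 5000 per type before phase
statistics, with a deterministic per-simulation stream.

## Feature table and clustering

Each (motif, RS rate, FS rate) condition yields 14 features: firing rate,
PPC and burst fraction per cell type, low/high-band peak frequencies,
log10 power at those peaks, and PAC. Features are averaged over the repeat
seeds; a feature computable in fewer than 5 of 10 seeds (proportionally
fewer for smaller repeat counts) is set to 0 — on the raw scale, before
standardization, so that the zero-filled entries participate in the
column statistics exactly like genuine zeros. Columns are then z-scored
(root-mean-square deviation, divisor n; the divisor rescales all columns
equally and cannot change the clustering). For the two-cell RS-LTS motif
the second grid axis drives the LTS population — it has no FS cells.

k-means uses Lloyd iterations with squared-Euclidean distance, 10 restarts
seeded by random distinct rows from a dedicated RNG substream, at most 1000
iterations, best restart by total within-cluster sum of squares; a restart
that empties a cluster is re-initialized. The cluster count is selected by
the Calinski–Harabasz index $\bigl(SS_B/(k-1)\bigr)/\bigl(SS_W/(n-k)\bigr)$,
scanned from k = 2 (the index is undefined at k = 1; a 1-cluster "no split"
baseline is reported only descriptively) with ties to the smaller k, and the
full CH-vs-k curve is returned for inspection.

## Synthetic fixtures

`make_am_signal()` builds amplitude-modulated two-tone signals with known
coupling depth — depth 0 is the uncoupled control, and PAC must increase
with depth. `make_locked_raster()` draws spike trains with von Mises phase
preference around the peak of a reference cosine; its PPC has the closed
form $(I_1(\kappa)/I_0(\kappa))^2$. These generators exercise every feature
extractor without running the simulator; they emulate stationary,
noise-free (or white-noise) locking and do **not** reproduce the
non-stationarity, frequency drift or amplitude fluctuations of real circuit
output, so passing them validates the estimators, not the dynamics.

## Problem sizes used by the shipped analyses

The package's own test-suite and the reproduction script use reduced scans
chosen as sensible desk-scale protocols: the two-cell clustering runs
motifs I and II on an 11 × 11 grid (0–5000 Hz in 500 Hz steps) with 3
repeats; the all-motif clustering in the test-suite uses a 6 × 6 grid
(1000 Hz steps) with 2 repeats; regime checks use 2–10 repeats of single
conditions. The full published-scale protocol (21 × 21, 10 repeats) is
available behind `--profile paper` in the CLI and via `grid_spec()`
defaults.

## Known limitations

* Point neurons only; no conductances, gap junctions or short-term
  plasticity. Slow adaptation lives entirely in the $U$ variable.
* The LFP proxy is the mean voltage, not a weighted synaptic-current model;
  amplitudes should be compared within, not across, studies.
* Regime *boundaries* in the input grid depend on the two free defaults
  (LTS drive, offset noise); regime *existence* and their signatures are
  robust within the explored ranges.
* The numeral assignment for motifs whose dynamics are not distinctive is a
  convention (see above); analyses that depend on an exact topology should
  construct it with `motif_spec()` rather than rely on a numeral.
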