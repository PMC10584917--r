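---
title: "Motor-imagery EEG brain networks: spectra, WPLI, spanning trees and permutation statistics"
author: "mstnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor-imagery EEG brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mstnet)
```

## The analysis problem

During motor imagery (MI) — the mental rehearsal of a movement — the EEG
shows task-related changes both in band power and in the phase coupling
between electrodes. When an MI session is run inside a brain–computer
interface with neurofeedback (visual, or combined visual–electrotactile
stimulation), the interesting question is how the *functional network*
over the electrodes reorganizes between a pre-feedback session and a
feedback session.

`mstnet` implements that analysis chain end to end for a 16-channel
montage (AF3, AF4, FC3, FCz, FC4, C3, Cz, C4, T7, T8, CP3, CPz, CP4, Pz,
O1, O2; regions frontal / parietal / temporal / occipital as in
`default_montage()`):

1. **Preprocessing** — zero-phase Butterworth band-pass [0.5, 30] Hz and
   50 Hz notch, decimation from 512 to 128 Hz, exponential moving
   standardization, epoching of the first 2 s of each MI period.
2. **Spectra** — multitaper power spectral density at 0.5 Hz resolution;
   band power; frontal alpha asymmetry (FAA); relative power (RP)
   against the pre-onset rest baseline.
3. **Connectivity** — the weighted phase lag index (WPLI) per electrode
   pair in the alpha band (8–12 Hz), giving a 16 × 16 adjacency matrix.
4. **Network** — the maximum-weight spanning tree (MST) of that matrix
   and its graph metrics: degree, betweenness centrality, diameter, leaf
   fraction, tree hierarchy, maximum betweenness, global functional
   connectivity, and graph edit distance between trees.
5. **Statistics** — network-based statistics (NBS) with sign-flip
   permutations for edgewise session differences, and Wilcoxon
   signed-rank tests with FDR correction for every scalar metric.

Because the study data such pipelines are run on are typically not
public, the package ships a first-class synthetic cohort generator with
*known* phase-coupling ground truth. Every stage is validated against
that ground truth.

## Phase-lag estimators

For channels $a$ and $b$ with (tapered) spectra $F_a(f)$, $F_b(f)$, the
cross-spectrum is $X = F_a \overline{F_b}$. Zero-lag (volume-conducted)
signal components are purely real in $X$, so estimators built on
$\Im\{X\}$ are insensitive to them:

$$\mathrm{PLI} = \left| E\{\operatorname{sgn} \Im\{X\}\} \right|, \qquad
\mathrm{WPLI} = \frac{\left| E\{\Im\{X\}\} \right|}{E\{\left|\Im\{X\}\right|\}}.$$

Both lie in $[0, 1]$; WPLI weights each observation by the magnitude of
its imaginary part, which suppresses noise-driven sign flips near zero
lag. When the denominator is zero (no imaginary energy at all) WPLI is
defined as 0: there is no measurable lagged synchronization.

The expectation runs over epochs and tapers *per frequency bin*; band
values average the per-bin estimates over the in-band bins (the
convention of the standard connectivity tooling this mirrors). A
`pool_bins = TRUE` flag instead pools all in-band observations into one
expectation. Two consequences worth knowing:

* **Band dilution.** With a single oscillation at 10 Hz, only the bins
  within the taper bandwidth of the peak are signal-dominated; the
  remaining alpha-band bins contribute null-level estimates, so a
  perfectly coupled noisy pair plateaus near 0.7 rather than 1. The
  noise-free case still gives exactly 1, because all bins inherit the
  oscillation's phase through leakage.
* **Finite-sample bias.** Each per-bin WPLI is nonnegative, so its null
  expectation is of order $\sqrt{2/(\pi\,n_\mathrm{eff})}$ rather than
  0, and the *maximum* over all 120 electrode pairs is higher still. At
  40 epochs × 3 tapers the all-pairs maximum under pure zero-lag mixing
  sits around 0.2; at 200 epochs it drops to ≈ 0.1. Tests and
  acceptance checks therefore state the zero-lag bound at 200 epochs,
  and at the single-pair level for short recordings. Pooling bins does
  not help: in-band bins are correlated through the taper bandwidth, so
  the pooled estimate has fewer effective observations, not more.

## Multitaper parameters

Spectra use discrete prolate spheroidal (Slepian) tapers computed from
the tridiagonal eigenproblem, with time-half-bandwidth `nw = 2` and
`k = 2*nw - 1 = 3` tapers. For the 2 s analysis windows this gives a
±1 Hz smoothing bandwidth — narrow enough to keep the alpha band's 8
half-Hz bins informative, wide enough for useful variance reduction.
The frequency grid spacing equals `rate / nfft`; a 2 s epoch at 128 Hz
supports exactly the 0.5 Hz resolution the pipeline reports. Scaling is
one-sided power per Hz, so `band_power()` (bin sum × resolution)
recovers signal power: a unit-amplitude sinusoid integrates to 0.5.

Band edges are half-open, $[\mathrm{low}, \mathrm{high})$: alpha
$[8, 12)$ and beta $[12, 30)$ share the 12 Hz edge and an inclusive
convention would double-count it. FAA defaults to AF4 (right) over AF3
(left), the montage's only prefrontal pair; RP uses the mean PSD of the
2 s rest segment preceding each MI onset as its baseline, the only rest
interval the trial structure provides. Spectra pool left- and right-MI
trials within a session; a per-condition split is a one-line filter on
the epoch set.

## Filters

The paper-matched design is an eighth-order Butterworth band-pass with
a 0.5 Hz lower edge at a 512 Hz rate. That design cannot be run in
expanded transfer-function form: the band-transform polynomial has
poles at numerical modulus > 1 and the output diverges. `mstnet`
realizes the band-pass as an order-8 high-pass at 0.5 Hz cascaded with
an order-8 low-pass at 30 Hz, each kept as factored second-order
sections built from the closed-form analog Butterworth poles with
bilinear pre-warping. The cascade keeps the maximally flat pass band
(measured response matches the closed-form magnitude to < 2% at 1–40
Hz) and attenuates 40 Hz to < 1% after the zero-phase double pass.
Filtering is always forward–backward: phase distortion would corrupt
the phase-lag estimators downstream. The 50 Hz notch is an order-4
band-stop with a ±2 Hz stop band (the conventional choice when only
order and center frequency are given).

Decimation is a simple stride after the 30 Hz low-pass edge — the
band-pass already serves as the anti-alias filter for the new 64 Hz
Nyquist (tests assert the residual power above 35 Hz is < 5% of alpha
power). Exponential moving standardization uses decay 0.999 and
variance floor 1e-4, the community-standard values for EEG decoding
preprocessing, with running statistics initialized from the first
sample; both recursions are first-order IIR filters and are evaluated
as such. Epochs are the half-open window [onset, onset + 2 s) with
0-based sample indexing — an unambiguous 256 samples at 128 Hz.

## Trees and their metrics

WPLI weights are synchronization strengths (inverse distances), so the
informative backbone is the spanning tree of *maximum* total weight —
Kruskal's algorithm on edges sorted by descending weight with
lexicographic tie-breaking, making the result deterministic. Tree
metrics use hop distances: paths in a tree are unique, so edge weights
cannot change which path is used, and the diameter normalization by
edge count presumes hops.

Betweenness centrality counts ordered node pairs $(h, j)$ whose unique
path crosses $i$, normalized by $(N-1)(N-2)$; on a tree this reduces to
a product of the component sizes created by deleting $i$, but the test
suite checks it against literal path enumeration. Tree hierarchy
$Th = L / (2 M \, C_{B\max})$ is 0.5 for a star and tends to 0 for a
line; note that 0.5 is *not* a universal upper bound — a double star
(two adjacent hubs splitting the leaves) reaches $8/13$ — so the
package documents the range as $(0, 1]$ with the star/line values as
the interpretable anchors.

Graph edit distance between two trees on the same labeled electrode set
uses unit edge insertion/deletion costs and no node operations; the
minimum edit cost is then exactly the edge symmetric difference, where
each differing edge costs its deletion plus its replacement's
insertion. Whether a swap should count once or twice is a convention;
`count_swaps_once = TRUE` halves the distance for sensitivity analyses.

Group-level trees average the subjects' connectivity matrices before
tree construction. That view is descriptive only — averaging discards
individual variability — so formal edgewise inference goes through NBS.

## Permutation and rank statistics

NBS computes an edgewise paired $t$ statistic, keeps edges with
$|t|$ above a threshold (default 2), extracts connected components, and
controls the family-wise error rate by permutation: subject difference
matrices are sign-flipped (all $2^n$ patterns enumerated for up to 12
subjects, identity included; 5000 seeded random patterns otherwise) and
the maximal component statistic is recorded per permutation.

Two small-montage caveats shape the defaults:

* At $|t| > 2$ with 10 subjects, about 7.6% of the 120 edges are
  suprathreshold under the null, and ~9 random edges on 16 nodes
  percolate into chance clusters several edges long. Small true
  components are therefore hard to flag by *extent* at the default
  threshold; detection-oriented analyses on this montage should raise
  the threshold (the validation suite uses $|t| > 3$) or use the
  *intensity* statistic (summed $|t|$ over the component). The
  false-positive guarantee itself holds at any threshold.
* A spatially sparse but strong effect — one or two disjoint edges with
  $t \sim 40$, which is what planted oscillator coupling produces — can
  never be an extreme *edge count*; the intensity statistic separates
  it cleanly. The end-to-end recovery checks use intensity for this
  reason.

The Wilcoxon signed-rank test drops zero differences, enumerates the
exact null over all sign assignments with midranks for up to 14
informative pairs (midrank enumeration stays exact under ties), uses
the closed-form exact distribution for tie-free samples up to n = 25,
and the tie-corrected normal approximation beyond. FDR correction is
Benjamini–Hochberg; all metric-level comparisons of a study are
adjusted as a single family, matching a single adjusted significance
level of 0.05 (correcting within each metric family separately would
multiply the study-level false-positive rate by the number of
families).

## The synthetic cohort generator

`generate_cohort()` emulates the study structure: two groups (VIS /
VES) × 10 subjects × two sessions (pre-feedback / feedback) × 2 runs ×
40 trials balanced over left/right MI, at 512 Hz on the 16-channel
montage. Each trial is 2 s of rest followed by 2 s of MI (the analysis
window; the event marker sits at MI onset). Ground-truth coupling is a
fixed-frequency sinusoid pair with per-trial uniform random initial
phase and a constant lag; partial strength $s$ mixes the lagged
component with an independent-phase component in proportion
$s : (1-s)$, interpolating the recoverable WPLI between ~0 and ~1.
Noise is white Gaussian (sd 1 by default, i.e. noise power comparable
to the unit oscillators), optionally 1/f-shaped; a
`common_source_gain` adds one shared zero-lag oscillation to every
channel to mimic volume conduction. All randomness derives from one
master seed through a stated integer hash (subject → session → run →
trial), so cohorts are bit-reproducible and trials independent.

What the generator does *not* emulate: biophysical head geometry and
lead fields, non-stationary amplitude dynamics, ocular/muscle
artifacts, or inter-subject anatomical variability. Passing tests
therefore demonstrate that the estimators and statistics recover known
phase-coupling structure under realistic noise — not that any
particular neurophysiological effect exists in real data.

## Problem sizes and numerical conventions

The validation suite runs at the protocol's native scale where the
claim depends on it: cohort structure at 20 subjects × 2 sessions × 2
runs × 40 trials; end-to-end recovery at 10 subjects × 2 sessions × 2
runs over 20 replicate seeds; NBS error rates over 500 replicate null
cohorts with full $2^{10}$ enumeration; zero-lag bounds at 200 epochs ×
20 seeds. Unit tests of the pipeline plumbing use reduced cohorts (2
subjects, 16 trials) since the structural claims do not depend on
scale.

Degenerate inputs are handled by convention, not silently: WPLI with a
zero denominator returns 0; epochs whose window crosses a recording
edge are dropped with a warning; a disconnected connectivity matrix
names its components in the error; betweenness, leaf fraction and tree
hierarchy refuse trees with fewer than 3 nodes; all-zero paired
differences raise a degenerate-sample error; p-values outside [0, 1]
are rejected. MST ties are broken lexicographically; permutation nulls
always include the identity so p-values are bounded below by
$1/n_\mathrm{perm}$.

## Known limitations

* WPLI is nondirectional and band-dependent; the band-averaged value
  dilutes narrow-band coupling (see above).
* The MST keeps only the strongest backbone; weaker but real
  connections are invisible to all tree metrics.
* On 16 nodes, NBS extent has little power for small components at the
  default threshold (percolation of the null $t$-field); this is a
  property of the statistic, not of the implementation.
* The exponential-standardization decay/eps, notch bandwidth, filter
  direction, RP baseline window, multitaper bandwidth and FDR family
  structure are analysis conventions chosen here (and stated above);
  other reasonable choices exist and would change numbers at the
  margin.
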