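---
title: "Eigenvector alignment analysis of EEG connectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eigenvector alignment analysis of EEG connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegalign)
```

## The problem

Sensor-space EEG connectivity is contaminated by volume conduction: a single
cortical source reaches many electrodes through tissue essentially
instantaneously, so channel pairs can be strongly correlated without any
genuine interaction. The imaginary part of coherency (iCOH) suppresses this
contamination — instantaneous (zero- or $\pi$-phase) coupling has a purely
real coherency — but it does so at a price: *true* zero-lag interactions are
erased along with the spurious ones, and single-pair iCOH values are noisy.

`eegalign` addresses both problems by reading the relationship between two
channels off the *global pattern* of connectivity rather than the direct
edge. Channels are embedded in a low-dimensional space spanned by dominant
eigenvectors of the connectivity matrix, and the angle between two channels'
position vectors — their *eigenvector alignment* (EA) — measures how similar
their whole connectivity profiles are. Two channels whose direct weight was
erased by iCOH can still be closely aligned if they connect to the rest of
the network in the same way, and a single corrupted edge moves every angle
only slightly.

## Connectivity estimation

For channels $i, j$ the coherency at frequency $f$ is

$$\mathrm{COH}_{ij}(f) = \frac{S_{ij}(f)}{\sqrt{S_{ii}(f)\,S_{jj}(f)}},$$

with $S_{ij}$ the trial-averaged cross-spectrum. `estimate_cross_spectra()`
demeans and Hann-tapers each trial, zero-pads to a length giving exactly the
requested grid step (0.5 Hz by default), and averages cross-periodograms
over trials. At least two trials are required: the coherency of a single
tapered trial has magnitude identically one and carries no information.

The band weight is the mean of $|\mathrm{Im}\,\mathrm{COH}_{ij}(f)|$ over
the grid bins inside the closed band interval (`icoh_band()`). The
conventional bands are delta 0.1–4 Hz, theta 4–7 Hz, alpha 7–13 Hz and beta
13–30 Hz; on the 0.5 Hz grid the delta band therefore spans the eight bins
0.5–4 Hz. For a pair that is a pure delayed copy at frequency $f$ with lag
$\tau$ the band iCOH around $f$ is $|\sin(2\pi f \tau)|$, which the test
suite verifies to within 0.05 at 100 trials.

`correlation_matrix()` provides the comparison measure: per-trial Pearson
coefficients on band-passed signals (zero-phase forward–backward 4th-order
Butterworth, so the filter introduces no artificial lags), averaged across
trials, absolute value taken. The absolute value keeps the matrix
nonnegative, which preserves the Perron–Frobenius argument below.

## Eigenvector alignment

`embed_connectivity()` diagonalizes the symmetric connectivity matrix and
places channel $i$ at $(v_2[i], v_3[i], v_4[i])$. Eigenvalues are ordered by
descending algebraic value; for a nonnegative matrix the leading eigenvector
is the Perron–Frobenius vector, whose entries all share one sign — it cannot
express a division of the network and is excluded. Ranks 2–4 capture the
three most prominent divisions; ordering by absolute eigenvalue is exposed
as an option for inputs that are not elementwise nonnegative.

The alignment angle is
$\theta = \cos^{-1}\!\big(\mathbf{r}\cdot\mathbf{s}/(|\mathbf{r}||\mathbf{s}|)\big)$,
reported in degrees. Numerical choices, each covered by a test:

* the cosine is clamped to $[-1, 1]$ before `acos` (floating-point safety);
* each eigenvector's sign is fixed (first loading above $10^{-8}$ made
  positive) so degenerate spectra give reproducible output; angles are
  invariant to this choice, and to any sign flip or rescaling of the matrix;
* channels whose position vector has norm below $10^{-12}$ have no direction:
  their angles are flagged `NA` and excluded from inference rather than set
  to an arbitrary value;
* equal eigenvalues (e.g. a complete graph) are handled deterministically —
  two calls on the same matrix are bit-identical.

A caution on interpretation: the embedding dimension bounds how much
structure EA can see. A network whose division structure spans fewer than
three non-leading eigenvectors (e.g. exactly three planted communities in a
noise-free matrix) leaves rank 4 in a degenerate eigenspace, and angles
along that axis are arbitrary. The test fixtures therefore use four planted
communities when they need noise-free structure spanning ranks 2–4 exactly.

## Significance against randomized null models

For a group of subjects, each subject's connectivity matrix is randomized by
permuting the upper-triangle weights (`randomize_connectivity()`), which
preserves the subject's multiset of connectivity values exactly while
destroying structure. `build_null_ensemble()` produces 1000 such matrices by
default, cycling round-robin through the group so every subject's value
distribution is represented equally (the allocation is a package choice; the
method itself does not prescribe one), and computes each null's EA with the
same eigenvector ranks as the subjects.

`pairwise_welch_test()` compares, per channel pair, the subjects' angles
(one per subject) with the null angles by an unequal-variance $t$-test with
Welch–Satterthwaite degrees of freedom — the Behrens–Fisher setting; the
null sample is large and its variance unrelated to the subject variance.
The test is two-sided with post-hoc direction labels: *increased* alignment
means subject angles significantly **smaller** than null (closer), and
*decreased* means larger. With a 128-channel montage this is 8128
simultaneous hypotheses, so p-values are converted to q-values by
Benjamini–Hochberg (`bh_fdr()`), applied within each band/measure family
(pooling across bands would let a strong band mask a weak one). Pairs with
undefined angles are dropped before adjustment so untestable hypotheses do
not dilute the FDR. Discoveries are `q < 0.05`.

`consistency_filter()` keeps pairs significant *with the same direction* in
at least 3 of the 4 bands. Requiring matching direction is deliberate:
increased and decreased alignment are distinct findings, and a pair split
2–2 between them is evidence of instability, not consistency.

`expand_cohort()` duplicates subject matrices to inflate apparent sample
size. It exists only as an illustrative device for comparing groups of
unequal size; its output, and every report derived from it, carries an
`artificially_expanded` flag.

## Robustness to connection alteration

The promise of EA is stability under the kind of edge erasure iCOH performs.
`robustness_sweep()` quantifies it: for each alteration percentage, the $k$
pairs with the smallest reference-iCOH weights are either zeroed in a target
correlation matrix (`erase_lowest()`) or raised to the matrix maximum in the
iCOH matrix itself (`create_lowest()`); EA is recomputed and
$\Delta EA$ — the mean absolute angle difference over pairs
(`delta_ea()`) — is reported as mean ± sd across subjects. Ties among equal
reference weights are broken by ascending (row, column) index, and
percent-to-$k$ rounding is half-away-from-zero; both rules exist purely for
determinism. On matched synthetic cohorts, $\Delta EA$ grows with the
alteration percentage, and sparser montages (24 channels) change more than
denser ones (64 channels) at the same percentage — fewer edges means each
one carries more of the embedding.

## Reporting geometry

`distance_bounds()` restricts reported connections to sensor pairs that are
neither neighbors nor very distant: the maximum distance is 65% of the
anterior–posterior (y-axis) coordinate range and the minimum is 250% of the
smallest pairwise sensor distance. "Maximum y-axis sensor distance" is
interpreted as the y-coordinate *range*, with full 3-D Euclidean distances
for the pairwise filter; both factors are arguments. Neighboring sensors
share connectivity patterns and are aligned almost by construction, while
decreased alignments between distant sensors are unsurprising; the window in
between is where findings are informative. On sparse montages the minimum
bound can exceed the maximum; `distance_bounds()` refuses such geometries,
and `run_pipeline()` then reports unfiltered edges with a warning rather
than failing the run. Layouts are user-supplied TSV
(`label, x_mm, y_mm, z_mm`); the package bundles no vendor coordinate files
and instead generates a synthetic Fibonacci spherical-cap layout
(`synthetic_layout()`) for tests and simulations.

## The synthetic generator

`simulate_epochs()` emulates exactly the ingredients the method is designed
around:

* **band-limited oscillatory sources** — sinusoids with per-trial random
  initial phase and Ornstein–Uhlenbeck phase drift (sd 0.2 rad/√s,
  relaxation 0.5 s by default). Drifting phase, rather than per-band
  filtered noise, was chosen because it makes the coherence level a direct,
  controllable function of the coupling strength;
* **lagged coupling** — a coupled source is
  `(1-strength)·own + strength·delay(origin)`, so `strength = 1` is a pure
  delayed copy and closed-form coherency phases are exact. Delays are
  applied by interpolating the instantaneous phase, so lags need not be
  integer multiples of the sample period;
* **volume conduction** — instantaneous nonnegative mixing with a Gaussian
  distance kernel $\exp(-d^2/2\sigma^2)$ ($\sigma$ = 35–40 mm), a smooth
  leadfield surrogate;
* **sensor noise** — additive white Gaussian noise after mixing;
* **cohorts** — `generate_cohort()` gives every subject the shared coupling
  pattern, with per-subject strength jitter (sd 0.05 in the reference
  conditions) and, for impaired-like profiles, a multiplicative attenuation
  of all coupling strengths. Subject $i$ is seeded with `spec$seed + i`, so
  a cohort is fully reproducible from its spec.

The reference scenario (`coupled_cohort_model()`) uses 64 sensors, 8 sources
at 10 Hz coupled in pairs at 25 ms lag (a quarter cycle at 10 Hz, hence
maximal iCOH) with strength 0.8, and noise sd 0.5. Passing several
frequencies places one oscillator set per band at the same sites, producing
networks consistent across bands. Per-band lags keep the coupling phase away
from 0 and $\pi$ in every band — at 20 Hz a 25 ms lag is exactly $\pi$ and
iCOH would erase it, which is itself a useful property to remember when
designing simulations.

What the generator does **not** emulate: realistic head-model forward
solutions, 1/f background spectra, artifacts (ocular, muscle, line noise),
nonstationary resting-state dynamics, or genuine zero-lag cortical coupling.
Passing tests on these cohorts therefore demonstrates the statistical
machinery — suppression of instantaneous mixing, recovery of planted lagged
structure, FDR control, reproducibility across null ensembles — not
performance on clinical recordings.

## Problem sizes and runtime choices

The test suite exercises cohorts of 5–15 subjects with 12–64 channels,
8–100 trials of 2 s at 128 Hz, and null ensembles of 25–1000 models; the
reproducibility experiment (15 subjects, 64 channels, two independent
1000-model ensembles) completes in well under a minute on one core. These
sizes were chosen as the smallest at which each property is stably
observable. The 128-channel combinatorics (8128 pairs) are checked directly
on planted matrices, where no signal estimation is needed.

## Known limitations

* Sensor-space only; no source reconstruction, no directed measures.
* The null model randomizes edges independently per subject matrix; it
  preserves the value distribution but not degree sequences or spatial
  autocorrelation, so "significant" means "more structured than an
  exchangeable rearrangement", nothing stronger.
* Welch tests treat subjects as independent samples and nulls as a fixed
  reference; with very few subjects the subject-side variance estimate is
  weak, which is exactly why the duplication device must never be read as
  real evidence.
* The consistency rule (3 of 4 bands) is a heuristic filter against
  single-band artifacts, not a formal multiple-testing procedure across
  bands.
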