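---
title: "Resting-state EEG networks and absolute pitch: the apnet methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state EEG networks and absolute pitch: the apnet methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apnet)
```

apnet implements a complete analysis chain for comparing whole-scalp
resting-state EEG functional networks between groups of musicians with and
without absolute pitch (AP vs RP), together with the behavioral instruments
that define those groups. This vignette explains the models and procedures,
the tunable parameters and their defaults, what the synthetic cohort
generator does and does not emulate, and the numerical and design choices
made where more than one defensible option existed.

## Connectivity: the weighted phase lag index

For channels $x$ and $y$, the cross-spectrum at one observation $t$ is
$S_{xyt} = X_x(f)\,\overline{X_y(f)}$. Its imaginary part is nonzero only
when the two signals maintain a nonzero, non-$\pi$ phase lag — instantaneous
(volume-conducted) coupling contributes nothing. The phase lag index and its
weighted refinement are

$$\mathrm{PLI}_{xy} = \left| n^{-1}\sum_t \operatorname{sgn}\,
  \mathrm{imag}(S_{xyt}) \right|, \qquad
  \mathrm{wPLI}_{xy} = \frac{\left|\sum_t \mathrm{imag}(S_{xyt})\right|}
  {\sum_t \left|\mathrm{imag}(S_{xyt})\right|}.$$

Both lie in $[0, 1]$. wPLI down-weights observations whose imaginary part is
near zero (which under noise carry an essentially random sign), so it is the
primary estimator; PLI is retained for comparison.

Observations are collected per subject, condition and band as follows:
recordings are cut into non-overlapping 4-s epochs (a 300-s recording yields
75); each epoch is mean-detrended, tapered and Fourier transformed; every
frequency bin inside the band contributes one observation per epoch and
taper. Delta (2–4 Hz) and theta (4–7 Hz) use a single Hanning taper; alpha
(7–13 Hz), beta (13–30 Hz) and gamma (30–60 Hz) use DPSS multitapers with
spectral smoothing half-bandwidths of ±1, ±2 and ±4 Hz. The taper count
follows the standard rule $K = 2TW - 1$ (e.g. 15 tapers for beta with
$T = 4$ s, $W = 2$ Hz). Because no installed R package provides Slepian
sequences, apnet computes them from the symmetric tridiagonal eigenproblem
whose eigenvectors are the DPSS, caching per $(N, NW, K)$.

Two conventions required a decision:

* **0/0 rule.** When $\sum_t |\mathrm{imag}(S_{xyt})| = 0$ (identical or
  exactly zero/$\pi$-lagged channels) wPLI is defined as 0 — consistent with
  the estimator's purpose of ignoring such coupling.
* **Observation pooling.** All epoch × taper × bin observations enter one
  ratio per pair ("pooled"), rather than computing a per-bin wPLI and
  averaging. The pooled form is a single well-defined estimator of the band's
  phase-lag asymmetry; the per-bin variant is available via
  `wpli(obs, pooling = "per_bin")` for sensitivity analyses. For single-bin
  bands the two coincide.

A `beta_low` preset (13–18 Hz) ships alongside `beta` (13–30 Hz): both
conventions appear in the resting-state literature and they are not
interchangeable; no default claims to reproduce results obtained under the
other convention.

## Graph construction and metrics

A wPLI matrix is binarized by first extracting the spanning tree of maximal
total weight (equivalently the minimum spanning tree of $1 -$ wPLI), then
adding the strongest remaining edges until $\lceil d \cdot n(n-1)/2 \rceil$
edges at each density $d$ of the sweep. The tree guarantees a connected
network of all $n$ nodes at every density, so path lengths are always finite
and networks of equal size are compared across subjects. Edge order is
deterministic (weight descending, then node-index pair ascending), making
sweeps reproducible even with tied weights, and the nested construction
means every lower-density edge set is a subset of every higher one.

The default grid is the nine densities 0.036–0.291 used for whole-scalp
binary networks. For 28 channels the spanning tree alone has density
$27/378 \approx 0.0714$, so the lowest grid value cannot be realized; apnet
clamps such densities up to the tree with a warning rather than silently
reporting an unreachable target.

On each binary network:

* **Clustering** $C_i = 2t_i / (k_i(k_i-1))$ with $t_i$ the triangles
  through node $i$ ($C_i = 0$ when $k_i < 2$, the 0/0 convention); global
  $C$ is the node mean — segregation.
* **Path length** $L_i$ = mean hop-count distance from $i$ to every other
  node; global $L$ is the node mean — integration.
* **Small-worldness** $\sigma = \gamma/\lambda$ with
  $\gamma = C/C_{\mathrm{rand}}$ and $\lambda = L/L_{\mathrm{rand}}$, the
  random references being means over degree-preserving surrogates.

The weighted forms of these definitions reduce exactly to the binary ones on
$\{0,1\}$ matrices, which is the network type constructed here; a
weighted-metric mode is deliberately out of scope. Triangle counts come from
$\mathrm{diag}(A^3)/2$ and distances from boolean-product breadth-first
expansion — at 28 nodes these direct formulas are faster than constructing
graph-library objects per density, and both are verified in the test suite
against exhaustive enumeration, Floyd–Warshall, and igraph.

The null model is the Maslov–Sneppen double edge swap: $10 \times k$
attempted swaps, rejecting any swap that would create self-loops,
multi-edges, or disconnect the network, with 50 surrogates per network by
default. Degree sequences are preserved exactly. If no valid swap exists
(e.g. complete graphs) the original network is returned with a warning.
$\sigma$ is reported as `NA` when a network is triangle-free ($C = 0$, e.g.
on the tree backbone itself), where $\gamma$ is undefined.

## Behavioral layer

**Pitch adjustment.** Each trial's final frequency is scored as the signed
cents deviation to the *nearest* octave-equivalent instance of the target
pitch class (A4 = 440 Hz equal temperament), mapped into $[-600, 600)$ —
the half-open interval resolves the exact-tritone tie deterministically.
Accuracy is $\mathrm{MAD} = \sum_i |C_i| / N$ and consistency
$\mathrm{SDfoM}$, the sample SD (divisor $N-1$) of the $|C_i|$ around the
MAD — the SD is taken over absolute deviations, matching the construct of
"pitch template tuning". For regressions, MAD and SDfoM are z-standardized
against the mean and SD of the non-AP group. Both scores are invariant under
octave transposition of all responses and scale linearly in cents.

**AQ.** 50 items, 5 subscales × 10; one point per item endorsed in the keyed
autistic direction (mild or strong agreement, reverse-keyed items inverted);
maximum 50. Incomplete questionnaires are an error by default (prorating is
opt-in).

**PIS and group rule.** Tone naming is scored as octave-free pitch-class
equality with enharmonic spellings equated (F♯ = G♭); whether octave-correct
naming was originally required is not recoverable, and octave-free scoring
is the assumption made here. A subject is AP iff strictly more than 12 of 36
tones are correct; explicit per-subject overrides (for re-assessed subjects)
take precedence and are recorded in the result's attributes.

## Group inference

**Density-sweep tests.** A Welch two-sample test is run per metric × band ×
condition × density cell, with Cohen's $d$ (pooled SD) as the effect size.
Because networks at neighboring densities are nested — hence strongly
dependent — standard multiplicity corrections are ill-suited; instead a cell
counts as significant only when an adjacent density in the same metric ×
band × condition is also below $\alpha = 0.05$ (two successive thresholds).
Tests are two-sided. A secondary mask at $\alpha = 0.10$ reports marginal
runs. For each surviving run, the representative density is the member with
the largest $|d|$; downstream regressions use metric values at those
representative thresholds. Cells where both groups have zero variance or a
metric is undefined (e.g. $C$ on the tree backbone) are marked untestable
rather than significant.

**Edge-wise permutation tests.** For each channel pair, the observed group
mean difference is referenced to its distribution under random relabelings
of subjects, the same shuffle applied to all edges so between-edge
dependence is preserved. Two-sided p values use the add-one estimator
$(\#\{|perm| \ge |obs|\} + 1)/(n_{perm}+1)$, so the smallest attainable p is
$1/(n_{perm}+1)$; the default is 10,000 permutations with group-label
permutation (not sign-flipping). Benjamini–Hochberg FDR at $q = 0.05$ is
applied across the $n(n-1)/2$ edges (the FDR variant and level are choices;
BH at 0.05 is the field's default). The test runs both on raw matrices and
on per-subject z-standardized matrices (off-diagonal entries standardized to
mean 0, SD 1), the latter contrasting the *relative* importance of
connections within each subject's network.

**Regression layer.** OLS models predict tone-naming performance and
z-standardized adjustment performance from autistic traits, starting age and
the network metrics at representative thresholds; per-metric model families
(trait + proficiency vs proficiency alone) are ranked by AIC (smaller
better, ties by adjusted $R^2$). AIC uses the Gaussian-likelihood convention
of `stats::AIC()`, which differs from $n\ln(RSS/n) + 2(p+1)$ only by a
constant in $n$ — rankings on a common response are unaffected. Mediation is
the product-of-coefficients estimate $a\cdot b$ with a percentile bootstrap
CI over case resampling (5,000 replicates by default); "significant" means
the CI excludes zero. Regression coefficients reported on real cohorts
cannot be reproduced from synthetic data, and none are asserted anywhere in
the package.

## The synthetic cohort generator

The generator exists so every downstream stage is testable with known ground
truth; it emulates the *statistical structure* the pipeline consumes, not
EEG physiology.

* **Background**: independent $1/f$ noise per channel (spectral slope 1,
  configurable), unit RMS — the standard resting-EEG background spectrum.
* **Coupling**: each `coupling_spec(pair, band, phase_lag, strength)` adds a
  shared band-limited Gaussian oscillation to both channels, the second
  channel's copy phase-shifted by `phase_lag` at every in-band frequency via
  the analytic signal. The carrier is an *independent random process per
  coupling*: an earlier design using a fixed sinusoid at the band center
  made all couplings in a band mutually coherent (their relative phases are
  constant within a recording), which wired every coupled channel to every
  other and erased the configured topology. With independent carriers the
  recovered wPLI adjacency equals the configured coupling graph.
  Zero and $\pi$ lags with positive strength are rejected at construction:
  they are invisible to wPLI, so such a spec could never be recovered.
* **Behavior**: single-trial cents deviations are Normal (an assumption —
  the empirical shape of single-trial deviations is not characterized;
  flagged in the config); the AP-like group uses $\sigma = 52$ cents, giving
  $E\,\mathrm{MAD} = \sigma\sqrt{2/\pi} \approx 41$ cents, while the RP-like
  group uses $\sigma = 600$ cents, which after wrapping into
  $[-600, 600)$ is nearly uniform and yields $\mathrm{MAD} \approx 300$
  cents — the two regimes bracket observed AP/RP performance. AQ items are
  Bernoulli with a per-subject logistic trait (group locations chosen to
  give totals near 20.5 vs 16.9 of 50, between-subject trait SD 0.4);
  tone-naming answers are correct with group probabilities 0.79 / 0.15, so
  the >12/36 rule reproduces group membership with high probability.
  Starting ages are Normal (6.0 ± 3.0 vs 7.1 ± 2.2 years, floored at 1).
* **Defaults**: 31 + 33 subjects, 28-channel montage, 512 Hz, 300 s, both
  eyes-open and eyes-closed conditions. The default coupling structure
  places one shared alpha coupling in both groups and six beta couplings
  among six fronto-temporal channels — closed into two triangles in the
  first group, arranged as a chain in the second — a clustering difference
  confined to beta.

What the generator does *not* emulate: volume conduction and reference
effects, artifacts (blinks, EMG, drift), spatially correlated noise,
electrode geometry, or nonstationarity beyond the carriers' natural
amplitude fluctuation. Passing tests therefore demonstrate that the
*pipeline* recovers known structure from signals with realistic spectral
statistics — not that the method is robust to everything real EEG contains.

Cohorts store EEG as seeded recording references materialized on demand
(`get_recording()`); a fully materialized default cohort would hold ~4.3 GB
of samples. All randomness derives from one master seed through a labelled
sub-seed hash, so partial re-runs reproduce the full run exactly.

## Numerical choices and degenerate inputs

* Epoching discards the trailing partial segment; recordings shorter than
  one epoch are an error, as is dropping all epochs.
* Bands must contain at least one FFT bin at the epoch's resolution
  (0.25 Hz at 4 s) and lie strictly below Nyquist.
* `cross_spectra()` accumulates exact per-bin sufficient statistics
  ($\sum \operatorname{sgn}$, $\sum$, $\sum|\cdot|$ of the imaginary part)
  in compiled code; the full complex observation array (gigabytes for long
  gamma-band recordings) is materialized only with `keep = "observations"`.
  Both routes give identical estimates — the pooled estimator is a ratio of
  sums — and the equality is asserted in the tests.
* MST ties break on ascending node-index pairs; all-equal weights give the
  deterministic star on the first node.
* Requested densities below the spanning-tree density are clamped up with a
  warning; edge counts round up ($\lceil\cdot\rceil$).
* The permutation p floor is $1/(n_{perm}+1)$; permutation tests, the null
  model, mediation and the generator are all reproducible under their seed
  arguments.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script experiments run at sizes chosen to
exercise the full cohort logic while completing on a single CPU: recovery
experiments use 31 + 33 subjects with 60-s recordings at 128 Hz (both
recovery bands lie below 30 Hz; taper and bin counts are independent of the
sampling rate), one condition, beta + theta bands, and the clustering
metric; type-I calibration uses 6-node matrices with 12 subjects per group
and 1,000 permutations; the Watts–Strogatz small-world check uses n = 28,
k = 4, rewiring 0.1 with 8 surrogates per network. The full-scale defaults
(512 Hz, 300 s, five bands, two conditions, 50 surrogates) run through
exactly the same code paths.

## Known limitations

* Binary networks only; weighted clustering/path-length variants are not
  implemented.
* The density grid's lowest published value is unreachable at 28 nodes
  (clamped); analyses at that grid point are tree-backbone analyses.
* EDF input is not supported; recordings are exchanged as delimited
  channels × samples matrices with a JSON sidecar.
* The successive-threshold rule controls multiplicity only across densities
  within a metric × band × condition, not across bands or metrics — by
  design, mirroring the cluster-like logic it implements.
* Mediation requires n ≥ 10 and is skipped (with a log entry) for smaller
  cohorts.
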