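---
title: "Permutation entropy for short expression time series: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation entropy for short expression time series: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentropy)
```

## The problem

Stress-response microarray (and RNA-seq) experiments typically measure each
gene at a handful of time points — often seven, sampled densely early
(0, 0.5, 1 h) and sparsely late (3, 6, 12, 24 h). Classical entropy-based
complexity measures are asymptotic quantities and break down on series this
short, non-stationary, and non-equidistant. Permutation entropy sidesteps
amplitude altogether: it decomposes a series into the *ordinal patterns* of
consecutive observations and scores the diversity of patterns actually
realized. A profile that only drifts monotonically, or not at all, is
"simple"; one that switches repeatedly between up, down, and no change is
"complex" and hints at correspondingly rich regulatory input.

## The model

Each overlapping window of three consecutive log2 expression values
$(x_1, x_2, x_3)$ is classified by the *thresholded signs* of its
differences: a difference counts as unchanged when its magnitude is strictly
below a noise threshold $d_e$ (log2 units). Allowing this tie relation
extends the $3! = 6$ strict rank permutations to the **13 weak orderings of
three elements**:

* codes 1–2: monotone up / down,
* codes 3–6: strict peak/valley variants, distinguished by whether the
  endpoint lies below or above the start,
* codes 7–12: exactly one tie (tied endpoints around a peak/valley, or one
  flat step before/after a changed step),
* code 13: all comparisons below threshold — the *no-change* pattern, which
  keeps pure measurement noise from masquerading as complexity.

`pe_patterns` documents the full code table; `pe patterns` prints it from
the command line. Two details deserve emphasis:

* Threshold relations are not transitive, so the endpoint comparison
  $x_3 - x_1$ is consulted *only* when the two consecutive differences are
  changed in opposite directions, where it is needed to separate the
  peak/valley variants. This is the unique consecutive-difference scheme
  that yields exactly 13 classes; the exhaustive enumeration is asserted in
  the test suite.
* A difference of exactly $d_e$ counts as changed (the tie region is open).

A series of $t$ points yields $w = t - n + 1 = t - 2$ windows (step 1,
overlapping). With pattern relative frequencies $p_i$ the score is the
Shannon entropy in bits,

$$PE_g = -\sum_{i=1}^{N} p_i \log_2 p_i , \qquad N = 13,$$

with $0 \log 0 = 0$ (only observed patterns enter the sum). The log base is
fixed at 2 — the CLI rejects `--log-base` values other than 2 — so that the
maximum for $w = 5$ windows is $\log_2 5 \approx 2.32$ bits. Because $w$ is
tiny, $PE$ is *discrete*: the value is determined by the integer partition
of $w$ into pattern multiplicities. For the 7-point design:

```{r}
achievable_pe_values(5)
```

Seven values, from a single repeated pattern (partition 5, $PE = 0$) to
five distinct patterns (1-1-1-1-1, $PE = \log_2 5$). Distinct pattern
*sequences* with the same multiplicity multiset are degenerate — they score
identically by construction. The discreteness is why all group comparisons
in the package use the Mann–Whitney-U test rather than $t$-tests.

## The noise threshold

$d_e$ is the only tunable parameter of the codec. It is estimated from
repeat measurements: pool the absolute log2 differences between all
unordered replicate pairs (all genes, time points, and conditions) and take
their mean plus one standard deviation. On the Arabidopsis abiotic-stress
arrays this gives $0.156 + 0.19 \approx 0.35$, the package default.
`estimate_noise_threshold()` recomputes it from any replicate set; how the
differences are pooled is stated above and is the only variant implemented.
Results are robust to moderate changes of $d_e$; the scale of the data
(log2) matters, not its offset, since the codec is shift-invariant and
jointly scale-covariant in $(x, d_e)$.

## Preprocessing choices

* **Low-expression filter.** Genes expressed near background trivially
  score $PE = 0$ (nothing can change detectably), which would contaminate
  any comparison of entropy against gene features. `filter_low_expression()`
  ranks genes by mean (optionally median) expression over the control time
  points and drops the lowest `n_drop`; ties break lexicographically by
  gene id so the kept set is reproducible. The pipeline default drops
  10,000 genes only when at least 20,000 are present (array-scale input),
  otherwise nothing; `n_drop` also accepts a fraction.
* **Spline resampling.** `resample_even()` probes sensitivity to the uneven
  sampling grid by evaluating a cubic interpolating spline at equidistant
  times spanning the original range. The default boundary handling is
  `"fmm"` rather than natural boundary conditions: natural splines force
  zero second derivatives at the ends and therefore cannot reproduce even a
  cubic trend exactly, whereas the exactness of `"fmm"` on cubics gives the
  test suite a closed-form oracle. `"natural"` remains available.
* **Control normalization.** `normalize_to_control()` subtracts the control
  trajectory elementwise (log2 scale), so entropy can be computed on the
  relative response. Whether enrichment analyses should run on raw or
  control-normalized entropies is exposed as the pipeline option
  `normalize_to_control`; both variants are legitimate and the package
  defaults to raw.

## Statistics

`mwu_test()` is implemented in the package because the entropy values are
heavily tied: for $m + n \le 12$ it enumerates all group assignments of the
mid-ranked pooled sample (exact even with ties; the suite checks it against
a brute-force pair-counting oracle), and otherwise uses the tie-corrected
normal approximation with continuity correction (checked against
`stats::wilcox.test`). `compare_conditions()` reports the shift as both
difference of means and of medians; the MWU decision is primary, the deltas
are descriptive. Enrichment uses `stats::fisher.test` (two-sided) per
category with Benjamini–Hochberg FDR across categories;
`mean_pe_by_category()` plus `bicluster()` (average linkage; Euclidean
distance by default, correlation distance optional — the linkage is part of
the method, the distance was an open choice and is documented here)
co-cluster categories and conditions. `correlation_degree()` builds one
correlation network per condition over its time points — per-condition
bars are what the degree/entropy comparison reports — with an edge when
$|r| > 0.98$ strictly; zero-variance profiles get correlation 0 (isolated)
rather than propagating `NA`.

## The synthetic-data generator

Real array data cannot be bundled, so `simulate_experiment()` generates
matrices whose *ordinal-pattern composition is known by construction*,
which is exactly what every downstream module consumes:

* Per gene, a pattern-count multiset (a partition of the 5 windows) is
  drawn from a mixture. The control default — probabilities 0.50, 0.10,
  0.02, 0.08, 0.12, 0.08, 0.10 over the partitions in ascending entropy
  order — mirrors the observed control-condition histogram: about half the
  genes at $PE = 0$, roughly 10% at the maximum, the strictly periodic 3-2
  realization rarest.
* `series_from_patterns()` inverts the codec: points are placed left to
  right, each drawn from the interval admitted by the requested pattern's
  sign constraints (changed steps move by `step_size` = 1 log2 unit,
  unchanged steps jitter uniformly within $\pm d_e/2$, bounded intervals
  take their midpoint). Consecutive windows share two points, so sequences
  must chain; geometrically infeasible requests (e.g. peak-end-above
  followed by valley-end-below at the default step size, which would need a
  gap of $\ge 2 d_e$ that the construction has already halved away) raise
  an error naming the first bad window, and the samplers simply redraw.
* The stress condition draws from the same mixture exponentially tilted
  toward partitions with more distinct patterns
  ($w_k \propto p_k e^{s(\text{parts}_k-1)}$); the default tilt $s = 0.3$
  raises mean PE by about 0.4, within the 0.11–0.48 range seen across real
  stress conditions. Replicate noise is additive Gaussian
  (`noise_sd` = 0.1, the scale of observed replicate differences);
  `simulate_replicate_noise()` separately generates replicate pairs whose
  pooled absolute differences match a prescribed mean and s.d. exactly in
  distribution (gamma-distributed magnitudes, random sign).

What the generator does *not* emulate: transcriptome-wide correlation
structure (genes are independent given the mixture), amplitude distributions
beyond a Gaussian baseline, and any biological covariance between entropy
and gene features. Tests that pass on these data therefore validate the
*computations* — codec, entropy, tests, rankings, degree — not claims about
real transcriptomes.

## Numerical and degenerate-input conventions

Entropies are exact up to floating point (the suite checks a $10^{-12}$
tolerance against an independent Shannon computation); achievable-value sets
collapse duplicates at $10^{-9}$. Series shorter than 3 points, empty count
vectors, single replicates, mismatched gene sets, and 1-row biclustering
inputs are errors, not silent results. Sorting ties (expression filter,
`pe_sum` ranking, degree strata) always break by gene id. All randomness
flows through R's RNG: a `simulation_spec` seed makes generated matrices
bit-identical, and the pipeline reruns byte-identically from its manifest.

## Problem sizes

The bundled tests and the acceptance script run at desk scale by design:
the codec enumeration uses a 216-point grid, noise-threshold recovery uses
$10^5$ pooled differences, the pooled-spectrum check uses 21,797 simulated
series, group-shift detection uses 5,000 genes, enrichment calibration 100
random selections over 15 categories, and the construction/encoding
round-trip 1,000 random sequences. These sizes give comfortable statistical
resolution for every assertion made; nothing in the method depends on
larger inputs, and the array-scale constants (21,797 genes, drop 10,000)
appear only where the arithmetic itself is the point.

## Known limitations

* Window order is fixed at $n = 3$; longer windows are pointless at
  $t = 7$ and unsupported.
* Absolute PE values are comparable only within a sampling scheme; across
  schemes only the gene ranking is meaningful.
* The weak-ordering codec ignores the endpoint comparison except in
  peak/valley windows; alternative tie codecs exist but do not yield 13
  classes.
* Exact MWU enumeration is limited to small samples; large tied samples use
  the standard approximation.
* The generator's feasibility notion is tied to its greedy construction:
  a few sign-chainable sequences are rejected as infeasible at the default
  step size (they are resampled, never silently altered).
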