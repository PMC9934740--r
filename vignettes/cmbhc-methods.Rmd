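---
title: "Methods: time-lagged correlation clustering of CSF tracer transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-lagged correlation clustering of CSF tracer transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glymclust)
```

## The analysis model

A DCE-MRI study of glymphatic transport produces, per brain region
(ROI), a signal time course $S_i(t)$ sampled on a uniform frame grid.
The package treats the analysis as three stacked estimators.

**Signal change.** With $n_b$ pre-infusion baseline frames,
$\Delta S_i(t) = p\,\bigl(S_i(t) - \bar S_i^{\,\mathrm{base}}\bigr)$,
where the polarity $p \in \{+1, -1\}$ makes tracer uptake positive for
every agent class: gadolinium agents brighten T1-weighted images
($p=+1$) while isotopically labelled water shortens T2 and darkens
T2-weighted images ($p=-1$). Curves are then divided by
$\max_t \Delta S_{\mathrm{ref}}(t)$ of a designated infusion-site
reference ROI (the *input function*), which removes inter-animal
scaling. Pearson correlation is invariant to these positive affine maps,
so normalization affects reporting, not the clustering; this is asserted
in the test suite rather than assumed.

**Time-lagged cross-correlation.** For each ROI pair and each integer
frame lag $\ell$ with $|\ell| \le L$, the Pearson correlation
$r_\ell(i,j)$ is computed between the overlapping segments of
$\Delta S_i$ and the $\ell$-shifted $\Delta S_j$, each segment re-centred
and re-scaled *on the overlap*. The maximal cross-correlation
coefficient is $\mathrm{mCC}(i,j) = \max_\ell r_\ell$ and the lag time is
the maximizing $\ell$ times the frame interval, positive when $j$ lags
$i$. Re-centring per overlap (rather than one global normalization) was
chosen because shrinking overlaps otherwise inherit mean offsets from
the non-overlapping ends of the curves, which biases large-lag
correlations; the estimator is defined explicitly here because the
field's descriptions of the statistic usually leave it open.

**Clustering.** Dissimilarity $d = 1 - \mathrm{mCC} \in [0, 2]$ (no
clamping) feeds complete-linkage agglomerative clustering. Complete
linkage is monotone, so merge heights never decrease toward the root;
the implementation asserts this on every run. Reported clusters are the
maximal subtrees merging strictly below the threshold (default 0.4,
i.e. all-pairs mutual mCC > 0.6) with at least two members; remaining
ROIs are reported as singletons rather than forced into clusters — with
twenty anatomically heterogeneous ROIs there is no reason every region
must belong to a transport community.

## Multiscale bootstrap

Cluster confidence uses the multiscale bootstrap: time frames are
resampled with replacement at sizes $n_r = \mathrm{round}(r\,n)$ for a
grid of ratios $r$, the pairwise correlation matrix and dendrogram are
rebuilt per resample, and a node's $\mathrm{BP}_r$ is the fraction of
resampled dendrograms containing exactly its member set. On the probit
scale the theory predicts
$z_r \equiv \Phi^{-1}(1-\mathrm{BP}_r) = v\sqrt{r} + c/\sqrt{r}$; a
weighted least-squares fit (binomial variance weights) across scales
gives the approximately unbiased p-value
$\mathrm{AU} = 1 - \Phi(v - c)$. Scales where BP is exactly 0 or 1 carry
no information about the curvature term and are excluded from the fit;
when fewer than two informative scales remain the node is assigned AU 1
or 0 by the sign of its mean BP, the convention of the multiscale
bootstrap tradition. With a single configured scale no AU is computed
and BP is the raw resample frequency. AU estimates are only as good as
the fit behind them: with two informative scales the fit is an exact
interpolation and AU can be erratic even when BP is high, so five or
more scales (default: ten, $r = 0.5, \dots, 1.4$) are recommended.

Naive frame resampling would destroy the temporal ordering that the lag
search needs, leaving the resampled statistic undefined. The default
scheme therefore freezes each pair's lag at its full-data optimum and
recomputes the correlation of the aligned pair on the resampled frame
multiset (frames outside a pair's overlap are dropped, duplicates kept).
The alternative — plain zero-lag correlation on resampled frames, which
is what piping the dissimilarity into a stock correlation-distance
bootstrap would effectively do — is available as
`bootstrap_config(scheme = "plain")`. Neither mode is claimed to
reproduce any particular published AU values; the frozen-lag scheme is
the one consistent with the lagged dissimilarity.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `max_lag_frames` | $\lfloor n/2 \rfloor$ | frames | admits transport delays up to half the scan (~65 min on the 130-min protocol) with margin over the longest plausible delays |
| `min_overlap` | $\lceil n/2 \rceil$ | frames | similarity is never declared on less than half the series |
| `lag_mode` | symmetric | — | transport directionality is not assumed; a nonnegative-lag mode exists for analyses anchored at the infusion site |
| `threshold` | 0.4 | dissimilarity | clusters = groups with all-pairs mCC > 0.6 |
| `n_average` | protocol | frames | 6 for the 25-s water protocol (2.5-min resolution), 1 for the 5-min gadolinium protocol |
| `n_boot`, `scales` | 1000, $0.5{-}1.4$ | — | standard multiscale-bootstrap defaults |

Ties in the lag search (correlations within $10^{-12}$ of the maximum)
resolve to the smallest $|\ell|$, then the negative lag, so identical
curves deterministically return lag 0. Ties in the linkage resolve to
the lexicographically smallest pair of cluster representatives. Lags are
integer frame shifts only — reported lag times are multiples of the
frame interval, matching how such delays are read off in practice; no
sub-frame interpolation is attempted. Zero-variance overlap segments
make the correlation undefined at that lag and are excluded; a pair
undefined at every lag is an error. Curves entering one correlation
matrix must share a single uniform time grid — cross-protocol
comparisons (different frame intervals) are outside the statistic's
contract and rejected at the door.

## The synthetic phantom

Real data of this kind (per-animal 4D series) are rarely deposited, so
validation rests on a generator that produces the statistical structure
the analysis assumes, with known truth.

Each ROI's noise-free curve is the infusion boxcar (10 µL at 1 µL/min,
started after the baseline frames) convolved with an Erlang impulse
response — a serial cascade of `n_stages` linear compartments with rate
`rate_const` — optionally mixed with a second parallel branch
(a fast CSF route plus a slow parenchymal route yields the biphasic
shapes seen in periventricular regions), shifted by an onset `delay`,
normalized to unit peak and scaled by `amplitude` on a baseline offset.
The mean transport delay of an ROI is
`delay + Σ branch-weight × n_stages/rate_const`, and ground-truth lags
are differences of these delays; the `delay_line` phantom plants lags of
exactly 0, 1 and 3 frames this way.

The `four_cluster` phantom (20 ROIs; sizes 6, 5, 5, 4) uses four kinetic
archetypes: an infusion-site spike (1 stage, 1.5/min), a slow
parenchymal ramp (2 stages, 0.008/min), a delayed deep-brain bump
(8 stages, 0.25/min, 45-min onset), and a biphasic periventricular
mixture (0.3 spike + 0.7 slow plateau). These were selected by a
numerical design search minimizing the maximum pairwise mCC *under
optimal lag alignment*: on a 52-frame series with a ±26-frame search
window, the lag maximization aligns any two smooth unimodal curves so
well that bump-versus-bump archetypes correlate above 0.8, and the
maximum over 53 lags of two independent noisy signals alone has an
expectation near 0.45. Mutually distinguishable clusters therefore
require shape differences beyond time shifts — washout versus plateau
versus late ramp versus biphasic. Per-ROI lognormal rate jitter
(sd 0.06) and amplitude spread (±10% around cluster means of 110, 100,
90 and 130 a.u.; CSF-adjacent regions enhance most strongly) personalize
the curves; measurement noise is iid Gaussian with default sd 10 a.u.,
i.e. 10% of the nominal peak — the protocols publish no SNR figure, so
this is a package choice, kept equal to the noise level at which lag
recovery is specified. Within-cluster mCC of the noise-free generating
curves exceeds 0.8 by construction (asserted in the tests).

What the generator does *not* emulate, and what passing tests therefore
do not establish for real data: temporally autocorrelated physiological
noise and drift, motion and registration error, partial-volume mixing
between neighbouring ROIs, nonlinearity between signal change and
tracer concentration, and inter-animal kinetic variability beyond the
jitter model. Fixtures are generated directly on the 6-average analysis
grid (52 frames × 2.5 min, 2 baseline frames); the raw 312-frame
protocol is exercised by the averaging and volume round-trip tests.

## Decisions on genuinely open points

* **Normalization reference.** Whether the input-function region is one
  of the atlas ROIs or a separate manual mask is left open in practice;
  here it is any designated label (`reference_roi`).
* **Group curves.** For multi-subject work, the mean of per-subject
  normalized curves is the default ordering (normalize, then average);
  averaging before normalizing is also possible by composing the same
  primitives. Pearson invariance makes the choice irrelevant to mCC for
  a single subject.
* **tMIP.** Computed on polarity-corrected signal change, not raw
  signal, so the map reads as "peak uptake" for all agents.
* **Lag window.** Symmetric by default; restricting to nonnegative lags
  encodes a directionality assumption the data may not support.
* **Singletons.** The threshold cut reports them separately; forcing
  every ROI into a cluster would fabricate transport communities.

## Problem sizes and numerical tolerances

The test suite checks the lag estimator against a brute-force
Pearson-by-sums scan (200 random pairs, length ≤ 64, agreement to
$10^{-12}$), the linkage against a naive max-distance reference (500
random matrices, n ≤ 6, exact) and against `stats::hclust` heights, lag
recovery on 200 noisy replicates of the planted-lag phantom (±1 frame),
cluster recovery on 100 replicates of the 20-ROI phantom (adjusted Rand
index 1 at the 0.4 cut), bootstrap calibration at $B=100$ with scales
{0.8, 1, 1.2}, and exact round trips for every reader/writer pair
(NIfTI double precision; Newick heights to $10^{-9}$). These sizes keep
the full suite under a few minutes while leaving the stochastic rates
(≥ 95%) far from their pass boundaries.

## Known limitations

The lag statistic has a spurious-correlation floor set by the lag
search itself (≈ 0.4–0.5 for 52-frame series with a ±26-frame window),
so mCC values in that range between unrelated regions are expected, not
evidence of transport; the 0.6 mCC cut sits above this floor. Integer
frame lags quantize delay estimates to the frame interval. AU p-values
inherit the usual caveats of the multiscale bootstrap (asymptotic
normal-curvature model, unstable with few informative scales). The
bootstrap treats frames as exchangeable given the frozen alignment,
which understates uncertainty under strong temporal autocorrelation.
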