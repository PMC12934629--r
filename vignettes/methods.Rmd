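---
title: "Multi-level integration and segregation metrics for brain states: models, parameters and design choices"
author: "BrainStates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Altered states of consciousness are thought to move the brain along an
integration–segregation axis: psychedelics toward hyper-integrated, globally
coupled dynamics, and sleep or anesthetic sedation toward fragmented, locally
constrained dynamics. BrainStates quantifies this axis from parcellated BOLD
time series with three complementary metrics, each evaluated at three spatial
levels (whole brain; the unimodal–attention–transmodal cortical hierarchy;
and the seven canonical networks VIS, SMN, DAN, VAN, LIM, FPN, DMN), and then
asks whether the metrics agree on a single ordering of conscious states.

## The three metrics

**Functional connectivity (FC).** Pearson correlation between ROI time
series. Level summaries average raw correlations (no Fisher z-transform, and
negative correlations are retained): the whole-brain value pools all unique
ROI pairs excluding self-connections; hierarchy contrasts pool pairs within
and between the unimodal (VIS+SMN), attention (DAN+VAN) and transmodal
(FPN+DMN) classes, with limbic ROIs excluded from the hierarchy level only;
the network level is the 7×7 matrix of block means. The global
within-/between-network scalars are by default the unweighted means of the 7
diagonal and 21 off-diagonal network entries, the same convention the
efficiency analysis states explicitly; because pooling ROI pairs directly is
an equally natural reading for FC, `summarizeLevels(..., pooling = "pairs")`
exposes the alternative (the two differ only when network sizes differ).

**Topological integration (EFF).** Weighted global efficiency
`Eg = mean(1/d(i,j))` over node pairs, after the logarithmic
weight-to-distance transform `len = -log(w)`: strong correlations are short
edges, non-positive correlations are removed (infinite length), and weights
at or above 1 are clipped to `1 - 1e-10`. Shortest paths come from
Floyd–Warshall; unreachable pairs contribute zero to the numerator but stay
in the denominator so that Eg is comparable across graphs of equal size. To
separate topology from overall coupling strength, every reported value is
`Eg_norm = Eg / mean(Eg_rand)` over weight-shuffled surrogates: the null
permutes the upper-triangular weight multiset (preserving the weight
distribution exactly, not the degree sequence) and is applied to the
submatrix before the distance transform. Between-set analyses build the
joint submatrix of the two node sets, close it under shortest paths (relays
through within-set edges are allowed), and average inverse distances over
cross-set pairs only — within-set pairs are excluded from numerator and
denominator. The number of null realizations is a precision knob, not a
scientific parameter: the default is `nNull = 100` (Monte-Carlo SE of
`Eg_rand` well under 1% on pilot graphs); replicate studies in the test
suite use 50 to keep total runtime proportionate, and the uniform-graph
identity `Eg_norm = 1` is exact at any `nNull`. The mean (not median) across
realizations defines `Eg_rand`.

**Interaction complexity (CPLX).** Time series are segmented into
non-overlapping 5-frame windows (trailing remainder dropped; the window is
defined in frames, not seconds). For node sets S1, S2 the windowed
cross-product `M = X1' X2` is mean-centered by its scalar global mean and
decomposed by SVD; the statistic is the normalized entropy of the singular
spectrum, `C = -(1/log2 K) * sum p_k log2 p_k`, `p_k = s_k / sum s_j`, with
`K = min(|S1|, |S2|)` counting all singular values of the economy
decomposition (zeros contribute nothing to the sum but fix the scale; a
rank-truncated variant would change the scale of C and is deliberately not
the default). C is 0 when one interaction mode dominates and 1 when all K
modes contribute equally. Windows are not re-standardized — the per-ROI
whole-run standardization is relied upon, and centering is applied only to
M. All-zero windows (possible only in degenerate inputs) are skipped rather
than propagating an undefined value; the per-recording value is the
arithmetic mean over valid windows.

A note on dimensionality: a 5-frame window bounds the rank of the uncentered
cross-product at 5 (centering can add 1), so for large node sets at most 6
of the K singular values are nonzero. The implementation exploits exactly
this: the centered cross-product factors through a (width+1)-dimensional
core, whose SVD gives the full nonzero spectrum at a small fixed cost. The
fast path is pinned against the direct SVD in the tests.

## Effect sizes, ranking, and the state ordering

Every altered state is compared with its own-subject baseline by paired
two-sided t-tests, summarized as Cohen's d for paired samples in the
difference-score convention `d = mean(diff)/sd(diff)` (the averaged-SD
convention is available as an option), with
`se_d = sqrt(1/n + d^2/(2n))` and Benjamini–Hochberg FDR correction.
The FDR family is all states × contrasts within one metric × level panel —
the natural per-panel reading — and is configurable (`metric`, `all`,
`none`) because the true family is a judgment call.

For each of the 27 analysis–metric pairs (3 global + 6 hierarchy analyses ×
3 metrics) the nine states are ranked by signed d (rank 1 = most negative);
ties get average ranks. The composite rank is the plain mean of a state's 27
ranks — all pairs weighted equally, the direct reading of averaging across
analysis–metric pairs. Agreement of each pair with the composite uses
Kendall's tau-b (tie-corrected, since average-rank ties occur).

The network-level effect sizes form an 84 × 9 feature matrix (3 metrics × 28
upper-triangular network cells, metric-major order, diagonal included).
PCA is applied **without centering**: a zero effect is scientifically
meaningful and must stay at the origin, so the decomposition is the SVD of
the raw matrix, with explained variance defined as squared singular value
over the total sum of squares (not variance about a mean — the two differ,
and the uncentered definition is the only coherent one here). States are the
observations, features the variables. Each component's sign is fixed by
making its largest-magnitude loading positive; the axis orientation is
otherwise arbitrary, so ordering comparisons accept either orientation.

## The synthetic cohort generator

The generator exists so that every downstream stage is testable without
neuroimaging data. It emulates the *structure* of a paired multi-dataset
design: for each altered state, `nSubjects` subjects each contribute one
baseline and one altered recording; subjects are independent across states.

Each recording is a stationary multivariate AR(1) series whose marginal
covariance is a block-structured correlation matrix: `wBase` within the
seven networks, `bBase` between them, shifted per state by
(`deltaWithin`, `deltaBetween`) and per subject by a scalar random effect
(SD `subjectSd`) added to both couplings and shared across that subject's
two conditions — this shared effect is what makes the paired design
strictly more powerful than an unpaired one. Couplings are clipped into
(−0.99, 0.99); positive definiteness is verified by Cholesky with a
diagonal jitter of at most 1e-6 before failing, so a silently distorted
target correlation is impossible. Optional observation noise is additive
(`noiseScale` × unit-variance white noise; as noise grows all correlations
shrink toward zero), and every ROI is finally standardized to zero mean and
unit variance, mirroring the preprocessing contract of real pipelines.

**Why AR(1) is part of the state model.** Static covariance shifts alone
cannot reproduce the complexity contrast. After standardization, lowering
couplings necessarily raises idiosyncratic variance, which *spreads* the
windowed singular spectrum and raises C — the wrong direction for sedation.
What distinguishes low-arousal states empirically is constrained, slow,
stereotyped dynamics; the generator encodes this as a per-state AR(1)
coefficient `arPhi`. High `arPhi` reduces the effective number of
independent frames per 5-frame window, concentrating the interaction
spectrum and lowering C, without changing the stationary covariance (so FC
and efficiency targets are untouched in expectation). Baseline uses
`arPhi = 0.30`; psychedelic states are faster (0.13–0.26), sleep and
sedation slower (0.35–0.62), graded with dose.

**Default study conditions.** 70 ROIs in seven networks of 10, 150 frames,
20 subjects per state, `wBase = 0.45`, `bBase = 0.20`, `subjectSd = 0.02`,
and nine states in three classes: psychedelic (LSD, PSIL, KTM, N2O —
between-network coupling up, within-network coupling down, dynamics
faster), sleep (N1, N2) and propofol sedation (PPF1.9/2.4/2.7) — both
couplings down, with the between-network coupling falling *proportionally
more* than the within-network coupling, and dynamics slower. Within the
sedation class the within-network deltas are nearly flat and the
between-network deltas are steeply graded: deep within-coupling drops would
weaken the efficiency null model's weight pool and push the normalized
between-network efficiency back toward 1, cancelling the segregation
signal, whereas a steep between-coupling gradient keeps that contrast both
negative and monotone in dose. Several of these numbers deserve
justification:

* `bBase = 0.20` rather than a smaller value: sedation must lower the
  between-network coupling proportionally more than the within-network
  coupling for the *normalized* between-network efficiency to fall (the
  null-model normalization divides out overall strength, so only the
  relative weakening of cross edges matters), and the block covariance must
  remain positive definite when the subject effect pushes the between
  coupling down. With `bBase = 0.20` the most extreme state keeps its
  smallest eigenvalue more than five subject-effect SDs away from zero.
* `subjectSd = 0.02`: large enough to dominate unpaired between-subject
  variance (making the paired design matter), small enough that positive
  definiteness is never at stake.
* Dose grading is geometric (adjacent in-class deltas differ by a factor of
  roughly 1.5–1.7 where the positive-definiteness floor allows; where it
  does not — the sedation between-network deltas — the separation is
  carried by the within-network deltas and the AR-phi gaps instead). The
  realized effect size of a whole cohort fluctuates with relative SE about
  `1/sqrt(2n) ≈ 0.16` at n = 20, and the composite-rank and PC1
  aggregations weight the same noisy cells differently; if adjacent doses
  are closer than this fluctuation, the two aggregations break the
  near-tie differently and the intended end-to-end recovery (PC1 ordering =
  composite-rank ordering) fails for uninteresting reasons. The geometric
  spacing keeps adjacent states resolvable at the reference sample size.

What the generator does **not** emulate: hemodynamics, scanner noise
spectra, motion, heterogeneous TRs and durations across datasets (a single
frame count stands in for the 6–16 minute range of real recordings),
network-pair-specific coupling shifts (a single within/between pair per
state; pairwise deltas would be a config extension), and any spatial
embedding. Consequently, passing tests demonstrate that the *pipeline*
recovers planted multi-level structure from realistically sized, noisy,
paired cohorts — they do not validate the neurobiological claims on real
data.

## Numerical and degenerate-input policy

* Correlation matrices are forced exactly symmetric with unit diagonal;
  zero-variance ROI series are an explicit error naming the ROI.
* `-log` transform: weights ≤ 0 become absent edges; weights ≥ 1 are
  clipped to `1 - 1e-10`; unreachable pairs contribute 0 to efficiency.
* `Eg_rand = 0` (possible only when the masked subgraph is empty of
  positive weights) flags the normalization as undefined (`NA`) rather than
  dividing by zero; undefined cells propagate to an `undefined` flag in the
  effect table, and ranking refuses tables containing them.
* Zero-variance paired differences flag the effect as undefined instead of
  producing infinite d.
* Ties in ranking receive average ranks; constant rankings yield an
  undefined tau.
* All stochastic stages (simulation, null shuffles) draw from R's RNG;
  the pipeline derives one seed per stage from the master seed by stable
  labels, so adding a stage never perturbs another stage's stream and any
  stage can be re-run in isolation bit-identically.

## Problem sizes used by the automated checks

The test suite exercises oracle equivalences on graphs of up to 30 nodes,
level summaries on 14–28 ROI toys, statistical calibration on 500 replicate
zero-delta cohorts at the reference design (70 ROIs, 150 frames, 20
subjects), and mirror-image recovery on 20 replicate nine-state cohorts with
25 efficiency nulls per analysis; the acceptance script recomputes the
headline quantities from one reference cohort at the default 100 nulls plus
a 300-replicate calibration. These sizes are the package's chosen reference
conditions; all of them are configurable upward.

## Known limitations

* The efficiency null model preserves the weight distribution only; degree-
  preserving nulls are out of scope by design.
* The between-set efficiency mask excludes within-set pairs from the
  average but still routes paths through them; a stricter variant that
  removes within-set edges entirely would answer a different question.
* `K = min(|S1|, |S2|)` makes C comparable across set sizes only through
  the `log2 K` normalization; comparisons across very different set sizes
  should still be made within, not across, analysis levels.
* With 5-frame windows the spectrum has at most 6 nonzero modes, so for
  large sets C lives well below 1; this is a property of the statistic, not
  a bug, and matches the fixed-window design.
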