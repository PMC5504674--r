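---
title: "Estimating classification complexity of myoelectric feature spaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating classification complexity of myoelectric feature spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Myoelectric pattern recognition (MPR) decodes intended movements from
surface EMG: descriptive features are extracted from overlapping time
windows of the multi-channel signal and fed to a classifier.  How well this
works depends almost entirely on how separable the movements are in the
chosen feature space.  A *classification complexity estimate* (CCE)
quantifies that separability directly from the labeled feature cloud,
before any classifier is trained.  This is useful for three things:
selecting feature sets without running a full training sweep, predicting
achievable accuracy, and spotting faulty acquisitions (one badly recorded
movement that collides with everything else).

`emgcce` implements four estimator families, each reported per movement
(*individual result* — which classes conflict) and averaged over movements
(*average result* — how good the feature space is as a whole):

* **Separability index (SI)** — for each movement, the distance between
  Gaussian models of that movement and its *most conflicting neighbor*
  (the nearest other class), under one of five distance definitions.
* **Nearest neighbor separability (NNS)** — a nonparametric,
  proximity-weighted measure of same-class dominance among each point's
  `k` nearest neighbors.
* **Purity** — a multiresolution cell-partition measure of single-class
  dominance.
* **Repeatability index (RI)** — the drift of a movement's feature
  cluster between recording repetitions.

## Gaussian models and the five distance definitions

Every class (movement) is summarised by its sample mean vector $\mu$ and
sample covariance $S$ ($n-1$ denominator; `fit_class_models()`).  Singular
or ill-conditioned covariances (condition number above $10^{12}$) receive a
relative ridge ($10^{-8}\,\mathrm{tr}(S)/d$ on the diagonal, escalated
tenfold until positive definite) — this matters in practice because several
EMG features are nearly collinear across channels.

With $\Delta\mu = \mu_1 - \mu_2$ (index 1 = the considered movement,
index 2 = the compared movement) and the pooled $S = (S_1 + S_2)/2$,
`class_distance()` computes:

| definition | value |
|---|---|
| Mahalanobis | $\tfrac12\sqrt{\Delta\mu^\top S_1^{-1}\Delta\mu}$ |
| modified Mahalanobis | $\tfrac12\sqrt{\Delta\mu^\top S^{-1}\Delta\mu}$ |
| Bhattacharyya | $\sqrt{-\tfrac12\ln \mathrm{BC}}$ |
| Hellinger | $1 - \mathrm{BC}$ (the squared Hellinger distance) |
| Kullback–Leibler | $\tfrac12\big(\mathrm{tr}(S_1^{-1}S_2) + \Delta\mu^\top S_1^{-1}\Delta\mu - d + \ln\tfrac{\det S_1}{\det S_2}\big)$ |

where the Gaussian Bhattacharyya coefficient is
$\mathrm{BC} = \frac{(\det S_1)^{1/4}(\det S_2)^{1/4}}{(\det S)^{1/2}}
\exp\!\big(-\tfrac18 \Delta\mu^\top S^{-1}\Delta\mu\big)$.

Three numerical/definitional choices deserve a note:

* **Bhattacharyya scale and sign.**  We define the Bhattacharyya value
  through the coefficient, $D_B = -\tfrac12\ln\mathrm{BC}$, and return its
  square root.  This keeps the two coefficient-based definitions mutually
  consistent ($D_H^2 = 1 - e^{-2D_B}$, an identity the test suite asserts
  on a thousand random model pairs) and uses the standard positive sign on
  the $\tfrac12\ln(\det S/\sqrt{\det S_1 \det S_2})$ term, which is
  nonnegative by the concavity of $\log\det$; a negative sign would put
  negative numbers under the square root.  Because the transform is
  monotone, every rank-based use (SI ranking, correlations, best sets) is
  unaffected by the scale choice.
* **Hellinger denominator.**  The denominator of the coefficient is
  $(\det S)^{1/2}$ with the pooled $S$ — the only form for which
  $D_H^2 = 1-\mathrm{BC}$ holds and the value stays in $[0,1]$.
* **KL direction.**  The formula above is the divergence of the compared
  distribution from the considered one, $\mathrm{E}_2[\log p_2/p_1]$
  (verified against a Monte-Carlo log-density-ratio estimate in the
  tests).  Mahalanobis and KL are therefore asymmetric; SI takes each
  class's minimum over its own row of the distance matrix.

**SI aggregation.** The individual result of class $i$ is
$\min_{j\ne i} D(i,j)$ with the arg-min reported as the most conflicting
neighbor; the average result is the *mean* over classes (rather than the
bare sum) so values are comparable across different numbers of classes.
$K$ is recorded in the result so the sum form is recoverable.

SI under every definition is invariant to invertible affine maps of the
feature space, which means it is unaffected by feature scaling — one reason
it is cheap to use directly on raw, wildly differently scaled EMG features.

## Nearest neighbor separability

For target point $p_t$, let $b(p_t, p_i) = 1$ when the $i$-th nearest
neighbor (Euclidean distance, the point itself excluded) shares $p_t$'s
class.  The dominance of the target is the harmonically weighted mean

$$d_t = \Big(\sum_{i=1}^k \tfrac1i\Big)^{-1} \sum_{i=1}^k
\frac{b(p_t,p_i)}{i},$$

and NNS is the mean of $d_t$ over all $N$ points (per class for the
individual results).  Ties in neighbor distance are broken by point index
after the distance sort, so results are reproducible on data with
duplicated coordinates.

The default `k = 120` suits guided recordings in which each movement
contributes on the order of 120 windows — `k` is meant to be about the
maximum number of same-class neighbors available.  For smaller data sets
the package clamps `k` to $N-1$ with a warning, but the better choice is to
pass `k` near the per-class sample count minus one (the synthetic studies
below use `k = 59` with 60 points per class).  No feature normalization is
applied by default (NNS on raw features is what the estimator is defined
on); a z-score option exists because Euclidean distance on raw EMG features
is dominated by the largest-scale feature.  NNS is invariant to translation
and uniform scaling, but not to general affine maps.

## Purity and repeatability index

**Purity** bounds each dimension by the data's $[\min,\max]$, splits it
into $r$ equal bins (top edge inclusive) for each resolution
$r = 1,\dots,5$, and scores each non-empty cell by its largest class
fraction.  The resolution's value is the occupancy-weighted mean over
cells, and the overall value the mean over resolutions.  For the
individual result of class $C$ we weight, over the cells containing $C$,
the fraction of the cell belonging to $C$ by the cell's total occupancy —
"occupancy" is deliberately the whole cell's population, so a class sitting
in crowded mixed cells scores low.  A guard refuses $r^d$ beyond $10^7$
cells; purity is meant for low-dimensional (projected or few-feature)
spaces.

**RI** fits a Gaussian to each repetition of each movement and reports, per
movement, the mean over later repetitions $j$ of
$\tfrac12\sqrt{(\mu_j-\mu_1)^\top S_1^{-1} (\mu_j-\mu_1)}$ — half the
Mahalanobis distance, matching SI's convention so the two are on the same
scale.  High RI flags inconsistent recording sessions (electrode shift,
fatigue) rather than inseparable classes.

## The processing pipeline

`window_signal()` follows the standard guided-recording protocol: per
movement, each contraction's initial and final 15% are discarded
(`trim_contraction()`; delayed response and anticipatory relaxation), the
trimmed repetitions are concatenated, and 200 ms windows are cut every
50 ms.  Index arithmetic is 0-based half-open with round-half-away-from-
zero, so a 3 s contraction at 2 kHz keeps exactly its central 70%
(4200 of 6000 samples) and a 6000-sample concatenation yields
$\lfloor(6000-400)/100\rfloor + 1 = 57$ windows.  Windows may span the seam
between two repetitions of the same movement (the data are concatenated
before windowing); a window's repetition label is the repetition containing
its first sample.

`split_features()` partitions rows per class into training (40%),
validation (20%) and testing (40%) with largest-remainder rounding, so 100
rows per class split exactly 40/20/40.  Cross-validation is Monte-Carlo
style: `n_randomizations` (default 10) independent seeded re-randomizations
of the whole split, not ten disjoint folds.

The 17-feature bank (`feature_ids()`) implements the usual time-domain
descriptors (mean absolute value, standard deviation, variance, waveform
length, RMS, zero crossings, slope sign changes, power, difference absolute
mean, maximum fractal length), two fractal dimensions (Higuchi with
`kmax = 8`; Katz), cardinality and rough entropy (threshold
$\tau = 0.01(\max - \min)$ on sorted adjacent differences; the entropy is
the binary entropy of the distinct-vs-indistinct fraction), and three
spectral descriptors on the rectangular-window single-sided DFT (spectral
waveform length, mean and median frequency).  Zero-crossing and slope-sign
counts use a deadband threshold `eps` that defaults to 0 (strict sign
changes), appropriate for 14–16-bit ADC data; raise it for noisy
recordings.  Constant windows never produce NaN: counts and entropies are
0, fractal dimensions 1, spectral statistics 0.  Exact lineages of the
cardinality, rough-entropy and Katz-dimension variants differ between
toolboxes; they are isolated behind `extract_feature()` so a different
variant is a one-function change.

## Classifiers

Ground-truth accuracy comes from three families: LDA (pooled-covariance
linear discriminant), a single-hidden-layer MLP, and an SVM with quadratic
polynomial kernel.  Topologies: `single` (one multiclass machine), `ovo`
(all pairwise machines, majority vote, ties broken by summed posterior
scores — used with LDA), `ami` (label power set: every movement
combination is its own class), and `mix` (one binary machine per
individual movement; a prediction is correct only when the entire output
vector matches; the all-zero vector decodes to rest).
`movement_label_space()` holds the AMI–MIX bijection; three degrees of
freedom with two directions each plus inactivity enumerate $3^3 = 27$
combined classes.

The MLP uses `hidden_units = max(10, number of outputs)` and logistic
outputs.  The underlying single-hidden-layer implementation has no
per-epoch validation callback, so the validation set instead selects the
weight decay from a small grid — the same role (held-out data limits
capacity) expressed as model selection rather than early stopping.  All
training is deterministic given the spec's seed.

## Synthetic data: what it emulates and what it does not

`synth_session()` produces an EMG surrogate: zero-phase band-pass-filtered
(default 20–500 Hz, 4th-order Butterworth, filtfilt) white Gaussian noise,
amplitude-modulated per segment — during movement $m$'s contraction,
channel $c$ carries the unit-variance carrier scaled by
`activation[m, c] + noise_floor`; rest segments carry the floor alone.
Defaults mirror a typical individual-movement acquisition: 11 movements,
4 channels, 3 repetitions, 3 s contraction and 3 s rest at 2 kHz.  This
reproduces exactly the cues the feature bank measures (per-channel
amplitude patterns and an EMG-like spectrum) and nothing else: no
motor-unit structure, no electrode crosstalk beyond the activation matrix,
no fatigue drift, no movement-transition dynamics.  Passing tests on this
surrogate therefore demonstrate the pipeline's correctness and the
estimators' behavior under controlled separability — they do not certify
performance on human recordings.

`synth_clouds()` draws labeled multivariate-normal clouds directly in
feature space (repetition labels block-wise in draw order, with an
optional per-repetition mean drift to exercise RI), and
`separation_sweep()` scales all class means about their centroid so
separation 0 collapses every class onto one distribution (chance level)
and larger values move them apart along fixed directions.

## Study procedures and the synthetic benchmark sizes

`correlate()` computes Spearman's rho on tie-corrected ranks with a
two-sided t-approximation p-value; `best_sets()` enumerates all
$\binom{F}{m}$ feature subsets and ranks them by average-result CCE
(higher predicts higher accuracy); `compare_sets()` is a paired Wilcoxon
signed-rank test whose exact null (for up to 25 effective pairs) is
computed by convolution over doubled midranks, which — unlike the stock
implementation — stays exact when absolute differences tie;
`conflict_report()` tabulates how often each movement is another's most
conflicting neighbor; and `channel_correlation_determinant()` returns the
determinant of the across-channel correlation matrix of one feature's
window sequence (1 = independent channels, 0 = fully redundant).

The package's own validation (the test suite and
`scripts/acceptance.R`) uses desk-scale problem sizes chosen to keep the
whole suite fast while leaving no statistical ambiguity: 3 classes in 2
dimensions with 60 points per class, 30 separation steps in $[0, 1]$ from
base means 4 units apart, 10 seeds (median Spearman rho between LDA
accuracy and both SI and NNS lands near 0.97), and a 6-feature bank with
an informative pair planted 3 standard deviations apart (both estimators
recover it in 10/10 seeds).  Brute-force oracle comparisons run on 50
random instances with $N \le 200$, $d \le 3$, $K \le 4$ at $10^{-10}$
tolerance.

## Input/output

The native session format is a directory with `session.json` (metadata)
and `signal.csv` (one row per sample, one column per channel) —
inspectable and language-neutral.  MAT-file import
(`read_biopatrec_mat()`) maps recording-session structs leniently (field
names vary across releases) through a purpose-written reader for
uncompressed Level-5 MAT files; compressed elements are rejected with an
informative message.  A thin command-line front end
(`inst/cli/emgcce.R`) chains the stages over files: `synth`, `extract`,
`complexity`, `select`, `classify`, `evaluate`.

## Known limitations

* Gaussian SI assumes unimodal, roughly elliptical class clouds; it is
  blind to multimodal structure that NNS and purity see.
* NNS is exact ($O(N^2)$ distances); it targets data sets of a few
  thousand windows, not millions of points.
* Purity is only meaningful in low dimensions; with the full
  17-feature × multi-channel space it must be applied to projections.
* The MAT importer reads the common uncompressed struct layout only.
* Real-time (completion-time) evaluation of the estimators requires
  interactive acquisition hardware and is out of scope.
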