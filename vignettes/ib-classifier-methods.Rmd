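---
title: "Information-bottleneck classification rules for SSVEP BCIs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-bottleneck classification rules for SSVEP BCIs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibbci)
```

## The problem

A steady-state visual evoked potential (SSVEP) brain-computer interface
shows the user several targets flickering at distinct frequencies; the
attended target's frequency and its harmonics appear in the occipital EEG.
After feature extraction, each sliding-window sample carries one
real-valued feature per candidate class (a spectral power, a canonical
correlation, or a discriminant score), and the classifier must map the
feature vector to a class — or abstain. Abstaining is cheap in this
setting: an overlapping sliding window advances every `s` seconds, so a
rejected sample costs `s` seconds of delay rather than an error.

Most SSVEP systems classify with the *argmax rule* (pick the class whose
feature is largest). `ibbci` instead learns the classification rule from
calibration data by solving an information bottleneck: the learned rule
directly trades off how much class information each prediction carries
against how coarse the rule is, which is the quantity the interface's
performance measure — the information transfer rate — actually depends on.

## Performance measures

With `N` targets and accuracy `a` on classified samples, the classical
per-prediction rate is Wolpaw's

$$\mathrm{ITR}_s = \log_2 N + a \log_2 a + (1-a)\log_2\frac{1-a}{N-1},$$

which is the mutual information of a *doubly symmetric* channel. Real
confusion matrices are rarely doubly symmetric, so the package's primary
measure replaces $\mathrm{ITR}_s$ with the plug-in mutual information
$I(P;C)$ between predicted and true class, estimated from the confusion
table over classified samples. Both are converted to bits/min through the
mean detection time

$$\mathrm{MDT} = w + \left(\frac{1}{P(\text{classified})} - 1\right) s
  + t_{\text{gaze}},$$

where `w` is the window length, `s` the step, and `t_gaze` an optional
gaze-shift constant (≈ 0.5 s when target switching is modelled; the
default is 0). `mi_from_confusion()` excludes the reject column and
renormalises, because MDT already charges abstentions via the retry term;
an `(N+1)`-outcome variant is available behind `include_unclassified =
TRUE` for sensitivity analyses. When every sample is rejected the MDT is
infinite and both rates are reported as 0.

`itr_wolpaw()` equals `mi_from_confusion()` exactly on doubly symmetric
tables with uniform classes — the test suite asserts the identity to
1e-12 — so the two rates coincide precisely when the classical
assumptions hold.

## Discretisation

The bottleneck solver needs discrete variables, so each feature is binned.
Equal-width bin edges span the training minimum and maximum of the
feature. The bin *count* applies an estimator per class-conditional sample
and averages over classes, rounding halves up:

* `fd`: Freedman–Diaconis, width $2\,\mathrm{IQR}/n^{1/3}$, count =
  range/width rounded up. The printed form of this estimator is a bin
  *width*; the package derives the count from it. Preferred when there
  are hundreds of samples per class.
* `sturges`: $\lceil \log_2 n \rceil + 1$, for smaller calibration sets.

Bins are half-open $[l, h)$ with the last bin closed; at prediction time
out-of-range values clamp into the edge bins rather than being rejected,
which keeps train/test treatment consistent with the skew-normal tail
handling below. Degenerate inputs (zero IQR or zero range) fall back to a
single bin.

Class-conditional bin probabilities $P(B_i = b \mid C_k)$ come from either

* `histogram`: relative counts, zero-count bins kept at 0 (no smoothing —
  impossible cells are handled downstream by support filtering), or
* `skew-normal`: a maximum-likelihood skew-normal fit per
  (feature, class), with bin probability $F(h) - F(l)$ and the tail mass
  beyond the extreme edges absorbed into the first and last bins so each
  row sums to 1 exactly. Fitting smooths the probability estimates, which
  in practice slightly improves downstream rates. Whether to fit by
  maximum likelihood was an open choice; MLE was selected for its
  standard asymptotics, with a moment-based start and a flagged normal
  (shape 0) fallback if the optimiser fails. The skew-normal CDF is
  evaluated through Owen's T function with adaptive quadrature (the
  reciprocal identity keeps the quadrature interval inside [0, 1], so the
  evaluation is accurate to ~1e-10 for any shape).

## The joint model

Binned features are assumed conditionally independent given the class:

$$P(X = (b_1,\dots,b_F) \mid C_k) = \prod_i P(B_i = b_i \mid C_k),$$

giving the joint $p(x, c)$ over the flattened bin vector (row-major
mixed-radix index, feature 1 most significant) and the class. The class
prior defaults to empirical training frequencies (uniform for balanced
designs; a uniform override exists). The grid is dense with a configurable
cell cap (default $10^6$) because its size grows exponentially in the
number of features — the method targets interfaces with ~5 classes or
fewer. Cells with marginal probability below `pmin` (default 1e-12) are
excluded from the support; samples landing there are unclassifiable. The
threshold is configurable because the exact cut-off for "close to zero"
probability mass is a design choice, not a derived quantity.

## The generalized information bottleneck

The encoder $q(p \mid x)$ minimises

$$H(P) - \alpha H(P \mid X) - \beta I(P;C)$$

subject to the Markov chain $C - X - P$. $\alpha = 1$ gives the original
bottleneck ($I(P;X) - \beta I(P;C)$), $\alpha = 0$ the deterministic
bottleneck, whose optimal encoder is a function of $X$ and therefore *is*
a classification rule. The fixed-point iteration scores each pair as

$$\ell(x, p) = \log_2 q(p) - \beta\, \mathrm{KL}\!\left[p(c \mid x)\,\|\,
q(c \mid p)\right],$$

sets $q(p \mid x) \propto 2^{\ell(x,p)/\alpha}$ (hard argmax at
$\alpha = 0$, ties to the lowest cluster index for determinism), then
refreshes the marginal and the decoder. The objective is checked to be
non-increasing across iterations; convergence is declared when it changes
by less than `tol` (default 1e-8 bits) or after `max_iter` (default 1000)
iterations. Because the problem is non-convex, the solver restarts from
`restarts` (default 20) seeded random initialisations — Dirichlet rows
for $\alpha > 0$, random hard assignments for $\alpha = 0$ — and keeps
the lowest objective. Restart count and tolerance were open choices; the
defaults make the $\alpha=0$ solver agree with exhaustive enumeration of
all deterministic encoders on ≥ 95 of 100 random small instances
(`exhaustive_dib_oracle()` is shipped precisely to make that check
routine). Clusters may die during iteration; solutions with fewer
occupied clusters than classes are returned as-is (expected at small
β) and the mapping step handles them injectively.

The number of clusters defaults to the number of classes. β defaults to
100: across the working grid β ∈ {10, …, 150} the solution's information
quantities are nearly constant (the package's β-scan reproduces this
stability; the standard deviation of $I(P;C)$ across the grid is well
under 0.05 bits on synthetic joints), so the choice mainly expresses a
large weight on the term that enters the performance measure. Very small
β (≲ 1) collapses the representation — fewer occupied clusters — and
very large β risks numerical overflow in the exponentials, which the
solver avoids by the usual max-subtraction stabilisation.

Every returned solution satisfies the data processing inequality
$I(P;C) \le I(X;C)$ up to 1e-9; the same inequality is a useful
diagnostic for comparing feature sets, since dropping a conditionally
independent feature can only lose class information.

## Classification rules

**Classifier 1** (point rule): map the sample to its bin-vector cell; if
the cell is outside the support, abstain; otherwise classify into the
cluster with $q(p \mid x) \ge 1 - \tau$ and abstain if none reaches it.
The deterministic encoder satisfies the "posterior = 1" condition exactly;
$\alpha = 1$ encoders are only numerically deterministic, hence the
tolerance $\tau$ (default 1e-6). An `argmax` rule (always classify
in-support cells by the largest posterior) is available as an option;
strict is the default because it is what gives the original bottleneck a
useful reject behaviour. Cluster identities are arbitrary, so training
enumerates all injective maps from occupied clusters to classes and keeps
the training-accuracy maximiser (ties broken lexicographically).

**Classifier 2** (neighbourhood vote): around the sample's bin vector,
consider all offset tuples $s \in \{-n,\dots,n\}^F$; count, per class,
the shifted cells that Classifier 1 would assign to that class. Offsets
leaving the grid or landing on filtered cells vote for no class —
clamping would double-count edge cells. Classify when a class's count
reaches the threshold $t$, abstain otherwise. Valid thresholds satisfy

$$\frac{(2n+1)^F}{2} < t \le (2n+1)^F,$$

so that more than half the neighbourhood must agree (at most one class
can reach the threshold — asserted, never violated, in the tests) and at
most full agreement can be demanded. The count test is `>= t`: the upper
endpoint then means "all neighbours agree", which is the intended
semantics of the bound, and radius 0 with `t = 1` reduces exactly to
Classifier 1 (verified exhaustively over all bin vectors). The exponent
generalizes the three-feature case to any number of features, because the
neighbourhood has $(2n+1)^F$ cells.

As $t$ rises the classified set shrinks, accuracy on classified samples
rises, and the mutual-information ITR typically climbs to a peak before
collapsing when too few samples classify — `scan_t()` evaluates the whole
valid range per radius (vote counts are computed once per radius, so the
scan is cheap) and exhibits that interior peak on moderately noisy
synthetic data.

## Synthetic data: what it does and does not emulate

`generate_features()` draws class-conditional skew-normal features,
conditionally independent given the class, with the feature matching the
attended class shifted up by `delta`. This is exactly the generative model
the discretisation and joint modules assume, so it validates the
machinery (parameter recovery, null behaviour at `delta = 0`, permuted
`boost_feature` to confirm the method needs no largest-feature
assumption) — it does *not* demonstrate robustness to real EEG
properties: within-trial autocorrelation of overlapping windows,
non-stationarity, inter-subject variability, or feature correlations.
Defaults (3 classes, 5 trials, 200 samples/class, unit scale, shape 3,
`delta = 2`, 1 s window / 0.125 s step) describe a small three-target
calibration session. Trials exist so cross-validation can be
leave-one-trial-out; random shuffling would leak dependent neighbouring
windows between train and test.

`generate_ssvep_eeg()` emits sinusoids at the first three harmonics plus
seeded 1/f noise, enough to exercise the PSDA/CCA front end
(`psda_features()`, `cca_features()`, `combine_features_lda()`), which is
a deliberately minimal re-implementation: rectangular-window periodogram
at the nearest bin, canonical correlation against six harmonic
references, and one-vs-rest Fisher discriminants whose signed border
distances become the per-class features. It makes no claim to replicate
any published preprocessing chain beyond those stated elements.

## Numerical choices and edge cases

* All information quantities are in bits; `0·log 0 = 0` throughout.
* Scoring uses natural logs internally (identical fixed points, cheaper),
  with the β-weighted KL in matching units.
* Encoder ties break to the lowest cluster index; mapping ties to the
  lexicographically smallest assignment; both for bitwise
  reproducibility, which the tests assert.
* Zero-probability clusters get score $-\infty$ and stay dead; rows with
  no feasible cluster keep their previous assignment.
* Accuracy is undefined (NA) with zero classified samples; the rates are
  0 and MDT infinite.
* Problem sizes in the tests and the acceptance script — up to 10 support
  cells for the enumeration cross-check, 150–500 samples per class for
  the synthetic studies, 50 restarts for oracle comparisons — were chosen
  so the full validation runs comfortably on a laptop-class single core
  while keeping the checks statistically meaningful.

## Known limitations

* Dense joint enumeration limits the method to few classes/features; the
  exact bottleneck's cost grows exponentially with classes. Approximate
  solvers are out of scope.
* The plug-in mutual information from small confusion tables is biased
  upward; with very few classified samples the reported `I(P;C)` should
  be read cautiously. No bias correction is applied, matching the direct
  estimation the measures are defined with.
* Skew-normal shape is weakly identified near symmetry; fits on symmetric
  data may return any small shape (the implied moments are still
  accurate, which is what the bin probabilities depend on).
* The front end deliberately omits TRCA, filter banks and latency
  correction.
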