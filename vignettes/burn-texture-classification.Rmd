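---
title: "Methods: burn severity classification from B-mode texture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burn severity classification from B-mode texture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burntex)
```

## The model

Thermal damage to skin produces growing low-intensity speckle regions
in B-mode ultrasound: evaporating tissue water leaves vapour-filled
pores whose acoustic impedance contrasts sharply with the surrounding
tissue, and the degraded microstructure scatters strongly. `burntex`
quantifies this with second-order texture statistics of the grey-level
co-occurrence matrix (GLCM) and classifies burn groups from them.

For an image $I(m,n)$ with $L$ quantized grey levels, the GLCM at
offset $(k,l)$ counts ordered pixel pairs,

$$\chi_{k,l}(i,j) = \#\{(m,n) : I(m,n) = i,\; I(m+k,n+l) = j\},$$

over all positions whose offset partner lies inside the image; boundary
positions without a partner are skipped — no wraparound or padding, so
a horizontal offset on an $M \times N$ image yields exactly $M(N-1)$
pairs. The matrix is **directional** (not symmetrized) by default,
exactly as the counting rule above reads; `symmetric = TRUE` adds the
transpose for users who want order-free pairs. The default offset
$(0,1)$ compares horizontally adjacent pixels, the direction along a
scan line in which speckle modulates intensity fastest.

Dividing by the pair count gives the joint probability $p(i,j)$, from
which the nineteen active texture features are computed
(`?glcm_feature_catalog` lists every formula). Features are evaluated
on the **probability** form, not raw counts: most features are then
invariant to image size, and images of different sizes become
comparable. Three conventions are fixed globally:

* all logarithms are natural, with $0 \log 0 := 0$. The base only
  rescales the entropy-family features by a common constant and cancels
  inside the second information measure of correlation, but it must be
  one consistent choice;
* *difference variance* is the variance of the difference distribution
  $p_{x-y}$ (the literature also contains a mean-absolute-deviation
  variant; one definition is fixed and documented);
* a constant image makes the marginal variances vanish and correlation
  undefined; it is reported as 0 with a `degenerate_correlation`
  attribute so batch extraction never aborts.

## Normalization without leakage

Each feature column is min–max normalized to $[0,1]$,
$(x - \min x)/(\max x - \min x)$, with a constant column mapping to
zeros (it carries no information, and the classifiers must still run).
Inside every cross-validation fold the $(\min, \max)$ statistics are
recomputed **from the training fold only** and applied to the held-out
sample without clipping. Leave-one-out error is only an independent
estimate if the held-out observation influences nothing about the
fitted pipeline — including the normalization constants — so the
leak-free variant is the only defensible one even though it is the more
expensive choice.

## Feature selection

`sbs_select()` is a greedy top-down wrapper: starting from the full
active set, each stage evaluates every single-feature removal by the
mean pairwise leave-one-out SVM accuracy (each class pair weighted
equally — six pairs for four groups — rather than pooling samples, so
small classes are not down-weighted) and commits the best one. The
search stops when the best candidate's criterion falls **strictly**
below the current stage's; equal-criterion removals continue, favouring
smaller sets, since a feature whose removal leaves the accuracy
unchanged is redundant by definition. Ties between equal candidates
remove the feature earliest in the fixed catalog order. Both rules make
the trace deterministic, and because the criterion is a fold-aggregated
count it is also invariant to sample order — properties the test suite
asserts. Greedy search does not explore all $2^p$ subsets; the tests
bracket its result between the full-set criterion and the exhaustive
optimum on five-feature problems.

## Classifiers

**Pairwise SVM.** A soft-margin SVM with RBF kernel
$\exp(-\gamma\lVert x - y\rVert^2)$ separates each pair of burn groups;
the class playing the null hypothesis is labeled $+1$ and the signed
decision value is the classification score. The fit is delegated to the
`e1071` bindings of libsvm; the package pins the score's sign
convention to the declared positive class rather than to factor-level
order. Neither $\gamma$ nor the penalty $C$ has a canonical value for
this problem, so the defaults are reproducible, scale-adaptive
heuristics: $C = 1$ and $\gamma = 1/(p \cdot \mathrm{Var}(X))$ with
$\mathrm{Var}(X)$ the pooled variance of all training feature entries
(on min–max-normalized features this is close to $1/p$). Both can be
overridden and swept.

**Multiclass KFDA.** Kernel Fisher discriminant analysis maximizes
projected between-class over within-class scatter in the kernel feature
space. With kernel matrix $K$, per-class column means $m_c$ and overall
mean $m$, the discriminant coefficients solve

$$M\,\alpha = \lambda\, (N + \varepsilon I)\,\alpha, \qquad
M = \sum_c n_c (m_c - m)(m_c - m)^\top,\quad
N = \sum_c K_c (I - \tfrac{1}{n_c}J) K_c^\top,$$

keeping the $C-1$ leading eigenvectors. The within-class scatter in the
kernel basis is rank-deficient, so the ridge is mandatory; the default
$\varepsilon = 10^{-3}\,\mathrm{tr}(N)/n$ scales with the problem. Each
eigenvector is unit-normalized with its first non-vanishing coefficient
made positive, a deterministic orientation. A sample is assigned the
class of the nearest training-score centroid (Euclidean distance in
score space) — the standard decision rule for discriminant scores —
with exact ties resolved toward the earlier class in training order.
With a very wide kernel the leading discriminant collapses onto the
classical linear Fisher axis; the suite checks correlation above 0.99
against an independent LDA fit on two-class Gaussian data.

**Monte-Carlo cross-check.** `monte_carlo_eval()` repeats stratified
train/test splits (default 90/10, 100 repetitions, one seed driving
every draw). Stratification is deliberate: with ~30 samples per class,
unstratified 10% test draws regularly empty a class. The mean split
accuracy should agree with leave-one-out on the same data to a few
points; the acceptance suite requires 3.

## The synthetic phantom generator

No imaging data ships with the package, so the generator provides the
study conditions: four severity classes, 30 images per class, the
severity ladder `c(0.1, 0.4, 0.6, 0.9)` with the two middle classes
closest so that the rare confusions concentrate between adjacent
middle severities.

Each phantom is built from two Rayleigh envelope fields (the standard
model of fully developed speckle), scaled to a mean grey of about 120
in an 8-bit range:

* the **healthy background** is smoothed with a Gaussian of
  $\sigma \approx 2.2$ px, giving adjacent pixels an autocorrelation
  near 0.95 — a resolution cell spans several pixels in a real scan, so
  background pairs co-occur close to the GLCM diagonal;
* **burn speckle** is added as a Poisson number of elliptical blobs
  whose count (`density_max * s`), mean radius ($1.5 + 2.5s$ px) and
  depth extent (onset fraction $0.6(1-s)$, measured from the surface)
  are affine in severity $s \in [0,1]$, so severity 0 is pure
  background. Blob texture is *unsmoothed* Rayleigh noise folded about
  zero and shifted to a core intensity drawn from 10–60 — rough,
  low-intensity scattering zones inside the 0–70 grey band, darkened
  into the background through a smoothed elliptical edge.

This construction reproduces the qualitative texture evolution the
classifier exploits, and the tests assert it: the off-diagonal
co-occurrence mass in the 0–70 band grows with severity, contrast,
difference variance, the second information measure of correlation and
sum entropy increase along the ladder while correlation, homogeneity,
inverse difference and maximum probability decrease. The default frame
is $132 \times 176$ px, a 1.1 cm × 1.5 cm field at ~85 µm per pixel.

What the phantoms do **not** model: physically propagated wavefields
(no attenuation, shadowing, refraction or ring-down artifacts), depth-
dependent gain, log compression of a real envelope detector, or the
histology-level structure of burned tissue. Passing the synthetic
acceptance checks therefore demonstrates that the pipeline recovers a
known texture-severity signal under controlled conditions — not that it
attains any particular accuracy on clinical images.

## Problem sizes and numerical tolerances

The study-scale checks run four classes × 30 phantoms (120 images,
leave-one-out over 60-70 samples per pair and 120 for multiclass, plus
100 Monte-Carlo splits); exact counting oracles run on images up to
16 × 16 with up to 8 grey levels, and feature formulas are verified
against brute-force evaluation on random 4 × 4 probability matrices at
$10^{-10}$. Probability mass computed by the GLCM normalizer must sum
to 1 within $10^{-12}$. The libsvm optimizer's decision values are
reproducible to its convergence tolerance but not bit-identical across
sample orderings; aggregated confusion matrices and predicted labels
are order-invariant exactly, and the tests treat scores accordingly.

## Configuration and reports

`run_pipeline()` drives manifest → extraction → optional selection →
evaluation from one flat configuration list; `read_run_config()` loads
the same keys from YAML, a format chosen for its ubiquity in scientific
R. Reports embed the exact configuration and seed used (excluding the
output directory, which is not part of the analysis identity) and no
timestamps, so a rerun with the same configuration is byte-identical —
an auditability property the tests verify.

## Known limitations

* The selection search is greedy; it guarantees no decrease of the
  criterion, not global optimality.
* Several variants of the signed SVM score and of the KFDA decision
  rule circulate in the literature; `burntex` fixes the standard
  formulations (signed libsvm decision value; kernelized Fisher
  eigenproblem with nearest-centroid assignment) as the package's own
  choices and documents them here.
* ROI cropping is available (`crop_roi()`) but defaults to the full
  frame; whether a skin-only ROI improves real-data accuracy is an open
  empirical question.
* Phantom realism is validated against qualitative trends only; no
  quantitative speckle statistics of burned porcine tissue are
  available to calibrate against.
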