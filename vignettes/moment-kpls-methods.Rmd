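---
title: "Methods: windowed statistical moments and kernel PLS for SELDI-TOF classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed statistical moments and kernel PLS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(momentKPLS)
```

# The problem and the pipeline

High-resolution SELDI-TOF serum profiling produces, per sample, an
intensity value at each of tens of thousands to hundreds of thousands of
m/z points, while cohorts rarely exceed a few hundred samples. Any
classifier must therefore reduce dimensionality drastically, and the way
it does so dominates performance. momentKPLS implements one pipeline for
this regime:

union alignment → refining → per-row t-test filter → windowed
statistical-moment transform → kernel PLS classification,

with all tunables surfaced in `pipelineConfig()` and three validation
schemes around the whole chain.

## Alignment and refining

`alignUnion()` builds the sorted union of every m/z value observed in any
spectrum and places each sample on it; a grid point a sample did not
record is an explicit `NA`. Matching is exact — two m/z values are the
same axis point only when they are bitwise equal. A tolerance window would
change the union axis in data-dependent ways and is deliberately not
offered; data acquired on a shared instrument grid (the intended input)
needs none.

`refineSpectra()` then drops every row with at least one `NA`. Under
independent per-sample dropout with probability $q$, a row survives with
probability $(1-q)^n$ — the step is aggressive by design and trades m/z
coverage for a complete matrix that the downstream moments need.

## The t-test filter

`tFilter()` tests each row with a two-sided two-sample t-test between the
classes and keeps rows with $p < \alpha$ (default $\alpha = 0.01$).
Two choices deserve comment:

* **Pooled vs. Welch.** The classical pooled-variance (Student) test is
  the default; Welch is available via `variant = "welch"`. On spectra the
  within-class variances at a fixed m/z are usually comparable, and the
  pooled test is the field's default reading of "two-sample t-test"; the
  choice is exposed rather than hidden because nothing in the method
  depends on it structurally.
* **No multiple-testing correction.** The filter is a screening device,
  not an inference: it is expected to keep a substantial fraction of rows
  (on real high-resolution data more than half the refined rows can pass
  at 1%), and any FDR-style correction would change its character
  entirely. Under a global null the retained fraction calibrates to
  $\alpha$, which the test suite checks by simulation.

A row with zero variance in both groups is assigned $p = 1$ and dropped:
it carries no class signal and would otherwise produce 0/0.

## The windowed moment transform

`momentTransform()` partitions the filtered rows into consecutive windows
of `width` m/z **points** (not Daltons) and replaces each window, per
sample, by up to four statistical moments. The trailing partial window is
retained, so $m$ rows become $k \lceil m / w \rceil$ features. Both
conventions are forced by the arithmetic the method is known to satisfy:
39,905 rows at width 40 must give exactly $998 \times 4 = 3{,}992$
features and 24,545 rows at width 50 exactly $491 \times 4 = 1{,}964$;
a Dalton-width reading or a dropped partial window cannot reproduce
either count.

The moment conventions are population (N-denominator) variance, an
N-denominator standard deviation $S$, and **raw** (non-excess) kurtosis:

$$\bar Y = \tfrac{1}{N}\sum Y_i,\quad
  \mathrm{var} = \tfrac{1}{N}\sum (Y_i-\bar Y)^2,\quad
  \mathrm{skew} = \frac{\sum (Y_i-\bar Y)^3}{N S^3},\quad
  \mathrm{kurt} = \frac{\sum (Y_i-\bar Y)^4}{N S^4}.$$

Whether kurtosis should subtract 3 (excess form) cannot be settled from
prose alone; the raw form is pinned here and used consistently, including
in the independent brute-force oracle the tests compare against. A
constant window ($S = 0$) gets skewness = kurtosis = 0 so that degenerate
windows cannot inject non-finite values into the kernel. Feature rows are
ordered window-major, moment-minor, and the transform restricted to a
single window agrees with `windowMoments()` on that slice — a consistency
the tests exercise directly.

`selectWindowWidth()` evaluates candidate widths by repeated five-fold
cross-validated accuracy of the full downstream pipeline and picks the
best, ties toward the smaller width (a smaller width discards less
information at equal measured performance).

## Kernel PLS

`kplsFit()` computes the polynomial kernel
$\kappa(x, z) = (\langle x, z\rangle + r)^p$ with defaults $p = 3$,
$r = 1$ — degree 3 captures low-order moment interactions while the unit
offset weights all monomial orders equally — and centers the Gram matrix
in feature space,
$K_c = (I - \tfrac1n \mathbf{1}\mathbf{1}^\top) K
       (I - \tfrac1n \mathbf{1}\mathbf{1}^\top)$,
the kernel-space equivalent of mean-centering the (implicit) feature
images. Test blocks are centered one-sidedly against the uncentered
training kernel. No feature scaling precedes the kernel: the moments are
kept on their natural, physically interpretable scales.

Latent components follow the kernel NIPALS recursion for a single
response: $t \propto K u$ with $u$ the current response residual, $t$
normalized to unit length, then both $K$ and the response are deflated by
$(I - t t^\top)$. Dual regression coefficients are assembled from the
undeflated centered kernel, $\alpha = U (T^\top K_c U)^{-1} T^\top y_c$,
so prediction is a single product $\hat y = K_{t,c}\,\alpha + \bar y$;
a sample is called cancer when $\hat y \ge 0$ (an exact 0 breaks toward
+1 — deterministic, measure-zero). With the linear kernel ($p=1$, $r=0$)
this reproduces classical primal PLS1 regression exactly, which is the
primary correctness oracle in the test suite; at full rank it reduces
further to ordinary least squares on centered data.

Numerical choices: each new score is re-orthogonalized against the
previous ones before normalization (deflation guarantees orthogonality
only in exact arithmetic; degree-3 kernels on raw-scale moments reach
magnitudes around $10^{12}$, where drift otherwise exceeds the $10^{-8}$
orthonormality bound the model class enforces); a score whose norm falls
below $10^{-10} \max(1, \max|K_c|)$ signals rank exhaustion and reduces
the component count with a warning rather than failing.

The number of components is not determined by the method itself. The
default configuration fixes `ncomp = 5` for reproducibility;
`ncomp = "auto"` selects over 1..10 by inner stratified five-fold
cross-validated accuracy (ties toward the smaller count, which is the
less complex model).

## Validation

`fiveFoldCV()` (stratified, default 100 repeats),
`proportionalValidation()` (per-class 80/20 splits) and `loocv()` report
Sn, Sp, Ac and the Matthews correlation
$$CC = \frac{TP \cdot TN - FP \cdot FN}
            {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},$$
defined 0 when any factor vanishes. Each repeat pools its held-out
predictions into one confusion matrix (per-fold averaging would weight
folds unequally when $n$ is not divisible by 5); means and SDs (sample SD,
$N-1$) are taken over repeats. Folds are stratified — with imbalanced
classes an unstratified fold can lose a class entirely, making Sn or Sp
undefined.

**Leakage.** By default the t-filter (and any component selection) is
refit inside each training fold, so held-out samples never influence which
rows survive: cross-validated metrics estimate generalization of the whole
pipeline. `paperMode = TRUE` instead filters once on the full data before
validation — the protocol under which published results of this kind were
obtained — and will generally look better; the two options exist precisely
so the difference is visible rather than silent.

All schemes are deterministic functions of (data, configuration, seed);
identical seeds give bitwise-identical reports.

# The synthetic generator

`generateSpectra()` emulates the statistical structure the pipeline
assumes: a shared fine m/z grid, a slowly decaying exponential baseline,
Gaussian peaks at locations shared across samples, within-class amplitude
variation, a class-dependent amplitude shift at a subset of peaks,
additive Gaussian noise, truncation at zero (ion abundances are
nonnegative), and independent per-point dropout to exercise union
alignment and refining.

Defaults: 30 controls + 30 cancers; grid of 2,000 points over
2,000–20,000 Da; 40 peaks of σ = 60 Da, 10 informative; effect size 5
within-class amplitude SDs; amplitude SD 5 and noise SD 1 (intensity
units); dropout 0.01. The dropout default follows from the refining
arithmetic: real high-resolution data of this kind lose roughly 89% of
union rows to refining across ~216 samples, which under independent
dropout implies a per-point rate near 1%; the amplitude and noise scales
put per-peak signal-to-noise in the range where the t-filter is selective
but not trivial. The class signal is an amplitude shift at shared
locations (not a location shift) because that is the signal the t-filter
and the window means are built to detect — a location-shift signal would
test a different method.

What the generator does **not** emulate: isotope envelopes, chemical and
electronic noise structure, mass-calibration drift, intensity
normalization artifacts, or correlated (block) missingness. Passing tests
on synthetic data therefore demonstrate internal correctness and
end-to-end signal recovery under the stated model, not performance on any
real cohort.

`generateNullMatrix()` produces a matrix with no class signal at all
(every row i.i.d. across both classes) and exists to calibrate the
t-filter's type-I behaviour.

# Problem sizes in the shipped checks

The test suite and the acceptance script run at deliberately modest sizes
chosen to make the properties they check unambiguous: dimension
identities on full-size (39,905- and 24,545-row) matrices, which are cheap
because the transform is linear-time; oracle comparisons on instances of
up to 30 samples and 10 features, where primal PLS is exact and fast;
type-I calibration on 1,000 null rows; and pipeline recovery runs on the
generator defaults with 10 cross-validation repeats. These sizes are the
package's own choices for crisp, reproducible checks; all operations
accept full-scale data.

# Known limitations

* Exact-match union alignment presumes a shared acquisition grid; spectra
  with per-sample mass calibration need external alignment first.
* The refine step's row loss grows geometrically with sample count under
  independent dropout; heavily fragmented grids may leave too few rows.
* The classifier is binary (+1/-1) with a fixed 0 threshold; no
  probability calibration, multiclass extension, or ROC machinery is
  included.
* Only the polynomial kernel is implemented; the kernel parameters are
  user-set, not optimized internally.
* No baseline subtraction, peak detection or intensity normalization is
  performed anywhere in the pipeline — inputs are taken as delivered.
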