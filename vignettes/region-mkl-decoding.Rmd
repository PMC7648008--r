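---
title: "Atlas-based multiple kernel learning for decoding brain states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas-based multiple kernel learning for decoding brain states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regionmkl)
```

## The decoding problem

Mass-univariate fMRI analysis tests each voxel separately and cannot
exploit the fact that task information is distributed over many voxels.
Multivoxel pattern analysis (MVPA) treats each subject's whole-brain
contrast image as a single high-dimensional pattern and asks whether the
pattern predicts a condition (e.g. viewing a threatening versus a neutral
picture) or a continuous trait (e.g. a subject's threat-perception index,
the sum of four 1–9 ratings of threat magnitude, proximity,
inescapability and impossibility of hiding, so an integer in 4–36).

A whole-brain linear decoder is hard to interpret: no single voxel's
weight supports a local claim. `regionmkl` therefore implements the
atlas-based multiple kernel learning (MKL) approach: the brain is split
into anatomical regions by an integer-labelled parcellation (any labelled
volume works; a 120-region whole-brain atlas is the motivating case), one
linear kernel is computed per region,

$$K_m(x, x') = \langle x_m, x'_m \rangle,$$

where $x_m$ collects the voxels of region $m$, and the decoder learns a
convex mixture of region kernels together with the kernel machine itself.

## The model

The SimpleMKL objective is minimised over the probability simplex. For
kernel weights $d \in \Delta = \{d : d_m \ge 0, \sum_m d_m = 1\}$ define
$J(d)$ as the optimal value of the inner kernel-machine problem on the
mixture kernel $K(d) = \sum_m d_m K_m$ — a soft-margin hinge classifier
for condition decoding, or an $\varepsilon$-insensitive regressor for
index decoding, both with regularisation constant $C$. SimpleMKL solves

$$\min_{d \in \Delta} J(d),$$

by alternating an exact inner fit (here: a compiled sequential minimal
optimisation solver for both duals, maximal-violating-pair selection with
a second-order choice of the partner variable) with reduced-gradient
descent on $d$. By Danskin's theorem the gradient at the inner optimum is
$\partial J / \partial d_m = -\tfrac12 \beta^\top K_m \beta$ with
$\beta$ the signed dual coefficients. The $\ell_1$ simplex constraint
makes the solution sparse: regions that do not contribute to prediction
receive weight exactly zero (weights below $10^{-6}$ are reported as 0).
The decision function is

$$f(x) = \sum_i \beta_i \sum_m d_m K_m(x_i, x) + b,$$

with the sign of $f$ as predicted class, or $f$ plus the training-target
mean as predicted index. `extract_weights()` back-projects the model into
voxel space ($w_m = d_m s_m X_m^\top \beta$ with $s_m$ the kernel
normalisation factor), so region weights (in percent, $100\,d_m$) and
voxel weight maps can be exported and ranked.

Numerical choices, all deterministic (no RNG anywhere in the solver):
$d$ starts uniform at $1/R$; the line search is Armijo backtracking along
the reduced gradient from the largest simplex-feasible step, so the outer
objective never increases; termination is a relative duality gap
$\big(\max_m S_m - \sum_m d_m S_m\big)/|J| \le$ `tol` ($10^{-4}$ by
default, $S_m = \tfrac12\beta^\top K_m\beta$) or 500 outer iterations,
whichever comes first, keeping the best objective seen. The inner SMO
solves to a KKT violation of $10^{-8}$ and warm-starts from the previous
$\alpha$ during the line search. $\varepsilon$ defaults to one tenth of
the training-target standard deviation.

## Kernel construction and train/test hygiene

Contrast images are masked by the intersection of the atlas foreground
with the *common finite mask*: a voxel is kept only if it is finite in
every image of every subject, so a single subject's NaN removes the voxel
for all (`build_common_mask()`). Each region's kernel is then

1. **mean-centered** in feature space using *training* samples only, and
2. **trace-normalised** so the training submatrix has trace $n_{train}$,
   compensating for unequal region sizes.

Centering precedes normalisation (the trace of the *centered* training
kernel is what measures effective region scale; the toolbox the approach
originates from does not document its order, so ours is declared and
oracle-tested against explicitly transformed features). Regions emptied
by the mask, or with zero variance across training samples, are dropped
with a warning rather than carried as zero kernels, which would break
trace normalisation. All kernels share one sample-ordering contract —
subjects sorted by id, conditions in declared order — enforced by a
provenance hash checked at prediction time.

## Cross-validation, metrics, and permutation inference

Folds are built over *subjects* (`make_fold_plan()`): leave-one-subject-out
(LOSO), or k-fold (k = 10) with subject shuffling controlled by the seed
and fold sizes differing by at most one (38 subjects give eight folds of
4 and two of 3). Both condition images of a subject always stay on the
same side of a split. Hyperparameter selection is a nested loop of the
same scheme inside each outer-training set: the inner loop scores each
candidate $C$ (default grid $\{0.01, 0.1, 1, 10, 100\}$) by pooled inner
balanced accuracy (classification) or pooled inner MSE (regression), ties
going to the smallest $C$; the model is then refit on the full
outer-training set. Centering/normalisation statistics and the regression
target mean always come from the training side of whichever split is
current, and the inner loop never sees outer-test subjects. A looser
duality gap ($10^{-3}$) is used while *ranking* candidate $C$ values;
outer-fold refits use the full tolerance.

Predictions are pooled across outer folds before computing metrics, so
every LOSO accuracy is an integer multiple of $1/n_{subjects}$ — the
granularity visible in published accuracy tables (e.g. $30/38 = 78.95\%$,
$18/38 = 47.37\%$). Classification reports per-class accuracy, balanced
accuracy (their mean), and the AUC of the pooled ROC curve (midrank tie
handling; a per-fold ROC is undefined for LOSO's single test subject).
Regression reports Pearson's $r$, $R^2 = r^2$ (the convention consistent
with every published $r$/$R^2$ pair at two decimals), and MSE.

Significance uses permutation tests: the full pipeline is re-run with
permuted targets, fold plans and grids held fixed. Classification flips
each subject's label pair with probability one half, preserving the
paired design ("free" permutation across subjects is available behind a
flag, and is the default for regression targets). The p-value follows the
add-one convention $p = (1 + \#\{|m_{perm}| \ge |m_{obs}|\})/(n_{perm}+1)$
(direction reversed for MSE), whose floor at 100 permutations is
$1/101 = 0.01$ at two decimals — the floor value visible in published
permutation p-values, which never fall below 0.01. Permuted runs can
either re-optimise $C$ (conservative) or reuse the modal selected $C$
(fast mode, the `run_experiment()` default).

## What the synthetic generator emulates

No imaging data accompany the motivating study, so the package ships a
generator reproducing the *statistical structure* the analysis assumes:

* **Design**: 38 subjects; 4 conditions (threat/neutral × towards/away);
  4 runs of 198 volumes at TR = 2 s; 56 blocks of 15 s (14 per
  condition, every condition in every run) separated by 12-s fixation
  baselines; the first three volumes of each run are dropped before
  modelling.
* **Atlas**: contiguous Voronoi regions tiling an ellipsoidal brain-like
  mask, with round-robin lobe labels — a stand-in for an anatomical
  parcellation.
* **Contrast images**: threat-condition images receive
  $\delta + \gamma\, z(\text{index})$ in the informative regions'
  voxels, where $z$ is the standardised threat-perception index;
  neutral conditions have zero mean; a per-subject scalar offset and iid
  Gaussian voxel noise are added inside the mask (optionally smoothed;
  optionally NaN-injected at ~1% of border voxels to exercise the common
  mask — off by default).
* **BOLD sessions**: baseline + per-condition amplitude × (boxcar ⊛
  canonical HRF) in the informative regions + slow cosine drift + AR(1)
  noise, plus six smooth motion-like nuisance series, for end-to-end GLM
  testing.
* **Ratings**: four independent discretised truncated normals (mean 3,
  sd 2, support 1–9), summed. This puts the index mean near the
  published towards-context value (≈ 12.4) but, because the four
  dimensions are sampled independently, the index SD (≈ 3.5) is smaller
  than the published 7.47 — real ratings are correlated within subject.
  The generator's distribution is a stand-in, not a claim about the
  population.

What the generator does **not** emulate: haemodynamic nonlinearity,
physiological noise, motion artifacts, spatial covariance of real brains,
or picture content. Passing recovery tests therefore show the pipeline
recovers the structure it assumes, not that real data meet those
assumptions.

## First-level GLM

`build_design_matrix()` convolves 15-s block boxcars with the canonical
double-gamma HRF (response delay 6 s, undershoot delay 16 s, dispersions
1, peak:undershoot ratio 6, 32-s support — all configurable, since
"canonical" is a convention), on a 16× oversampled microtime grid with
the kernel normalised to unit integral so betas carry the signal's
amplitude units. Low-frequency drifts use the discrete cosine basis with
a 128-s cut-off ($K = \lfloor 2NT_R/128 \rfloor$ non-constant terms, e.g.
6 for a 390-s run); motion covariates enter as nuisance columns; the
fixation baseline is left unmodelled, so a condition's contrast is just
its own column. Runs are modelled independently and per-condition
contrast estimates *averaged* across runs (averaging, not summing, keeps
units run-count-independent; the original report does not state which was
used). Voxelwise estimation is OLS; AR(1) prewhitening is deliberately
omitted — at the scale of the package's property tests OLS recovers
noiseless amplitudes to machine precision, which is the contract tested.
Rank deficiency aborts with the names of the collinear columns. Spatial
smoothing is a separable Gaussian (FWHM in mm, edge-renormalised so
constant images are fixed points).

## Stimulus picture metrics

Following the standardisation conventions used for the picture set:
**brightness** is the mean over pixels of the per-pixel mean RGB value;
**contrast** is the standard deviation across columns of the column mean
RGB values; **spatial frequency** is the median FFT power per row and per
column (zero-frequency term excluded — otherwise a constant picture would
have nonzero "frequency"), averaged within rows and within columns and
then across the two. The terse published definitions leave the exact
row/column aggregation and the power convention open; the choices here
are fixed and oracle-tested against direct DFT evaluation, not asserted
to be bit-identical to the original scripts.

## Problem sizes used by the test-suite simulations

All empirical statements in the package are computed by its tests; the
simulations are sized for a single desktop CPU:

* end-to-end recovery: 38 subjects, 8 regions on a 12³ grid, one
  informative region, $\delta/\sigma = 2$, 10-fold nested CV over
  $C \in \{0.1, 1, 10\}$, 10 seeds (classification and regression), 20
  seeds for the null-calibration band;
* permutation-calibration: 16 subjects, 4 regions, 4-fold CV at fixed
  $C = 1$, 25 permutations, 40 pipeline seeds, Kolmogorov–Smirnov test
  at $\alpha = 0.01$;
* null ROC behaviour: 10,000 draws of 38 balanced labels.

## A small worked run

```{r example, eval = FALSE}
atlas <- make_synthetic_atlas(c(12, 12, 12), n_regions = 8, seed = 2)
effect <- effect_spec(informative_region_ids = 3, delta = 1,
                      gamma = 0, noise_sd = 0.5)
ds <- make_contrast_dataset(study_design(), atlas, effect, seed = 101)

sel <- ds$info$condition %in% c("threat_towards", "neutral_towards")
y <- ifelse(ds$info$condition[sel] == "threat_towards", 1, -1)
subjects <- ds$info$subject_id[sel]

mask <- build_common_mask(ds$images) & atlas$label_volume > 0
blocks <- parcellate(ds$images[, , , which(sel)], atlas, mask)
kset <- build_kernel_set(blocks)

plan <- make_fold_plan(subjects, "kfold", k = 10, seed = 3)
cv <- run_nested_cv(kset, y, subjects, "classification", plan,
                    C_grid = c(0.1, 1, 10))
cv
rank_regions(cv$fold_weights)
summarize_by_lobe(rank_regions(cv$fold_weights), atlas$region_table)
```

## Known limitations

* The inner solvers are exact convex QPs, but the region-weight path is
  only as identifiable as the data allow: strongly correlated regions
  share weight arbitrarily (the $\ell_1$ constraint picks one), which is
  an acknowledged property of sparse MKL rather than a defect.
* Spatial preprocessing (realignment, coregistration, normalisation,
  slice timing) is out of scope; inputs are assumed aligned on a common
  grid.
* Permutation inference re-runs the pipeline and is therefore the
  dominant cost; the fast mode fixes $C$ at the modal selected value.
* The generator's rating distribution and noise model are simplifications
  (see above); conclusions about real data require real data.
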