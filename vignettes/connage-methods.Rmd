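---
title: "Methods: sensorimotor connectivity and connectome-based age prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensorimotor connectivity and connectome-based age prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connage)
```

## What the package models

Healthy aging weakens the functional integration of the sensorimotor (SM)
system.  In resting-state fMRI this shows up as reduced correlation between
the spontaneous BOLD signals of the mid-posterior insula and the primary
motor/somatosensory cortices (M1/S1) in older adults, alongside increased
coupling between M1/S1 and the superior parietal lobule.  `connage`
implements the full statistical-learning pipeline that turns such data into
(a) group-level maps of altered resting-state functional connectivity (rsFC)
and (b) individual age predictions for older adults from those altered
edges, with permutation inference.  Because raw scans of this kind are
rarely shareable, the package ships a synthetic-cohort generator with known
ground truth, so that every stage is testable end to end.

## The synthetic world

`sim_config()` fixes the generator's "stated world".  Defaults follow a
typical aging rsFC study design:

* two groups, 52 older (51-76 years) and 51 younger (18-26 years) subjects;
* 250 usable volumes at TR = 2 s (a 510 s scan minus five dummy volumes);
* a sensorimotor node set (bilateral M1, S1, SMA, mid-posterior insula,
  rolandic operculum, superior parietal lobule) plus five null nodes with no
  connectivity, which act as negative controls;
* motion traces as clipped random walks, with a configurable fraction of
  subjects (default 0.1, a typical motion-exclusion rate for cohorts that
  include older adults) receiving an injected excursion beyond the
  1 mm / 1 degree exclusion thresholds;
* demographics with older adults having fewer education years
  (9.9 +- 3.2 vs 13.9 +- 1.2) and lower gray-matter volume, so covariate
  regression has real work to do.

Node time series are Cholesky mixes of white noise (optionally AR(1), plus
an optional sinusoidal confound for the filtering stage) whose target
correlation matrix encodes the two planted effects:

* within the older group, every insula-M1/S1 edge declines linearly with
  age, `r = base + slope * (age - 51)`;
* for every older subject, every M1/S1-SPL edge is raised by a constant.

Published group contrasts of this kind report directions and T-scores, not
correlation-scale effect sizes, so the effect magnitudes are free generator
parameters.  They were fixed once, before any acceptance run, to mirror the
*qualitative* pattern such tables show (decreased insula edges carrying the
stronger statistics):
`base_within_network_r = 0.4`, `insula_decline_slope = -0.012` r/year (mean
older-younger insula difference about -0.15), and
`parietal_increase_delta = +0.08`, i.e. the decreased edges carry the larger
effect, which is what makes the decreased-edge classifier the stronger one.
A per-subject jitter (sd 0.06) on the network baseline models
inter-individual rsFC variability; without it, subject-level Fisher-z noise
at T = 250 is so small that both classifiers saturate at AUC near 1 and the
reported ordering of the two classifiers could not be reproduced even in
direction.  Ages are drawn uniformly over the stated ranges (such designs report
only means, SDs and ranges, which do not pin down a distribution).

What a green test does *not* establish: the generator has no hemodynamics,
no voxel geometry, no physiological noise, and its "ICA-derived" features
are simply network-level connectivity values.  Passing tests certify the
statistics and the learning machinery, not fMRI preprocessing.

## Motion QC and signal cleaning

Framewise displacement is the mean Euclidean norm of successive differences
of the translation triplet (mm) and, separately, the rotation triplet
(degrees, no radius conversion): `FD = 1/(M-1) * sum_i ||d_i - d_{i-1}||`.
Exclusion uses strict thresholds — a subject is removed only if the maximum
absolute translation exceeds 1 mm or the maximum rotation exceeds 1 degree
strictly; a subject exactly at threshold is kept.

Temporal filtering is an ideal frequency-domain band-pass (0.01-0.08 Hz by
default): Fourier bins inside the band are kept, everything else including
DC is zeroed.  The classic alternative is a zero-phase Butterworth; the
ideal filter was chosen because it is the convention of the REST/DPABI tool
family, requires no filter-design code, and trivially satisfies any
pass/stop-band attenuation contract.  Nuisance regression projects each
node signal onto the orthogonal complement of an intercept, the six motion
parameters (or any supplied confounds) and, optionally, the global mean
signal (GSR); the GSR toggle is exposed through the whole pipeline because
the field has no consensus on it and analyses of this kind are commonly
validated under both settings.

## Connectivity and group statistics

Seed maps are Pearson correlations between a seed's mean signal and every
node, Fisher-transformed (`z = atanh(r)`, with `r` clipped at
`1 - 1e-12` so degenerate perfect correlations stay finite).  Seed nodes
and zero-variance nodes carry `NA` sentinels rather than being dropped, so
all per-subject vectors stay aligned.  Volume-mode seeds (an MNI centre and
a 6 mm radius) are resolved against a node-coordinate table and reduce to
ROI mode; no NIfTI reader is required or used.

Group analysis mirrors the standard SPM workflow: per-group residualization
of gray-matter volume, education and gender (means re-added, so the
between-group contrast is preserved), per-group one-sample t-tests, a
union mask, a pooled-variance two-sample t-test inside the mask (Welch
available as a flag), Benjamini-Hochberg FDR at q = 0.05, and strict
cluster-extent filtering (`> k` nodes; k = 23 is the grid-mode convention
at 3 mm isotropic voxels, while ROI mode uses k = 0 because every node is
its own "cluster").  Features are defined once on the full two-group
sample: the group contrast uses group labels, not older-adult ages, so the
age-prediction stage that follows sees no information about its own target
variable.  The stricter reading — re-deriving the contrast inside every
LOOCV training fold — would also be leakage-free but makes the feature list
fold-dependent; it is documented here as a known variation rather than
implemented as a second code path.

## The two-aspect prediction framework

**UVPA** is leave-one-out cross-validated simple linear regression of age on
one altered-edge feature.  Every training fold is recomputed from scratch;
with a zero-variance training feature the fold predicts the training mean
age.

**MVPA** is the nested LOOCV + linear epsilon-SVR framework:

1. Outer loop: hold out one older subject.
2. Inner loop over the S-1 training subjects: rank all features by
   `|corr(feature, age)|` on the inner-training data (ties broken by
   ascending feature index), train a linear eps-SVR on the top-k features
   for every k in 1..F, and predict the inner-held-out subject.
3. The k* maximizing the inner r(predicted, observed) is kept (ties go to
   the smaller k).  The per-inner-fold top-k* sets are combined by a
   consensus rule: a feature is retained if it appears in at least a
   fraction theta of inner folds (default 0.5; 1.0 gives unanimity; an
   empty consensus falls back to the top-ranked feature on the outer
   training set).
4. The outer model is an eps-SVR on the consensus features, trained on all
   S-1 subjects, and predicts the held-out subject.

Features are z-scored and ages centred using training-fold statistics only,
at every level, which is what makes the exact no-leakage contract testable:
changing a held-out subject's age cannot change any quantity used to
predict it.  The word "stratified" in descriptions of nested LOOCV has no
meaning for leave-one-out with a continuous label, so plain LOOCV is used.

The SVR itself is a dual coordinate-descent solver for the linear
epsilon-insensitive loss (epsilon = 0.001 years, the LIBSVM default;
C = 1 because no cost parameter is prescribed).
Following the LIBLINEAR convention, no intercept is fitted — features are
z-scored and ages centred, so the optimal offset is absorbed by the
centring.  Numerical choices that matter:

* stopping on the maximum projected-gradient violation (default 0.1 years
  for the inner model-selection fits, matching LIBLINEAR's default
  tolerance; outer per-fold models are solved to 1e-6), with a hard,
  deterministic cap on the work per fit;
* a hybrid schedule — a few full sweeps in a deterministic pseudo-random
  order move the bulk of the dual variables to their +-C bounds, then
  greedy (maximum-violation) single-coordinate updates fine-position the
  free support vectors, where plain cyclic sweeps crawl because the
  epsilon tube is three orders of magnitude narrower than the age scale;
* warm starts and rank-one Gram updates across the k grid inside each
  inner fold.

Everything is deterministic: fixed sweep orders, fixed tie-breaks
(ascending feature index, smaller k), and permutations drawn from a seeded
RNG.

**Permutation inference** re-runs the *entire* prediction pipeline —
selection included — on label-permuted data and reports the +1-corrected
exceedance probability `p = (#{r_perm >= r_obs} + 1) / (n_perm + 1)`
(1000 permutations by default).  Descriptions of this procedure sometimes
count permutations *below* the observed statistic, which would assign
large p-values to good predictions; the standard exceedance direction is
used here.

**Classification** of older vs younger subjects uses a linear soft-margin
SVM (same dual solver family, trained with an L2-regularized bias) under
LOOCV with training-fold z-scoring, the older group as the positive class,
and ROC/AUC computed as the tie-corrected normalized Mann-Whitney U
statistic.  The increased-edge and decreased-edge feature sets are the
per-subject vectors of Fisher-z values over the corresponding surviving
edges.  The procedural details of the original classifiers live in an
unavailable supplement, so LOOCV with a linear kernel and C = 1 is adopted
for consistency with the regression framework; all three are arguments.

## Degenerate inputs and tie-breaks (summary)

* constant features: `|r| = 0` in ranking, zero contribution after
  standardization, rejected outright only when *all* features are constant;
* zero-variance seeds are errors, zero-variance target nodes are `NA`
  sentinels;
* zero-variance one-sample nodes give `t = +-Inf, p = 0` (non-zero mean) or
  `NA` (identically zero);
* the consensus fallback, the k* tie, the ranking tie and the BH step-up
  are all deterministic, as is the full pipeline given its seed.

## Known limitations

* The generator's effect sizes are calibrated to directions and relative
  magnitudes, not to any real study's absolute statistics; r/MAE values on
  synthetic cohorts are not comparable with published numbers.
* Because the insula decline is age-graded within the older group (an older
  subject at the lower age bound carries no effect), the older class is
  intrinsically heterogeneous for the decreased-edge classifier.  Per
  cohort the decreased-edge classifier clearly dominates (AUC ~0.90 vs
  ~0.75 at the defaults), but across replicate cohorts the ordering
  reproduces in about 84% of draws rather than the 90% a homogeneous
  effect would give; the acceptance suite reports this honestly.
* The inner model-selection SVR is solved to a finite tolerance (0.1 years
  by default) with a hard iteration cap; this is a deterministic
  approximation of the same kind LIBSVM/LIBLINEAR make, and the
  permutation test remains exact because the identical procedure is
  applied to observed and permuted labels.
* Voxel-grid analyses (cluster extent over a 3-D mask) are supported
  through the adjacency argument of `cluster_filter()`, but the package
  does not read NIfTI volumes; volume-mode seeds require a node-coordinate
  table.
* Consensus across *outer* folds (the reported overall feature set) reuses
  the theta rule; published applications of this framework report consensus
  feature sets without stating the rule, so the rule here is a package
  choice.
* Because the permutation test re-runs feature selection (the honest null),
  its reference distribution is that of the *best spurious* feature among
  all candidates — with ~50 features and ~50 subjects its upper decile sits
  near r = 0.25 and occasional draws reach 0.5+.  A planted signal of
  population r = 0.6 therefore yields p < 0.05 in only a minority of
  replicate cohorts even though the point estimate and the consensus set
  recover it almost always.  Power statements about this framework should
  be made against the selection-inclusive null, not against the classical
  null distribution of a single fixed correlation.
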