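---
title: "Cross-property transfer in linear discriminant face spaces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-property transfer in linear discriminant face spaces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package addresses

A face recognition system must read out several properties of the same image:
who the person is (identity), and attributes such as sex, race and facial
expression. Identity, sex and race are *invariant* properties — stable across
images of one person — while expression is *variant*. A long-standing question
in face-perception modelling is whether one representational face space can
serve several of these read-outs at once, or whether each needs its own
optimized representation.

`facetransfer` operationalizes that question with a transfer experiment on
linear face spaces. A discriminant subspace is trained on one property; the
projected samples are then *relabelled* with a different property and scored
without any retraining. If the second property remains decodable, its
structure was embedded in the space as a by-product of learning the first.

## The model

**Eigenface preprocessing.** Each 90×90 grayscale image is a row-major
8100-vector. The global mean face is subtracted and the data are projected
onto the leading `n` eigenvectors of the pixel covariance (the Eigenfaces),
computed by SVD. `n` is the swept "number of components" (default 10).

**Fisher discriminant subspace.** In PCA space with class labels
$c = 1, \dots, C$, the between-class scatter weights class means by class
size,
$S_B = \sum_c n_c (\mu_c - \mu)(\mu_c - \mu)^\top$, and
$S_W = \sum_c \sum_{i \in c} (x_i - \mu_c)(x_i - \mu_c)^\top$ pools the
within-class scatter. The discriminant directions solve the generalized
eigenproblem $S_B v = \lambda S_W v$; at most $C-1$ of them are informative,
and `fit_lfd()` caps the count at $\min(C-1, k)$.

**Projection geometry (a deliberate design choice).** `fit_lfd()` returns
directions normalized so that $v^\top S_W v = 1$ — the native scaling of a
generalized eigensolver. Euclidean distance between projected samples is then
a *within-class-whitened* distance: directions along which the training
classes vary internally are compressed, directions that separate them are
expanded. This scaling, not the subspace span alone, is what makes the
transfer experiment informative. When the trained property has $C-1 \ge k$
classes (identity training at `n = 10`), the discriminant directions span all
of PCA space; if they were re-orthonormalized to a Euclidean frame
(`normalization = "euclidean"`, available as an option), the projection would
be a plain rotation and every property would be exactly as decodable after
projection as before — the experiment would be vacuous in those cells. Under
the default `"sw"` scaling an identity-trained space compresses expression
variation (it is within-identity) and preserves identity morphology, so the
measured transfer reflects how the *trained geometry* organizes the other
property.

**Small-sample safeguard.** With few samples per class $S_W$ is singular
(rank at most $n - C$); its null-space directions separate the training
classes perfectly without generalizing. `fit_lfd()` therefore whitens $S_W$
on its numerical range only (eigenvalues above `1e-6` of the largest,
after adding a relative ridge `ridge * trace(S_W)/k`, default `1e-8`, to the
diagonal). Discriminants are confined to that range — the standard remedy in
appearance-based face recognition, where PCA dimension is conventionally
capped so that $S_W$ stays invertible.

**Orthogonal padding.** Subspaces trained on different class counts have
different dimensionality (1 for sex, 5 for expression, up to `k` for
identity). Where scores are compared across such conditions, all subspaces
are padded with seeded random, class-uninformative directions to the largest
discriminant count present at that grid point. Padding is orthonormalized in
the same metric the model projects with: in `"sw"` mode each padded axis has
unit within-training-class variance, exactly like the discriminant axes, so
padding adds comparable-scale, uninformative dimensions rather than
re-injecting raw-scale variance; in `"euclidean"` mode the padded frame has
Gram matrix equal to the identity. Figure-scale runs (projections, distance
histograms) describe a single condition's native subspace and are not padded.

## The transfer protocol and its estimator

For one condition at one grid point (`run_condition()`):

1. subsample `n_faces` images (see below) with a 50/50 class-stratified
   train/test split;
2. fit PCA on the subsample; fit the Fisher model on the training half's
   labels for the *training* property;
3. project the held-out half, relabel it with the *test* property;
4. score with the delayed-match-to-sample (DMS) estimator and summarise the
   within/between-class distance geometry.

**DMS estimator.** A trial takes two reference samples from two distinct
evaluation classes and a probe from one of the two (never a reference
itself); it is correct iff the probe is strictly nearer, in Euclidean
distance, to its own class's reference. Ties count as incorrect — a
deterministic, conservative rule that is measure-zero for continuous
coordinates. `dms_performance()` enumerates *all* such triples exactly
(an $O(n^3)$ count evaluated by rank-counting on the distance matrix rather
than by materializing triples) and falls back to seeded uniform sampling of
triples above a cap (default 100,000). Chance level of this two-alternative
task is 50%. Evaluation classes with fewer than two samples cannot appear as
a probe's class and are excluded with a warning.

**Distance statistics.** For each sample, the mean distance to all other
same-class samples ("within") and to all different-class samples
("between"); singleton classes contribute to "between" only. The two
per-sample averages are compared with a one-sided two-sample
Kolmogorov–Smirnov test of "between stochastically larger than within",
$D = \max_x[\hat F_w(x) - \hat F_b(x)]$, with the asymptotic one-sided tail
$p = \exp(-2 n_{\mathrm{eff}} D^2)$, $n_{\mathrm{eff}} = n_1 n_2/(n_1+n_2)$.
Exact small-sample p-values are out of scope; only the coarse
significant/non-significant dichotomy is interpreted. Condition score sets
are compared with pooled-variance two-sample t-tests
($\mathrm{df} = n_1 + n_2 - 2$, positive $t$ when the first-named condition
has the larger mean).

## The synthetic face generator

The study's two stimulus databases are private, so the package ships a
seeded generator that emulates their size, balance and — crucially — the
variant/invariant statistical structure the analysis depends on. Faces are
points in a latent space of three orthogonal blocks, rendered to pixels by a
fixed, seeded, smooth orthonormal basis (differences of 2-D Gaussian bumps,
QR-orthonormalized; a linear isometry into pixel space followed by clipping
to [0, 1] and 8-bit quantization):

| Block | Dims | Content |
|---|---|---|
| morphology M | 16 | per-identity code, i.i.d. N(0,1) on all dims; dims 15/16 additionally carry the sex and race offsets |
| expression E | 8 | category prototype + per-image jitter |
| viewpoint V | 2 | deterministic shift per camera angle |

Key parameters, with defaults and rationale:

* `effect_size = 2` — sex/race offset in units of the within-cell identity
  standard deviation; identities of the two sexes (races) sit ±2 along a
  fixed axis. Groups are linearly separable but overlap the morphology
  continuum.
* `noise_sd = 0.02` — additive Gaussian pixel noise on the [0,1] intensity
  scale; keeps every covariance non-degenerate without swamping signal.
* `expr_strength = 3`, prototypes in general position on the unit sphere of
  E — per-dimension expression variance then matches per-dimension
  morphology variance, so principal components retain both families at small
  component counts, and all $C-1 = 5$ expression discriminants carry genuine
  expression structure.
* `jitter_frac = 0.25` — per-image expression jitter as a fraction of the
  prototype norm; expression is learnable but harder than the invariant
  tasks.
* `vp_scale = 1.5` — viewpoint is a latent shift, not a geometric rotation;
  the analysis never uses viewpoint labels, the block only adds
  within-identity variance.
* `kappa` in [0,1] — routes a fraction of expression deformation energy
  through an identity-derived component (a fixed orthonormal map from the
  morphology block into the expression block), with a
  $\sqrt{1-\kappa}/\sqrt{\kappa}$ energy split. At `kappa = 0` expression is
  statistically independent of identity; at `kappa = 1` the deformation
  direction is a deterministic function of identity. Raising `kappa`
  monotonically increases identity decodability from expression-trained
  spaces — the package's probe for expression–identity interaction.

The invariant database renders 120 identities, balanced over sex × race,
at five viewpoints (−10…30°); the expression database renders 50 identities
(half female, race constant) with six frontal expressions, neutral being the
undeformed face.

## Sweeps, subsampling and the omission rule

`run_sweep()` crosses component counts (default 6–42 by 2) with face counts
(20–120 or 20–160 by 10) for every condition block. A grid point is omitted,
not failed, when `n_faces < n_components`; the package also omits the
equality case, where the centered covariance (rank at most `n_faces - 1`)
cannot supply `n_components` components.

Subsampling respects the databases' factorial structure: identities are
drawn evenly across the sex × race cells and *all* their replicate images
(viewpoints or expressions) are included, with the identity count set to
`round(n_faces / n_replicates)`. The 50/50 split is stratified by training
class and alternates over the sorted replicate levels, so both halves span
viewpoints/expressions and the within-class scatter estimate is never left
to an unlucky draw. One trained subspace serves all of its test properties
at a grid point. Non-factorial face sets (user-supplied data) fall back to
plain per-class stratified sampling.

The default protocol configuration (`default_protocol_config()`) uses
desk-scale grids — components {6, 10, 14}, faces {40, 80, 120} — and
figure-scale runs at 10 components with 120 (invariant) and 160 (expression)
faces; a full study completes in well under a minute.

## Numerical conventions

* Eigenvector and discriminant signs are fixed by making the
  largest-magnitude loading positive, for bit-reproducible output.
* All randomness flows from one base seed through a multiplicative hash
  (`derive_seed()`), so every grid cell, split, padding draw and DMS sample
  has its own stable stream and full runs are byte-identical under a fixed
  configuration.
* DMS ties lose; KS `D` is clamped to [0, 1]; zero pooled variance with
  equal means yields `t = 0, p = 1`, with unequal means it is an error.
* Generated images are quantized to 8-bit intensity levels at render time,
  so writing and re-reading PNG datasets is bit-lossless.

## What the synthetic experiments do and do not show

With the default generator (`kappa = 0`) the pipeline reproduces the
qualitative dissociation the method is designed to expose: same-class
conditions and invariant-to-invariant transfer (identity-trained spaces
tested on sex or race) score far above the 50% chance level with strongly
significant between>within distance separation, while every
variant↔invariant cross (identity/sex-trained spaces tested on expression
and vice versa) sits near chance with non-significant distance separation.

Two honest limitations deserve emphasis.

First, in this generator sex and race are *single fixed offset axes* against
fourteen independent morphology dimensions of equal per-dimension variance.
An identity-trained space preserves all of that morphology at equal whitened
scale, so sex/race decoding in it is clutter-limited: a latent-space
Monte Carlo with perfect whitening bounds it near 75%, some twenty points
below a dedicated sex- or race-trained baseline. Transfer is therefore
substantial (far above chance, with decisive KS separation) but not
baseline-matched. In real faces, group information is spread over many
morphology dimensions and correlates with the dimensions that individuate
faces; whether transfer there is baseline-matched is exactly the kind of
question this pipeline measures rather than assumes.

Second, the generator is a statistical emulation, not a face model: no
lighting, no hairline, no 3-D geometry, viewpoint as a latent shift. Passing
tests on it validate the machinery and the direction of the study's effects,
not quantitative claims about any particular face database — the original
stimulus sets are private, and their printed percentages depend on them.
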