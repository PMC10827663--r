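---
title: "Methods: hemispheric asymmetry of connectome gradients"
author: "gradasym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hemispheric asymmetry of connectome gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradasym)
```

# The model

`gradasym` analyses the hemispheric organization of a functional
connectome. For a subject with a parcellated Fisher-z FC matrix over a
bilaterally matched parcellation (180 homolog pairs per hemisphere, each
pair assigned to one of 12 functional networks), the matrix is split into
the four seed-by-target blocks LL, LR, RL and RR, reindexed so row *i* of
every block refers to homolog pair *i*. Each block is reduced to its
*gradients*: eigenvectors of a diffusion operator built from the
similarity of sparsified connectivity profiles. The operator is

* sparsification: per row, the top `sparsity_density` (default 10%) of
  values are kept — connectivity profiles, not single edges, carry the
  signal, and weak edges are noise-dominated;
* affinity: the normalized-angle cosine
  `a(i, j) = 1 − arccos(ρ_ij)/π` between sparsified rows, the standard
  kernel of the connectome-gradient toolchain (1 for identical profiles,
  0.5 for orthogonal ones);
* diffusion map: `W' = D^{−α} W D^{−α}` with `α = 0.5` (half-discounting
  sampling density, the recommended setting that is robust to noise in the
  similarity matrix), row-normalisation to a transition operator,
  eigendecomposition, removal of the trivial stationary component, and
  multiscale eigenvector scaling `λ/(1 − λ)` (diffusion time 0). Ten
  components are computed; the first three are analysed.

Gradients of different blocks and subjects have arbitrary rotations and
signs, so every block embedding is aligned to a common left-left template
by an orthogonal Procrustes rotation computed in the full 10-dimensional
space (`R = argmin ‖S·R − T‖_F` over orthogonal `R`, from the SVD of
`SᵀT`); G1–G3 are read off afterwards. The template is the embedding of
the cohort-mean LL matrix (average-then-embed, not embed-then-average), or
any supplied reference matrix.

The *asymmetry index* of pair *i* on gradient *g* is the plain difference
`AI = left − right` — positive values mean leftward dominance. The
intra-hemispheric pattern contrasts LL and RR, the inter-hemispheric
pattern LR and RL. The index is deliberately not normalised by
`(left + right)`: gradient values take both signs, so the ratio form is
discontinuous.

## Statistics

Group comparisons treat the G1–G3 AI vector of a pair (or the network mean
of its pairs) as one multivariate observation and use the two-sample
Hotelling `T²` with its exact F transform. Benjamini–Hochberg FDR at
`q = 0.05` runs over the 180 pairs of each pattern separately (12 networks
at the network level); pooling both patterns into one family is possible
but not the default, since the two patterns answer distinct questions.
Per-gradient post-hoc t tests are *gatekept*: they are only flagged for
units that survived the multivariate FDR gate, at `p < 0.05/3`,
correcting for the three gradients. Positive t (comparison group minus
clinical group) means lower leftward asymmetry in the clinical group.

Age enters the group comparison as a preserved covariate of the
harmonization step, not as a GLM covariate; interaction analyses instead
model `group × age_group` explicitly in a multivariate linear model whose
terms are tested with the Hotelling–Lawley trace (for a single two-level
factor this reduces exactly to the two-sample `T²`, which the tests
verify). Within-group age contrasts compare the three age groups pairwise
with `T²` at a Bonferroni `0.05/3` level over the three age-group pairs.
Age groups are children 5–12, adolescents 12–18 and adults 18–40 years,
half-open on the left; the boundaries are configurable because published
groupings vary even within single studies.

## Harmonization

Multi-site batch effects are removed with the classic parametric
empirical-Bayes location/scale model: features are standardized with
covariate effects retained, per-batch location (`γ`) and scale (`δ²`)
estimates are shrunk towards their across-feature moments (normal prior on
locations, inverse-gamma on scales, moment-matched, solved by the standard
fixed-point iteration with the reference implementation's stopping rule,
kept verbatim for numerical agreement), and the shrunken effects are
removed before restoring covariate structure. Two properties are worth
knowing:

* shrinkage leaves a small remainder of a planted shift by design — the
  remainder is the price of variance reduction; the tests quantify it;
* re-applying the model is not exactly idempotent: the estimator mixes an
  MLE pooled variance (denominator *n*) with unbiased per-batch variances
  (denominator *n−1*), so a second pass rescales deviations by
  `sqrt((n − B)/n)` and does nothing else. This matches the reference
  implementation exactly.

Diagnosis group is never a batch or removed covariate; a guard refuses
designs where batch is pure in the protected factor.

## Decoding

A statistic map is rank-binned into 20 equal bins (ties broken by parcel
index; remainders go to the lowest bins), each bin's loading is its mean
statistic, and a term's score is the sum over bins of the mean *positive*
activation times the loading. Bins with negative loadings contribute with
their sign by default; an absolute-loading mode exists. "Loading = bin
mean" is the central interpretive choice of this module; nothing in the
decoding literature pins it further.

## Prediction

Trait scores are predicted from the 540 AI features (180 pairs × 3
gradients) of one pattern. Each of the `n_perm` permutations draws a
random 4:1 train/test split; site effects are harmonized and age regressed
out *within each part separately* — independent fits, not
transform-from-train, matching the described workflow despite its known
covariate-shift trade-off (a transform-from-train mode is available for
comparison in `combat_apply`). The elastic net (`l1_ratio = 0.1`) is
tuned over 30 log-spaced strengths on `[1e-4, 1]` by 5-fold
cross-validated MAE and refitted at the winner; test MAE and the Pearson
correlation between observed and predicted scores are recorded, plus each
feature's selection (nonzero coefficient) frequency. Features are
standardized with training-split parameters only. The response is also
standardized on the training split, so the fixed strength grid is
meaningful regardless of the trait's scale; coefficients are mapped back
to original units. A constant test prediction (fully shrunken model)
carries no association and is scored `r = 0`.

# The synthetic cohort generator

Every downstream claim is tested against cohorts with planted ground
truth, generated at two levels.

**Latent geometry.** Parcels sit on a closed ring coordinate; the latent
basis is its Fourier harmonics (10 sine/cosine pairs) with a decaying
loading spectrum (`0.3·m^{−1.5}` per harmonic pair), and the planted
G1–G3 axes are the first three harmonics. The ring was a deliberate
choice: connectivity profiles are then local along the ring, the affinity
matrix is circulant, and the sparsified-cosine diffusion embedding
recovers the planted harmonics essentially exactly, up to within-pair
rotations that Procrustes alignment resolves. Open-interval and
random-cloud geometries were examined and rejected during design: interval
boundaries warp the third harmonic and random clouds of 180 points carry
enough sampling noise that no embedding recovers their axes at the rank
correlation the package promises (≥ 0.95). The ring's degenerate
eigenvalue pairs (its variance-explained shares tie pairwise) are an
accepted artifact of this choice.

**Connectomes.** A subject's left and right latent scores are the basis
plus half the planted AI signal with opposite signs (so left minus right
reproduces it exactly), a shared symmetric subject deviation, and
hemisphere-specific noise on the analysed harmonics. Block connectivity is
the loading-weighted inner product of latent scores plus a baseline
(0.25), squashed to (−1, 1) with `tanh` and Fisher-z transformed — the two
maps cancel, so the z-blocks keep the latent low-rank form exactly; this
is a generator convention, not a claim about hemodynamics. Site batch
effects act on the z values (scale, then shift). An optional time-series
emitter realises the same structure as latent spatial patterns times
random temporal loadings plus noise, to exercise the connectivity builder.

**AI features.** For statistics and prediction studies the generator also
emits AI features directly: planted signal + biological noise
(`ai_noise_sd = 0.2` per pair and gradient), observed through per-site,
per-feature location/scale effects. This is exact for the planted effects
(they live on the latent scores, and AI is their left-right contrast) and
keeps 50-replicate power studies tractable.

**Planted effects and their sizes.** Defaults are chosen for the power of
the detection tests, not for biological realism — the magnitude of real
asymmetry effects in AI units is unknown:

* group effect: standardized AI difference 0.8 (i.e. shift 0.16) on the
  first ten language-network pairs along G1, clinical group less leftward;
* age effect: comparison-group slope 0.025 AI units/year on ten
  default-mode pairs along G3, clinical group flat — calibrated by a
  replicate power study to give ≈ 0.98 interaction detection power at
  n = 70 per group (0.02 gave 0.78, under the 0.8 design target);
* trait coupling: ADOS-like total = linear combination of ten
  intra-hemispheric features (unit weights, random signs) scaled to
  R² = 0.5, plus noise, shifted to mean 10, SD 4, rounded and clipped at
  zero. Communication and social subscores share the signal; the
  restricted/repetitive-behaviour subscore is pure noise. The R² = 0.5
  default was likewise set for test power: at the fixed strength grid and
  540 features, per-cohort out-of-sample r at R² = 0.3 fluctuates between
  0 and 0.4 purely through elastic-net estimation noise;
* demographics: ages uniform on 5–40 years, five sites, FIQ offset −8
  points and mean-FD offset +0.02 mm in the clinical group;
* site effects: per-site mean shift SD 0.1 and log-scale SD 0.1, realised
  per feature with SD 0.05 around the site mean.

All generation is bit-reproducible from a single integer seed.

# Numerical choices

* Fisher z clipping at `|r| = 1 − 1e-7`; diagonals zeroed before
  sparsification (self-connections carry no information).
* Sparsification tie-break: lowest column index wins — deterministic and
  oracle-checked.
* Negative cosine similarities are clipped into the arccos domain; the
  normalized angle is floored at 0 so the operator stays non-negative.
* Disconnected affinity graphs fail by default; a permissive mode embeds
  the largest component and fills the rest with missing values.
* Rank-deficient Procrustes cross-products fall back to the SVD's sign
  convention with a warning (this happens legitimately when aligning to a
  zero-padded reference).
* Singular pooled covariances in `T²` can be ridged with
  `λ = 1e-6 · tr(S)/p`, flagged in the output.
* The EB fixed-point stops at relative change `1e-4` with the reference
  code's signed-denominator criterion, so shared-matrix comparisons agree
  to better than `1e-6`.
* Inter-subject similarity uses all same-site subjects of both groups as
  the reference population (configurable to same-site-same-group or whole
  cohort); the concatenated G1–G3 AI vector is the default map.

# Problem sizes of the continuous checks

The test suite verifies, among others: gradient recovery on noise-free
180-pair blocks (rank correlation ≥ 0.95 per axis and block); the
embedding against a dense eigendecomposition on 20-node affinities
(1e-8); Hotelling calibration over 2000 null replicates and against
10,000-draw permutation nulls on 20 datasets; detection power and
empirical FDR over 50 replicate cohorts of 70 + 70 subjects; prediction
null/signal behaviour at n = 150 with 25 permutations, averaged over
replicate cohorts (five null, three signal — single-cohort means move by
±0.1 through chance feature–trait correlations); and bit-identical re-runs
of the end-to-end pipeline. Empirical FDR is compared to the nominal level
with its one-sided Monte-Carlo standard error, because the step-up
procedure attains its bound almost exactly under these conditions.

# What passing tests do and do not show

The generator emulates the *structure* the pipeline claims to detect:
low-rank gradient organization, homotopic asymmetry with group and age
effects, location/scale site effects, and sparse trait coupling. It does
not emulate hemodynamics, motion artifacts, spatial autocorrelation on a
cortical surface, non-Gaussian noise, site-by-group confounding, or
heterogeneous effect topographies. Passing tests therefore demonstrate
that the implementation is correct and well-calibrated under its stated
model — not that real resting-state cohorts satisfy that model. Results on
real data inherit all the usual caveats of site harmonization and
cross-sectional age contrasts.

# Known limitations

* The multivariate interaction test models age group as a factor;
  continuous-age interaction surfaces are out of scope.
* Whether the original workflows sparsified per block or thresholded the
  full matrix before splitting is unknowable from published descriptions;
  per-block row sparsification is implemented (`sparsify_rows` applies to
  whichever matrix it is given).
* FIQ and head motion can be added as preserved harmonization covariates,
  but no sensitivity-analysis automation is provided.
* Heritability of asymmetry is consumed from external sources in the
  literature this package serves; it is not estimated here.
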