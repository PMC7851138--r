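---
title: "Texture markers of Parkinson's disease progression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture markers of Parkinson's disease progression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdtexture)
```

## The scientific question

Conventional structural measures of neurodegeneration in Parkinson's disease
(PD) — structure volumes, voxel-based morphometry — change late, which limits
their use as progression markers at diagnosis. An alternative is to quantify
how the T1-weighted signal is *organised* inside the deep grey-matter nuclei
of the nigrostriatal pathway (substantia nigra, putamen, caudate nucleus,
thalamus, sub-thalamic nucleus). `pdtexture` implements that analysis as a
reusable pipeline: masked texture features per structure, ROI volumetry, and
a fixed inference chain that screens features across three clinical groups
(healthy controls, early-stage PD, late-stage PD), selects independent
markers, and evaluates them against motor severity scores.

Because no patient imaging cohort is bundled, the package ships a seeded
synthetic cohort generator with the statistical structure the analysis
assumes, so every stage — from NIfTI voxels to the final correlation table —
is exercised and tested end to end.

## Texture features

Each structure is analysed per hemisphere and the two feature vectors are
averaged element-wise; an undefined value on either side (for instance
skewness of a constant region) makes the average undefined rather than
silently dropping a side.

**First-order features** are population moments of the ROI intensity
histogram: mean, standard deviation (dividing by $N$, not $N-1$), skewness
$E[((X-\mu)/\sigma)^3]$ and kurtosis $E[((X-\mu)/\sigma)^4]$. Kurtosis is
kept non-excess (a normal sample gives $\approx 3$). A constant ROI has zero
SD; skewness and kurtosis are then returned as `NA` and propagated as such.

**Second-order features** derive from a grey-level co-occurrence matrix
(GLCM). Intensities are first quantized to $G$ levels ($G = 64$ by default)
by linear binning with clamping, either on the ROI's own min-max range
(`roi_minmax`, the default — this makes every second-order feature exactly
invariant to affine intensity rescaling) or on a fixed global range shared
by the whole study (used by the synthetic pipeline, so that more
heterogeneous tissue occupies more grey bins). For every axial slice of the
ROI, ordered voxel pairs at distance $d = 1$ along the four in-plane
directions ($\theta = 0°, 45°, 90°, 135°$) whose two ends both lie in the
mask are pooled into one count matrix, which is symmetrized by adding its
transpose and normalized into probabilities $P(i,j)$. Pooling counts across
directions (rather than averaging per-direction features) follows the single
four-direction matrix formulation; a 13-offset fully-3D variant
(`glcm_3d = TRUE`) is available for users who prefer volumetric pairs, since
slice-wise versus 3D co-occurrence is a genuinely open choice for 3D ROIs.

From $P$ the eight features are, with 0-based levels $i,j \in [0, G-1]$,
marginals $P_x, P_y$, their means/SDs $\mu_x, \mu_y, \sigma_x, \sigma_y$,
and the diagonal-sum distribution $P_{x+y}(k) = \sum_{i+j=k} P(i,j)$,
$k \in [0, 2G-2]$:

| feature | definition |
|---|---|
| homogeneity | $\sum_{i,j} P(i,j)^2$ |
| contrast | $\sum_{i,j} (i-j)^2 P(i,j)$ |
| entropy | $-\sum_{i,j} P(i,j)\log P(i,j)$, with $0\log 0 \equiv 0$ |
| correlation | $\left(\sum_{i,j} ij\,P(i,j) - \mu_x\mu_y\right) / (\sigma_x\sigma_y)$ |
| sumSQR | $\sum_{i,j} (i-\mu)^2 P(i,j)$, $\mu = \sum_{i,j} i\,P(i,j)$ |
| sumA | $\sum_k k\,P_{x+y}(k)$ |
| sumV | $\sum_k (k-\text{sumA})^2 P_{x+y}(k)$ |
| idm | $\sum_{i,j} P(i,j)/(1+(i-j)^2)$ |

Three notational decisions are worth making explicit. "Homogeneity" here is
the sum of squared probabilities — what the wider radiomics literature calls
angular second moment or energy (the name clash is historical; the
definition above is what is computed). Entropy uses the natural logarithm by
default (`log_base = 2` is available). The index origin for $P_{x+y}$ is
0-based; sum variance is invariant to that origin and sum average shifts by
a constant, so the choice affects no comparison or test. Correlation is the
standard normalized form and is undefined (flagged `NA`, never silently 0)
when a marginal SD vanishes.

A mask with no valid voxel pair (for example a single voxel) cannot define a
GLCM and is an error, not a silent zero.

## ROI volumetry

Volumes are whole-voxel counts times voxel volume, reported in cm³ per
structure and hemisphere, plus the dimensionless ratio to total intracranial
volume (TIV). TIV is an input column — estimating it is a segmentation
problem outside this package's scope. Masks are voxel-center sets with no
partial-volume weighting, and image and mask grids must match exactly;
resampling would alter texture, so a mismatch is an error rather than a
warning.

## The inference chain

For every (structure, feature): one-way fixed-effects ANOVA across the three
groups, screened at $p < 0.05$. Features passing the screen enter pairwise
Welch $t$ tests (unequal variances are the safer default for clinical
groups), corrected by Benjamini–Hochberg *within structure across the whole
(feature × pair) family* and flagged at $q < 0.02$. The family scope is a
design choice — per-structure scoping matches how results are reported
structure by structure — and is deliberately isolated in one place so it can
be changed.

ANOVA-significant features from all structures then enter a multinomial
logistic LASSO over the three groups: columns are z-scored, the penalty is
chosen by 5-fold stratified cross-validation at the 1-SE rule, and any
feature with a nonzero coefficient in any class equation is "selected". The
recipe (multinomial rather than one-vs-rest, deviance loss, 1-SE) is the
standard reproducible default; the only randomness is fold assignment,
fixed by the analysis seed. Collinear features make the selected set
non-unique — with duplicated columns at least one of each group survives,
but which one is arbitrary; this is a property of the L1 penalty, not a
defect. In simulation the recipe recovers informative columns essentially
always, at the price of occasionally admitting a handful of noise columns
(median ≈ 2 of 20 at $n = 60$); cohorts with fewer than three subjects in a
class cannot support cross-validation and skip selection with a warning.

Each selected feature is evaluated for early- versus late-stage
discrimination by ROC analysis: AUC by the Mann–Whitney pair-count
convention (ties count one half), with a *fixed* orientation (late-stage
positive) and no direction flipping — an anti-discriminative marker honestly
reports AUC below 0.5. Specificity and sensitivity are read at the threshold
maximizing Youden's $J$, the conventional single operating point when none
is pre-specified. Finally, selected features are correlated with the motor
scores (MDS-UPDRS III, Hoehn–Yahr, MDS-UPDRS total) by Spearman's rank
correlation with average ranks for ties and pairwise deletion of missing
values, BH-corrected within structure across the (feature × score) family at
$q < 0.05$.

## The synthetic cohort generator

The generator is a stand-in for a generative model that the histology does
not yet provide: no quantitative law links dopaminergic degeneration to
T1 texture. What it encodes is the *ordinal* structure the analysis is
designed to detect:

- Each of the ten structure ROIs (five bilateral ellipsoids on a
  $40 \times 48 \times 44$, 1 mm grid) has a baseline intensity plus a
  zero-mean Gaussian random field smoothed to a 1.5 mm correlation length
  and scaled so its realized within-ROI SD equals the subject's
  heterogeneity $h$.
- Group means of $h$ are 3 / 2 / 1 (controls / early / late; SD 0.4 between
  subjects): texture heterogeneity *decreases* with disease stage. Under
  the study's fixed global quantization range, a larger field amplitude
  occupies more grey bins, so GLCM entropy rises monotonically with $h$ —
  giving the synthetic data the same direction of effect as the markers the
  analysis is built to find.
- Clinical scores follow $s = c_0 - c_1 h + \varepsilon$ (for MDS-UPDRS III:
  $c_0 = 50$, $c_1 = 8$, $\varepsilon \sim N(0, 2^2)$), clipped to
  instrument ranges, parts rounded to integers, Hoehn–Yahr to the nearest
  0.5; the total is the sum of present parts and controls carry a missing
  part IV. Motor severity therefore rises exactly as texture heterogeneity
  falls, producing the negative feature–score correlations the pipeline
  should recover. Controls receive (low) scores from the same linear model:
  the generator models severity as a continuous function of tissue state,
  not of diagnostic label.
- Every subject is drawn from its own substream of the base seed (keyed by
  subject index), so cohorts are bit-reproducible and extensible without
  perturbing existing subjects; the whole cohort, images included, is
  byte-identical across reruns.

What the generator does *not* emulate: real neuroanatomy (shapes are
ellipsoids in non-overlapping bands), bias fields (inputs are assumed
N3-corrected upstream), scanner noise characteristics, registration error,
or any histologically grounded link between degeneration and texture.
Passing tests therefore demonstrate that the pipeline recovers the assumed
monotone structure from voxel data — not that the markers behave this way in
patients.

## Numerical and sizing choices

- Quantization default $G = 64$: fine enough that 8-bit-scale T1 contrasts
  are not aliased, coarse enough that small ROIs still populate the matrix.
- Tolerances: GLCM mass and symmetry are exact to 1e-12; oracle-equivalence
  tests compare against brute-force enumeration at 1e-10.
- Simulation studies (null-calibration and seed sweeps) use a compact
  configuration — the same structure set scaled by 0.78 onto a
  $32 \times 36 \times 32$ grid, $n = 20$ per group — chosen so repeated
  cohorts remain cheap while every ROI keeps enough voxel pairs for stable
  co-occurrence estimates. The type-I calibration runs 200 null cohorts
  (equal heterogeneity across groups) and checks that pairwise flags at
  $q < 0.02$ stay below a 3% rate; the gradient study sweeps 20 seeds.
- CSV output fixes float serialization at 10 significant digits so repeated
  runs are byte-identical; NIfTI writing is likewise deterministic.

## Known limitations

The slice-wise four-direction GLCM treats the through-plane direction
differently from in-plane ones; the 3D offset option is provided but not the
default. The generator's texture mechanism is one of many that produce a
monotone entropy gradient; effect sizes measured on it do not transfer to
patient data. LASSO selection frequencies depend on the CV fold structure
and should be read as reproducible-given-seed, not as inference. Volumetric
group differences are intentionally absent from the generator (all groups
share the same masks), mirroring the expectation that volumetry is
insensitive where texture is not; the volume ANOVA stage exists for real
data, where masks differ per subject.
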