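---
title: "Defining subject-specific visual regions from a short movie run"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defining subject-specific visual regions from a short movie run}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Category-selective visual regions — the fusiform face area (FFA) and
posterior superior temporal sulcus (pSTS) for faces, the occipital place
area (OPA), parahippocampal place area (PPA) and retrosplenial complex
(RSC) for scenes, the lateral occipital complex (LOC) for objects — vary in
their exact anatomical position across individuals. The standard way to
find them in a given subject is a blocked localizer experiment: contrast
conditions (faces > objects, scenes > objects, objects > scrambled), rank
voxels inside a probabilistic group parcel by the contrast t-value, and
keep the top k (the group-constrained subject-specific, GSS, approach).
Localizers are long and demand compliance, which rules them out for very
young children. `movieroi` implements an alternative: define the same
subject-specific ROIs (ssROIs) from a single short, engaging movie run, by
regressing each voxel's movie timecourse on mean timecourses of
localizer-defined regions measured in an independent adult cohort.

## The method

**Movie ssROI definition.** For each subject, every parcel voxel's cleaned
movie timecourse is regressed (OLS, with intercept) on 14 predictor
timecourses: the adult-mean movie timecourse of each region's traditional
ssROI (7 predictors) and of each region's *counter ROI* — the bottom-k,
least selective voxels of the parcel (7 more). Counter-ROI predictors soak
up the nonselective, shared component of the movie response; including
them sharpens selectivity. The per-region contrast assigns +1 to the
region's own predictor and −1 to a reference predictor: the object region
(LOC) for face and scene regions, early visual cortex (EVC) for LOC, and
LOC for EVC. Voxels are ranked by the contrast t and the top k = 100 kept.
Adults who contributed predictors get leave-one-out means, so no subject's
data ever predicts itself.

**Timecourse hygiene.** Before any analysis, each run passes through a
fixed sequence: (1) artifact timepoints are flagged when composite head
displacement between consecutive volumes exceeds 2 mm or the global signal
deviates more than 3 SD from its mean; (2) subjects with one third or more
of their timepoints flagged are dropped; (3) flagged TRs are
nearest-neighbour interpolated (ties to the earlier neighbour); (4) one
spike regressor per artifact TR and five CompCor components — principal
components of white-matter voxel timecourses, the white-matter mask eroded
by two voxels — are regressed out; (5) residuals are high-pass filtered by
projecting out a discrete-cosine basis with periods longer than 100 s;
(6) ROI timecourses are voxel means, with artifact TRs set to missing
(NaN-ed) *after* averaging. The order matters: interpolation precedes
regression so spikes do not leak into the CompCor estimates, and filtering
follows regression; a test asserts that permuting the last two stages
changes the output.

The composite-motion formula is not uniquely standard; we use the common
artifact-detection convention of converting each rotation increment to the
worst-case arc displacement on a 65-mm sphere and taking the Euclidean
norm of the six increments. The global-signal mean and SD are computed
over the whole run, including candidate artifact TRs — simple and
deterministic; with realistic spike amplitudes the inflated SD never masks
a spike, and the choice is exposed as an argument.

**Split-half independence.** With only one movie run per child, defining
and measuring on the same data would be circular. ROIs are therefore
defined separately on TRs 1–82 and TRs 86–168 (1-based, inclusive; the
three TRs in between are a guard against temporal autocorrelation and are
never analyzed). Extraction is crossed — first-half timecourse from
second-half-defined ROIs and vice versa — and the two pieces are
concatenated into a 165-TR spliced timecourse.

**Downstream statistics.** Spliced timecourses are Pearson-correlated with
adult target timecourses (Fisher z for group tests; pairwise-complete TRs,
with the pair count reported). Partial correlations residualize both series
on the other regions' targets. Reverse correlation z-normalizes each
subject's timecourse, tests each TR against zero with a one-tailed
one-sample t-test across subjects, and calls maximal runs of two or more
consecutive significant TRs (≥ 4 s) *events*; a child's event response is
the mean of their z-scored timecourse over event TRs. Age trends use
Spearman partial correlations (midranks; residual method; t approximation
on n − 3 df) with the number of artifact timepoints as covariate, because
that motion measure is far from normal. Developmental lag is probed by
shifting child timecourses one TR earlier and comparing correlations to
adult targets with a paired t-test. All reported p-values are two-sided
except the per-TR event test, which is one-tailed by construction.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `motion_mm` | 2 mm | composite-motion artifact threshold (strict >) |
| `gs_sd` | 3 | global-signal threshold, SD units |
| `hp_s` | 100 s | high-pass cutoff period |
| `ncomp` | 5 | CompCor components |
| `k` | 100 | ssROI size, in voxels of the analysis grid |
| `split` | 82 / 86 | last TR of half A, first TR of half B |
| `alpha` | 0.05 | per-TR event-test level, one-tailed, uncorrected |
| `shift` | −1 TR | lag probe (earlier in time) |

The event-test level deserves a note: the reverse-correlation tradition
this follows does not fix a canonical alpha, so 0.05 uncorrected is our
declared convention, stamped into every output. `k` is interpreted
relative to whatever grid the data are on and is configurable, since the
"top 100" convention is grid-resolution-dependent. TRs with fewer than
three contributing subjects (after artifact NaN-ing) are defined
non-significant rather than erroring, because ragged group matrices are
routine.

## What the synthetic generator emulates

The generator writes cohorts with a known answer key. Its defaults are the
emulated study conditions: a 168-TR movie run at TR = 2 s; a 415.8-s
localizer of sixteen 19.8-s stimulus blocks (4 per condition, the block
order palindromic, the first half randomized per run) and five fixation
blocks; a 24×24×18 grid of 2-mm voxels carrying seven disjoint 6×6×6
parcels plus a white-matter block. Within each parcel, 100 voxels are
selective: they carry the region's latent timecourse at unit gain (movie)
and an HRF-convolved response to the preferred condition (localizer);
remaining parcel voxels get a weak anti-preference (gain −0.2). Latents
are white noise smoothed with a 3-TR-FWHM Gaussian kernel (a cheap stand-in
for haemodynamic autocorrelation — downstream methods need realistic
smoothness, not a biophysical model) and mixed to a target correlation
structure: 0.3 within domain, 0.1 across. Voxel noise SD is 0.5 and a
smooth subject-global component (SD 0.2) emulates shared physiological
noise; these amplitudes are synthetic conventions chosen so that recovery
is hard enough to be informative (per-voxel latent correlations around
0.8, not 1.0) — the real study does not characterize movie-evoked signal
amplitude. Artifacts are persistent 3-mm motion steps plus a global-signal
excursion at about 6% of TRs, over a 0.1-mm random-walk background,
matching the artifact counts reported for pediatric scanning. Children
carry two planted developmental effects in pSTS: a fraction of the face
latent mixed in (0.6 at age 3, decaying linearly to 0 by age 8) and a
one-TR response delay below age 5.

What the generator does *not* emulate: spatial autocorrelation and
smoothing, registration error, susceptibility dropout, physiological
recordings, AR(1) temporal noise, or surface geometry. Passing recovery
tests therefore shows the algorithms are correct and well-calibrated on
data satisfying their assumptions — not that the pipeline is robust to
every artifact of real pediatric fMRI.

## Numerical choices and degenerate inputs

- High-pass filtering is DCT-basis regression, the dominant fMRI
  convention for a "100-s cutoff", exactly linear and easy to test against
  a projection oracle, rather than a recursive filter.
- The GLM is OLS without prewhitening. The original SPM analyses used
  AR(1); on synthetic white-noise data the distinction is immaterial to the
  method's logic, and the type-I calibration suite verifies the nominal
  5% level holds. Real-data use should revisit this.
- The canonical HRF is a double gamma with response peak at 6 s,
  undershoot at 16 s, undershoot ratio 1/6, peak-normalized; designs are
  built on a 16× oversampled grid and sampled at volume times.
- PCA signs are arbitrary, so CompCor fixes each component's sign by
  making its largest-magnitude spatial loading positive — determinism that
  regression reproducibility requires. Components with numerically zero
  variance are dropped with a warning.
- Voxels with numerically zero residual variance (possible in noiseless
  synthetic limits) get t capped at ±1e6 and a flag, keeping rankings
  total; correlations of ±1 are clipped to 1 − 1e-15 before `atanh`.
- Ranking ties break by ascending linear voxel index; interpolation ties
  break toward the earlier neighbour; both are documented determinism
  choices.
- Missing data policy: listwise deletion within a GLM fit,
  pairwise-complete TRs for correlations (artifact NaNs differ per
  subject), per-TR missing-aware means for predictors and group means.
- The per-voxel movie regression includes an intercept (the alternative
  conflates mean offsets with selectivity).
- Voxel indices are serialized 0-based in R's native array order (first
  axis fastest); TR indices are 1-based everywhere a human reads them.

## Validation design

Every estimator is checked against an independent oracle: contrast t
against explicit normal-equation OLS; CompCor against an
eigendecomposition of the T×T covariance; partial correlation against the
precision-matrix formula; Spearman partials against the closed form on
ranks. Null calibration uses 200 iid-noise groups of 30 subjects × 168 TRs
(per-TR rejection rate) and 50 pure-noise GLM datasets of 200 voxels × 100
TRs; the expected count of null events has the closed form
$\alpha^2(1 + (T-2)(1-\alpha))$ for independent TRs, which the simulation
must match within its Monte-Carlo interval. Recovery experiments replant
and re-find ground truth: ssROI Dice against planted voxels, artifact
sensitivity/specificity over 20 generated subjects, the planted one-TR lag
over 20 seeds, and the noiseless split-half splice. Pattern-replication
runs the full pipeline on cohorts of 12 synthetic adults (5 seeds) and on
a 12 + 17 + 14 three-group cohort (one seed) — sizes chosen to mirror the
emulated study's group sizes while keeping a full validation run in
minutes on one core.

## Known limitations

Spatial preprocessing (realignment, normalization, smoothing) is out of
scope: inputs are assumed to share a grid. Linear mixed models and
repeated-measures ANOVAs on the output tables are left to standard tools —
the package emits tidy long-format tables ready for them. The
leave-one-out hygiene of predictor construction is asserted structurally
from provenance records, but nothing prevents a caller from handing the
lower-level functions circular inputs directly.
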