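---
title: "Multi-fiber tractography of cerebellar cortex-to-dentate pathways: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-fiber tractography of cerebellar cortex-to-dentate pathways: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dentract)
```

## The problem

Purkinje cells are the sole efferent neurons of the cerebellar cortex, and
their axons converge on the dentate nuclei. Post-mortem studies of autism
spectrum disorder repeatedly report reduced Purkinje cell number and size in
the posterior-lateral cerebellar cortex, which predicts a loss of directional
coherence in the white matter connecting that cortex to the dentate. In vivo,
that prediction is testable with diffusion-weighted MRI tractography: seed
streamlines in the cerebellar cortex, sort them into pathways terminating in
the dorsal and ventral dentate nuclei (DDN, VDN) of each hemisphere, and
compare per-pathway diffusion metrics between groups.

Two obstacles make this hard on clinical data. First, cerebellar white matter
is dense with crossing fibers, which a single diffusion tensor cannot
resolve. Second, pediatric acquisitions differ systematically in head motion
and physiological artifacts between sedated and unsedated groups, which can
masquerade as group differences. `dentract` implements the full analysis
chain that addresses both: a multi-fiber per-voxel model estimated by
alternating independent component analysis with ball-and-stick fitting,
deterministic streamline tracking through the resulting field, ROI-sorted
pathway metrics, robust tensor estimation with outlier rejection, a scalar
head-motion index used as a covariate, and the group and single-subject
statistics. Because no clinical data are deposited, the package ships a
synthetic phantom generator with complete ground truth; every stage is
validated against it.

## The signal model

A voxel's diffusion-weighted signal at b-value $b$ and unit gradient
direction $g$ is modelled as one isotropic "ball" plus up to three perfectly
anisotropic "sticks" with orientations $v_j$ and volume fractions $f_j$,
sharing a single diffusivity $d$:

$$S(b, g) = S_0\left[\left(1 - \sum_j f_j\right) e^{-bd}
  + \sum_j f_j\, e^{-bd\,(g \cdot v_j)^2}\right].$$

Sticks are axial quantities: $v_j$ and $-v_j$ are the same fiber population,
and every estimate is reported with the first nonzero coordinate positive.
The shared-$d$ assumption is the classical ball-and-stick parameterisation;
it keeps the per-voxel problem well-conditioned at a single shell
(b = 1000 s/mm², 55 directions — the acquisition the defaults mirror, with
1.88 × 1.88 × 3 mm voxels).

## Multi-fiber estimation: ICA + ball-and-stick

Per voxel, `fit_voxel_icabsm()`:

1. **Window construction.** An eleven-voxel neighbourhood is assembled
   around the centre — the centre, its six face neighbours, and its four
   in-slice diagonal neighbours — and each member contributes one row of
   attenuations $S/S_0$ over the b > 0 gradients. The in-slice-biased
   geometry reflects the anisotropic voxel (slices nearly twice as thick as
   the in-plane spacing): in-plane neighbours are physically closer, so they
   are preferred before reaching across slices. Because only the
   neighbourhood's *size* is conventionally stated, the layout is
   configurable (`"face"` = 7, `"eleven"` = 11, `"cube"` = 27). Members
   outside the mask or with non-positive $S_0$ are dropped; fewer than three
   usable rows is a degenerate window and the voxel falls back to a
   single-tensor stick.
2. **Source decomposition.** PCA on the window's data matrix decides how
   many components to retain (eigenvalue share ≥ 5%, capped at 3 and at the
   matrix rank); deflationary FastICA with the logcosh contrast (a smooth,
   even nonlinearity), run on the whitened rows with a seed derived from the
   run configuration and a 500-iteration cap, separates the attenuation
   profiles of the fiber populations mixed across the window. ICA operates
   on attenuations rather than raw signals so the decomposition is invariant
   to $S_0$ variation across the window. Non-convergence falls back to the
   PCA components. Each profile is sign-normalized to nonnegative mean and
   scaled to unit maximum.
3. **Per-source stick fit.** Each profile is fit by least squares with
   $c\,e^{-bd (g\cdot v)^2}$, initialising $v$ from the principal
   eigenvector of the log-profile tensor. Flat profiles yield no stick.
4. **Alternation.** With orientations fixed, all volume fractions and the
   shared $d$ are refit by constrained least squares (nonnegative fractions,
   sum ≤ 1) against the centre voxel's attenuations; then each orientation
   is refined against the centre voxel holding the other compartments
   fixed. The loop stops when fractions change by less than $10^{-3}$ or
   after 10 iterations. When the decomposition yields a single source, the
   centre voxel's secondary tensor axis is offered as an extra candidate —
   crossing bundles can collapse into one source when the window mixes them
   in near-identical proportions — and survives only if the constrained fit
   assigns it a fraction above the prune threshold.
5. **Pruning.** Sticks below a 0.05 fraction are removed (a fit-time floor,
   deliberately below the 0.15 tracking threshold so that tracking applies
   its own documented gate), and fractions plus ball renormalize to 1.

The whole-mask wrapper `fit_stick_field()` also reports the *no-stick
density* — the fraction of mask voxels with no surviving stick compartment —
used as a per-subject index of lost fiber coherence.

## Tracking

`seed_and_track()` distributes the configured number of seed points (2000 by
default) uniformly over the seed-mask voxel volumes and launches one
bidirectional streamline per seed along the voxel's most prominent stick;
the two half-tracks are concatenated. Each step:

- interpolates the incoming direction from the 8 voxels at the corners of
  the trilinear cell around the current position — per corner, among sticks
  with fraction > 0.15, the orientation (sign-resolved toward the previous
  direction) with the smallest turning angle is selected, and the selections
  are blended with the trilinear weights;
- terminates if no corner contributes, or if the incoming direction turns
  more than 60° from the previous one;
- otherwise advances 0.2 voxel widths along the equally weighted (0.5/0.5)
  blend of previous and incoming directions, terminating on mask exit or
  after 2000 steps per half-track.

Bidirectional launching is the field convention for seeds placed mid-bundle;
it is configurable off. One consequence of trilinear interpolation plus
direction smoothing is worth stating: the incoming direction is *continuous*
in position, so a smooth 70° bend spread over an interpolation cell is
followed (each per-step turn stays below the threshold) rather than
angle-terminated. The angle rule fires when the eligible neighbourhood
disagrees with the current direction by more than 60° within a single step —
for example a seed voxel whose dominant stick lies below the tracking
threshold inside a differently oriented field, or incoherent fits in noisy
data. Both behaviours are pinned by tests.

## Pathways and metrics

Streamlines are sorted to the first target mask reached along arc length
from the seed point (a streamline touching no target is discarded but
counted, so streamline counts are conserved). For each pathway, a visitation
map counts *distinct* streamlines per voxel; voxels with strictly more than
5 visits form the pathway voxel set. SC is the pathway's streamline count,
SV the summed volume of pathway voxels (at the study voxel size each voxel
contributes 10.6032 mm³), and FA/AD/RD are unweighted means of the tensor
maps over pathway voxels. SC counts all sorted streamlines of the pathway,
before the visitation threshold, which only defines the voxel set.

## Robust tensor fit

FA/AD/RD maps come from a per-voxel single-tensor fit with iterative outlier
rejection: equal-weight nonlinear least squares (Gauss–Newton on
$S = \exp(X\beta)$, initialised from the log-linear solution), flagging of
measurements whose residual exceeds 3 robust standard deviations (median
absolute deviation × 1.4826), and refitting on the retained set until the
flag set stabilises (≤ 10 iterations), with a final ordinary fit on the
retained measurements. b = 0 frames are never rejected (they anchor $S_0$),
at least 7 measurements must survive (6 tensor degrees of freedom plus
$S_0$), and the tensor is projected to positive semidefinite by clamping
negative eigenvalues. The robust scale uses a relative floor
($10^{-9}$ of the mean signal) so that exact fits do not flag
numerically-zero residuals. The rejection constant and the MAD scale are
conventions: the published description of the informed variant specifies the
loop (fit → reject → refit) but not its constants.

The per-voxel rejections are also aggregated per frame: a frame rejected in
at least 30% of valid mask voxels is treated as a whole-frame dropout
(pulsation or motion-related), and the pipeline excludes it from the
multi-fiber stage, which has no outlier model of its own. On phantoms at the
reported 7–9% dropout rates the separation is sharp — injected frames are
rejected in 57–100% of voxels, clean frames in at most ~5% — so the 30%
default sits in a wide gap.

## Motion quality control and correction

Each b > 0 frame is rigidly registered to the first b = 0 frame by
Nelder–Mead minimisation of the mean squared intensity difference under
trilinear resampling (same subject, same modality — plain MSE suffices),
restarted up to three times because the simplex tends to collapse early on
image-matching costs. The scalar motion index is the sum over the six rigid
parameters of the mean absolute between-frame displacement; it is unitless
(millimetres and radians are summed), zero for a static series, and
invariant to constant offsets. Rotations enter in radians. An externally
estimated parameter table can be supplied instead of running registration.

The package also applies a minimal rigid motion *correction* (per-frame
inverse-rigid resampling using either the registration output or a supplied
trace) before fitting. The full preprocessing of clinical data (eddy-current
and susceptibility correction) is out of scope here, but the synthetic
cohort injects real rigid motion, and every downstream stage assumes aligned
frames — exactly as the clinical pipeline consumed corrected data. Gradient
reorientation after rotation is not applied (rotations at QC scale are a few
degrees; the caveat is logged).

## Statistics

Group comparisons fit, per pathway, `value ~ group + age + motion` and
report the covariate-adjusted (partial) F-test of the group term with raw
per-group means ± SD, plus a Wilks' Λ omnibus across the four pathways;
per-pathway p-values are primary, matching the shape of the reported
clinical tables. No multiple-testing correction is applied in the primary
columns, mirroring that reporting; a Benjamini–Hochberg column is emitted
and labelled as an extension. Constant covariates are dropped with a
warning, which reduces the test to the unadjusted comparison (pinned against
a two-sample t oracle in the tests).

Single-subject flagging uses two criteria, both strict inequalities:
below `mean(ref) − 3·SE(ref)` with SE computed from the reference group's
own n (the reference-group notation implies as much), and below the
empirical 10th percentile (linear interpolation). Note the three-SE rule is
*not* a rare-event threshold: at n = 14 it sits 0.80 SD below the reference
mean, below which ~21% of an exchangeable test group falls — the tests
assert that calibration rather than a near-zero rate. Partial Pearson
correlations correlate the residuals of both variables after regressing out
age and motion, with n − 4 degrees of freedom. Within-group age regressions
report R², slope, and the slope's p-value; under the null the expected R²
is 1/(n−1), which the tests verify by simulation.

## The phantom generator

`simulate_subject()` renders ball-and-stick bundles (polyline centerlines
with radius, fraction, and optional per-voxel orientation dispersion) on a
grid inside a head-like ellipsoid (air outside, so registration has the
spatial structure a real acquisition has), then injects, in order: rigid
motion per diffusion frame (a smooth random walk over all six parameters,
with per-step SDs of 0.4 mm and 0.02 rad per unit amplitude, so the
resulting motion index approximates the amplitude), whole-frame signal
dropout (probability `outlier_rate` per frame, attenuation factor uniform
in [0.2, 0.6]), and Rician noise (magnitude of complex Gaussian with channel
sigma $S_0/\mathrm{SNR}$). Everything injected is recorded in the truth
object. Defaults are the study acquisition (55 directions at b = 1000 plus
one b = 0, 1.88 × 1.88 × 3 mm voxels), $S_0 = 1000$, and
$d = 1.7\times10^{-3}$ mm²/s — a typical white-matter axial diffusivity;
the study states no tissue ground truth, so these are conventions, not
reproductions, and SNR 30 is a typical clinical magnitude SNR.

`make_cerebellum_phantom()` is the end-to-end fixture: one curved seed
ribbon per hemisphere (posterior-lateral cortex surrogate) connected by
curved bundles to two target blobs per side (DDN/VDN surrogates). Group B of
`simulate_cohort()` degrades one pathway (right VDN by default) by reducing
its stick fraction 30% *and* adding 20° of per-voxel orientation dispersion.
The dispersion is the substantive choice: the hypothesized pathology is loss
of directional coherence, and a fraction reduction alone (0.6 → 0.42) leaves
every stick above the 0.15 tracking threshold, lowering FA but barely
touching streamline counts; dispersion degrades FA, SC and SV together, as
the clinical comparison reports. Group motion amplitudes are drawn from
Normal(2.00, 0.67) and Normal(1.12, 0.63) — the two groups' published motion
indices — and dropout rates 9.1% vs 7.2% match the reported outlier rates.
Ages are uniform on 3.6–14 years.

What the phantom does **not** emulate: anatomy (the geometry is a
topological surrogate, not a cerebellum), eddy-current or susceptibility
distortion, cardiac pulsation, multi-shell acquisitions, partial-volume
gray matter, or spatially varying SNR. Tests passing on these phantoms
demonstrate that the algorithms implement their contracts and recover known
truth under the stated noise model — not that the clinical effect sizes
would reproduce.

## Problem sizes

The validation suite and the acceptance script run at desk scale, chosen so
the full chain is exercised in minutes on one core: single-voxel inversions
and tensor oracles use the full 55-direction scheme; crossing-recovery
Monte Carlo uses 100 seeded repeats at 90° (50 at 60° and 40°) on a
12 × 12 × 5 grid; tracking contracts use 2000 seeds on 24 × 12 × 6 and
22 × 22 × 6 grids; the motion Spearman check registers 20 subjects at 8
directions on 16 × 16 × 6; statistical calibration simulates 1000 null and
200 powered cohorts at the study's 14 + 15 sizes; and the end-to-end cohort
runs 29 subjects at 30 directions on a 30 × 30 × 8 grid with 1500 seeds and
supplied motion traces (the registration path is validated separately —
the bypass is itself a documented interface).

## Known limitations

- The per-voxel fit costs tens of milliseconds in pure R; whole-brain
  clinical grids would want compiled inner loops or parallel voxel batches.
- MSE registration is same-modality only, and correction resamples once
  (interpolation blur is visible as a small FA depression on phantoms).
- The eleven-voxel window geometry is a documented convention; other
  definitions of an "eleven-neighbourhood" exist and are selectable.
- Sticks share one diffusivity per voxel; free water, kurtosis, and
  weighted-least-squares variants are out of scope.
- At 40° crossings the two-stick recovery rate drops steeply — a known
  single-shell limitation, visible in the monotone angle-resolution curve.
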