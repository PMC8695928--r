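---
title: "Bilateral differential topography: model, simulator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bilateral differential topography: model, simulator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilatopo)
```

## The screening problem

Keratoconus and post-surgical corneal ectasia begin focally: the cornea
thins and steepens around a cone whose position, width and amplitude
differ between a patient's two eyes. Unilateral indices (maximum
keratometry, thinnest pachymetry, elevation at the thinnest point) miss
the earliest cases — in particular forme fruste keratoconus (FFK), the
topographically normal fellow eye of a unilateral keratoconus patient —
because each eye, viewed alone, can sit inside normal limits. What is not
normal in FFK is the *pair*: fellow eyes are near-perfect enantiomorphs,
and keratoconus breaks that mirror symmetry early.

`bilatopo` operationalises this observation. It consumes the raw per-eye
topographic matrices a Scheimpflug analyzer exports and reduces each
OD/OS pair to twelve inter-eye asymmetry parameters.

## The differential algorithm

Inputs are 121 × 121 grids at 0.1 mm spacing with the corneal vertex
frozen at cell (61, 61): front keratometry (FK, D), front/back elevation
(FE/BE, µm), pachymetry (CP, µm); back keratometry is read and validated
but takes no part in the differential parameters. For each modality:

1. `mirror_flip()` reverses the right-eye grid's columns
   (`c → 122 − c`). Fellow-eye anatomy mirrors nasal–temporal, i.e.
   across the vertical meridian, so the flip axis is the column axis;
   rows are untouched and the central column is fixed pointwise. The
   operation is an involution.
2. `differential_map()` forms `|OS − flip(OD)|`. A cell is missing in
   the result iff it is missing in either operand; unmeasured cells are
   `NA` throughout, never silently zero. Because of the absolute value,
   swapping the two eyes only column-flips the differential grid, so all
   summaries below are eye-order invariant (asserted by test).
3. `roi_mask(1.5)` enumerates the lattice offsets within 1.5 mm of the
   vertex, boundary inclusive. The membership rule is Euclidean
   (`0.1·sqrt(di² + dj²) ≤ 1.5`), giving N = 709 cells — the count is
   exposed so an exclusive-boundary variant could be audited against it.
4. `characteristic_triplet()` returns the zone's maximum, mean and
   standard deviation. The SD uses the population divisor N, following
   the defining radical formula literally rather than the N − 1
   convention of spreadsheet functions; for N = 709 the numerical
   difference is below 0.1 %, but the choice is fixed and tested.

`compute_parameters()` applies steps 2–4 to FK, FE, BE and CP and returns
the named vector `dFKmax … dCPsd`. No spatial registration is performed
between the eyes: grids are assumed vertex-aligned by the device, and no
cyclotorsion or pupil-offset correction is attempted.

Missing cells inside the 1.5-mm zone are an error by default; with
`allow_missing = TRUE` the summaries use the measured cells and report
the effective N. Devices normally resolve the central 3-mm zone
completely, but the switch covers exports that do not.

## Reference thresholds and diagnostics

`kc_reference()` ships the per-parameter diagnostic statistics
established on a clinical case–control cohort of 161 keratoconus/ectasia
and 174 control subjects: Mann–Whitney Z, AUROC with 95% CI, cutoff,
sensitivity and specificity. `classify_subject()` flags a parameter when
its value is at or above the cutoff (boundary inclusive) and calls a
subject positive when any of the four headline parameters flags —
ΔFKmean ≥ 0.75 D, ΔFKsd ≥ 0.67 D, ΔFEsd ≥ 2.9 µm, ΔFEmax ≥ 14.6 µm. The
reference performances are per-parameter, so the any-of combiner is an
explicit extension and is kept out of `evaluate_cohort()` reports.

The statistical layer mirrors the conventions under which those reference
numbers were produced:

- `mann_whitney()` computes U from midranks and
  `Z = (U − n₁n₂/2)/√V` with the tie-corrected variance and *no*
  continuity correction. This choice is not arbitrary: with it, the
  normal-approximation inversion
  `implied_auroc_from_z(Z, n1, n2) = 1/2 + |Z|·√(n₁n₂(n₁+n₂+1)/12)/(n₁n₂)`
  reproduces every one of the reference AUROCs from the corresponding
  reference Z at 3-decimal rounding — an internal-consistency check the
  acceptance suite runs in full.
- `empirical_auroc()` credits ties ½, making the identity
  `AUC = U/(n₁n₂)` exact (tested on thousands of random tied instances).
- `roc_cutoff()` scans thresholds at midpoints between consecutive
  distinct scores (a cutoff need not be an observed value). The reported
  cutoff maximises Youden's J; "highest sensitivity and specificity" is
  not a formal criterion, so Youden was adopted, with ties broken toward
  higher specificity and then lower threshold, and the full curve is
  returned so other criteria can be applied. The 95% CI uses DeLong's
  method (cross-checked against `pROC`); the reference CIs' method is
  unpublished, so agreement there is not asserted.

```{r}
ref <- kc_reference()
all(round(implied_auroc_from_z(ref$Z, ref$n_kc, ref$n_control), 3) ==
      ref$auroc)
```

## The paired-cornea simulator

No patient grids are distributed, so the simulator is a first-class
module: it generates OD/OS exam pairs with the co-signatures of
keratoconus (steepening, thinning, raised elevations, all sharing one
cone locus) at controllable asymmetry, and every pipeline stage is tested
against it.

**Surfaces.** Each corneal surface is a conicoid
`z = ρ²/(R + √(R² − (1+Q)ρ²))` plus a cylindrical term for corneal
astigmatism plus a Gaussian cone `A·exp(−((x−x₀)² + (y−y₀)²)/2σ²)` that
*reduces* the sag (the cone protrudes forward). The minimal model was
chosen because it reproduces, with one shared cone locus, all three
keratoconus map signatures at once. The posterior surface carries the
same bump scaled by `post_cone_scale > 1`, thinning the cornea under the
cone. Anterior surfaces are evaluated to 6 mm from the vertex, posterior
to 5 mm; the square grid's corners are `NA`, as in device exports.

**Keratometry.** Maps use axial (sagittal) curvature,
`r_ax = ρ√(1+z′²)/z′` with `z′` the radial slope from central
differences, matching common device FK-map semantics; tangential
curvature could be swapped in at one site. Powers are
`337.5/r_ax` (anterior) and `−40/r_ax` (posterior) — keratometric-index
constants chosen so that simulated scalar summaries land inside the
reference cohort's observed ranges (a 7.85-mm sphere gives 43.0 D mean
front keratometry; a 6.50-mm posterior sphere −6.15 D). Within 1 mm of
the vertex the axial curvature is blended linearly with the surface's
exact mean curvature: the axial formula degenerates at ρ → 0, and on
cones displaced from the instrument axis the radial slope can cross
zero, which would produce unphysical power spikes. For a sphere both
curvatures coincide, so the blend is seamless (the sphere map is
constant to 0.01 D by test).

**Elevation.** The reference surface is the least-squares sphere over an
8-mm zone with its centre constrained to the vertex normal and free
radius and axial offset — the float-sphere construction of clinical
elevation displays, whose proprietary details are unpublished. An
algebraic (linear) sphere fit provides the start; Nelder–Mead minimises
the geometric sag residual. Elevation is `1000·(z_BFS − z_surface)` µm,
so a cone yields a positive peak; the sign convention is fixed and
asserted. The fit's cells are sorted into a canonical order first, making
the fit invariant to grid orientation.

**Pachymetry.** `CCT + 1000·(z_post − z_ant)` µm: anchored at the vertex
by the central thickness, increasing peripherally (posterior surface
steeper than anterior), and dipping below CCT under the cone — the
thinnest point migrates toward the cone, as clinically observed.

**Pairs and noise.** The right eye follows the base profile; the left is
the mirrored profile (cone `x₀ → −x₀`, astigmatism axis `→ 180° − axis`)
with normally jittered biometry and the cone amplitude scaled by
`fellow_amp_frac` (0 = FFK pattern). Measurement noise is white Gaussian
convolved with a 0.3-mm kernel — device smoothing leaves spatially
correlated error, and uncorrelated noise would understate zone maxima —
rescaled to a per-modality sd. True inter-eye parameter correlations in
normal subjects are not published; the jitter scales are calibration
knobs, documented as such.

**Calibration.** Defaults were set once so that (a) simulated scalar
summaries (FKm, FKmax, BKm, TCT, CTV) fall inside the reference cohort's
per-group ranges, and (b) a simulated normal cohort's differential
parameters land near the reference control-group means (ΔFKmean ≈
0.45 D, ΔFEmean ≈ 2.4 µm, ΔBEmean ≈ 5.8 µm, ΔCPmean ≈ 11.8 µm); noise
sds are 0.33 D (FK/BK), 2.3 µm (FE), 5.6 µm (BE) and 8.5 µm (CP).
Keratoconic subjects draw cone amplitude ~N(0.075, 0.04) mm truncated to
[0.02, 0.2], width ~N(1.5, 0.3) mm, an infero-temporal centre, posterior
scaling ~N(1.5, 0.15), and a fellow-eye amplitude fraction uniform on
[0.1, 0.6], with a 25 % FFK subset near zero. Group sizes default to the
reference cohort's 161/174. These constants were frozen after one
calibration pass and are not tuned per run.

**Exactness of the null.** A zero-noise, zero-jitter, symmetric-cone
pair must give twelve *exact* zeros, which requires every map operation
to commute bitwise with a column flip. Three numerical details secure
this: the astigmatism axis trig is evaluated on the acute angle via
`cospi`/`sinpi` with an explicit sign; second-difference stencils are
grouped `(A + C) − 2B`; and the BFS fit sorts its cells canonically.
None of these changes any result beyond the last ulp.

## What the simulator does and does not show

The simulator emulates smooth parametric corneas with a single Gaussian
cone and stationary correlated noise. It does not model Scheimpflug image
formation, tear-film or fixation artefacts, pellucid-type inferior
crescents, multi-lobed cones, epithelial remodelling, or the true joint
distribution of biometry between fellow eyes. Tests passing on simulated
cohorts therefore demonstrate that the algorithm recovers engineered
asymmetry under realistic magnitudes and noise — group separation with
the observed front-surface-over-pachymetry ordering — not that the
shipped clinical cutoffs attain their published sensitivities on new
patients. The reference AUROC/sensitivity/specificity values derive from
the 335-subject clinical cohort, whose raw data are not redistributable;
the package's reproduction of them is the Z-to-AUROC consistency check
above.

## Degenerate inputs and edge behaviour

- Grids that are not 121 × 121 are structural errors naming the actual
  shape; unparseable cells are reported with row and column.
- Sign-convention violations (non-positive FK/CP, non-negative BK) warn
  by default and error under `strict = TRUE`, since exported BK signs
  vary by device firmware.
- `roi_mask(0)` is the vertex alone (N = 1); negative radii are errors.
- Zone membership uses a 1e-9 absolute slack so exact-boundary cells
  (e.g. (0, ±15) at 1.5 mm) are not lost to floating rounding.
- All-identical samples give Z = 0, p = 1; single-class ROC inputs are
  errors.
- Duplicate subject ids and empty manifests are errors; subjects with
  incomplete exams are skipped with a logged count, never silently
  dropped.

## Problem sizes used by the checks

The acceptance script simulates 50 keratoconus + 50 control pairs
(about a minute end to end) — large enough that all twelve group
comparisons and the AUROC ordering are stable across seeds, small enough
to run routinely; the unit suite uses smaller cohorts (2–8 pairs) for
I/O and determinism checks and full-size random grids for the oracle
equivalences.
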