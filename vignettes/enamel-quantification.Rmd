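---
title: "Quantifying enamel demineralization from OCT B-scan stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying enamel demineralization from OCT B-scan stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octenamel)
```

## The measurement problem

Demineralization — the calcium loss that precedes caries — changes a tooth
in three ways an intensity-calibrated OCT cross section can see: the
enamel band thins, its optical backscatter falls, and at later stages the
dentino-enamel junction (DEJ) stops producing a resolvable secondary
reflection. This package quantifies all three from stacks of reconstructed
8-bit B-scans: enamel thickness from an averaged A-scan depth profile,
depth-resolved signal loss from binned total intensity, and the remaining
sound enamel from threshold voxel counting.

Throughout, a B-scan is stored rows-by-columns with row 1 on the shallow
(air) side; depth increases with the row index. Raw data keep their
*optical* row pitch; the tissue refractive index enters only when a result
is expressed in physical micrometres. All indices are 1-based, R's native
convention.

## Geometry and depth scaling

A `voxel_geometry` carries the lateral pitch `lx`, the axial (optical)
pitch `ly`, the inter-frame spacing `lz` — defaults 12, 12 and 7 µm — and
the tissue refractive index `n_tissue`, default 1.63, the conventional
value for tooth structure. One image row spans `ly / n_tissue` = 7.36 µm
of tissue. The refractive index is deliberately a plain config parameter:
published axial-resolution pairs for dental OCT systems imply values
anywhere between about 1.6 and 1.66, and a user calibrating against a
different instrument should be able to change it in one place.

## A-scan depth profiling

`averaged_profile()` implements the profile procedure:

1. **Peak search.** The global maximum of each of the `width` (default 15)
   A-scan lines is located (`detect_peak_index()`); ties break to the
   shallowest row. In real dental B-scans this maximum is the specular
   Fresnel reflection at the air–enamel interface.
2. **Flattening.** Every line is shifted axially by an integer number of
   rows so its peak lands on the *median* of the detected peak indices
   (lower median for an even count — robust to a single outlier line).
   Vacated samples are zero-filled; no interpolation or wraparound, so
   pixel intensities are preserved exactly for the later total-intensity
   analysis. Flattening is idempotent, and the applied shifts are kept for
   audit.
3. **Average and normalize.** The aligned lines are averaged per depth
   sample and divided by the maximum, so the surface peak is 1.

### Enamel thickness

How to read thickness off such a profile is genuinely open — peak-to-peak
and edge-to-edge conventions both exist — so the package defines its rule
explicitly and treats every constant in it as a config parameter of
`estimate_enamel_thickness()`:

* the **surface** is the raw profile maximum (the flattening reference);
* descending from it, the profile must fall into a **trough** below
  `valley_fraction` (default 0.5) of the surface value — the attenuated
  signal at the enamel bottom;
* the **DEJ** is the first local maximum after the trough that rises at
  least `dej_prominence` (default 0.08) of the surface value above it;
* thickness is `(dej_index - surface_index) * ly / n_tissue`.

Three numerical details matter in the presence of speckle, and each was
chosen after simulating the estimator on speckled phantoms:

* Extrema are searched on a moving-average smoothed copy of the profile
  (half-width `smooth_halfwidth`, default 2 samples ≈ 15 µm), but a trough
  qualifies on the *raw* minimum within its smoothing neighbourhood.
  Under thin enamel (≈100 µm) the trough is only one or two samples wide
  and smoothing alone fills it in, which would push the detected junction
  a whole layer too deep.
* The deepest qualifying trough is carried forward until a sufficiently
  prominent peak ends the search. Without the prominence gate, speckle
  bumps inside the trough trigger premature DEJ calls; without carrying
  the trough forward, a single early noise minimum would anchor the
  search too shallow.
* The reported DEJ row is refined to the steepest single-sample rise of
  the raw profile between trough and smoothed peak. A smoothed argmax
  systematically lands ~2 rows past the junction; the rise onset marks
  the enamel/DEJ boundary itself.

Profiles whose pre-normalization peak is below `min_peak` (default 10 of
255) are rejected as having no detectable surface; profiles with no
qualifying trough or no prominent post-trough peak return `NA` thickness
with a diagnostic — on a carious sample the junction may genuinely be
gone, and the estimator must say so rather than guess.

Percent reduction against a healthy reference is
`100 * (1 - t/t_ref)`, reported to one decimal with half-up rounding.
(Note one published worked pair, 150.30 µm against 255.45 µm, computes to
41.16% and prints as 41.2% under this convention; the reference report
truncated it to 41.1%, so comparisons allow a ±0.1 point slack there.)

## Depth-binned total intensity

`bin_total_intensity()` sums pixel intensity in consecutive physical depth
bins, by default four 250 µm bins covering the visible 1 mm. Two
conventions are the package's own and are stated rather than guessed:

* **Bins are half-open** `[lo, hi)`. The bins then partition the analyzed
  range, and the sum of bin totals equals the pixel sum of that range
  *exactly* — an invariant the tests enforce against a brute-force loop.
* **Depth 0 is anchored at the per-frame tooth surface**, not at image row
  0. B-scans carry an air gap above the tooth; binning from the image top
  would dilute the first bin with background. `detect_surface_rows()`
  supplies the anchor (lower median of per-column peak rows), or the
  caller passes explicit rows.

Per-frame averages are the summed totals divided by the frame count and,
optionally, by a single `reporting_scale`. Absolute arbitrary-unit levels
of a given instrument are not recoverable from published tables, so the
package asserts orderings and conservation, never absolute a.u. values.
Source-power drift can be compensated per frame by a factor bounded to
[0.95, 1.05] (`compensate_power()`); the factor is an explicit per-run
parameter, recorded in the frame's processing log, because no principled
per-frame estimate of it exists.

## Threshold volumetry

`residual_volume()` counts, per frame, the pixels of a fixed rectangular
window whose intensity lies in an inclusive range — default
45 ≤ TH ≤ 255, which keeps the bright enamel band and excludes the dark
background — and accumulates

    V_tot = sum_i N_i * lx * ly * lz

in mm³, 1008 µm³ per voxel at the default geometry. Both threshold bounds
are inclusive, the window is one rectangle applied to every frame, and no
morphological cleanup is performed: the method counts raw qualifying
pixels.

The published reference count/volume pairs for the five clinical
specimens are mutually consistent but do not follow this formula: each
pair implies an effective voxel volume of ≈1348 µm³ (coefficient of
variation 0.2% across specimens) rather than the nominal 1008 µm³.
`volumetry_calibration_check()` computes both the literal-formula volumes
and the implied constant so the discrepancy is documented
programmatically. The package implements the formula literally and leaves
the effective per-voxel volume overridable (`voxel_volume_um3`); it does
not guess which calibration produced the published numbers.

## The tooth phantom

No clinical stacks ship with the package, so validation rests on
`phantom_spec()` / `generate_volume()`: layered slabs in physical depth
(defaults mimicking a healthy molar — enamel to 250 µm with base
reflectivity 200, a DEJ band to 600 µm at 150, dentin to 800 µm at 110,
each with exponential attenuation), a specular surface reflection raising
the topmost tissue row to 255, optional linear surface tilt, and lesions
that scale backscatter by `reflectivity_scale` ≤ 1 down to a stated depth
while eroding the local enamel top. Speckle is multiplicative
gamma-distributed noise with mean 1 (shape 8 by default, a moderately
averaged speckle contrast; 0 disables it), applied before clipping to
[0, 255] and half-up quantization. Per-frame RNG streams derive from the
master seed, so a frame's content is independent of generation order and
identical spec + seed reproduces a stack bit-exactly.

Every generated stack comes with an analytic ground truth (per-column
enamel rows, voxel counts, physical volume) computed from the same
row/depth arithmetic the renderer uses, which is what makes exact
noise-free recovery tests possible.

What the phantom does *not* emulate — and what passing tests therefore do
not show about clinical data: wave-optical speckle correlation (real
speckle is spatially correlated; the phantom's is i.i.d.), depth-dependent
sensitivity roll-off and focus effects, refraction at the tilted surface,
curved or irregular layer boundaries, pits and fissures, and any
calibrated relation between mineral loss and scattering coefficient. The
lesion contrast defaults are chosen to be qualitatively realistic
(demineralization lowers backscatter), not calibrated to histology.

## Validation problem sizes

The shipped tests validate: peak search against brute-force argmax (1000
random columns); flattening idempotence and shift equivariance; depth-bin
conservation against a brute-force double loop; volumetry against
brute-force voxel enumeration (100 random 20×20×5 stacks, exact);
thickness recovery on 100 speckled phantoms with enamel thickness drawn
uniformly from 100–300 µm (median absolute error within two physical
axial pixels, 14.7 µm; observed ≈4–5 µm); exact noise-free and ≤5%
speckled volume recovery on slab phantoms (20 seeds); and the
healthy > partially demineralized > carious ordering of every depth bin's
mean intensity (20 seeds). Stack sizes in the tests (e.g. 200×20×1 for
profile phantoms, 110×200×3 for volumetric slabs) are chosen as the
smallest geometries that exercise the full 1 mm depth range at the
default pitch; clinical-scale stacks (1024×500×500) differ only in cost,
not in code path.

## Known limitations

* The thickness rule assumes a resolvable DEJ reflection; fully carious
  profiles correctly return `NA`, but heavily smoothed or very low-SNR
  profiles may too.
* Surface detection is an argmax: on speckled data the detected surface
  row is biased up to a few rows deep even with the specular boost, which
  is why thickness accuracy is quoted as a median over many windows
  rather than per-scan.
* The depth-bin a.u. scale is instrument-specific; only orderings and
  conservation are meaningful across instruments.
* Volumetry counts every in-range pixel; bright non-enamel structures
  inside the window (e.g. specular artifacts) are counted as enamel.
  Choosing the window to avoid them is the operator's task, as it is in
  practice.
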