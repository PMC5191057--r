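# octenamel

Quantitative assessment of dental enamel demineralization from optical
coherence tomography (OCT) B-scan stacks.

Early caries begins as mineral loss in the enamel: the enamel thins, its
optical backscatter drops, and the dentino-enamel junction (DEJ) becomes
harder to resolve. Intensity-calibrated OCT cross sections make all three
effects measurable without ionizing radiation. This package implements the
three quantification methods an examiner needs for that, plus a synthetic
tooth-phantom generator with known ground truth so every stage can be
validated without clinical images. It is aimed at researchers working with
reconstructed dental OCT intensity stacks (8-bit, 0–255) in multi-page
TIFF or raw-binary form.

## Methods

**Averaged A-scan depth profile and enamel thickness.** A window of *W*
adjacent A-scan lines (default *W* = 15) is cropped from a B-scan. The
global intensity maximum of each line — the specular surface reflection —
is located, and every line is shifted axially so all peaks align on the
median peak index ("flattening", which removes surface tilt). The aligned
lines are summed, averaged, and normalized to a single depth profile.
Depth is converted from optical to physical units by the tooth refractive
index *n* = 1.63: one image row spans *l*y/*n* micrometres. Enamel
thickness is read off the profile as the distance from the surface peak to
the DEJ peak — the first sufficiently prominent local maximum after the
profile has fallen into a trough below half the surface value — and is
compared against a healthy reference as a percent reduction
100 × (1 − *t*/*t*ref).

**Depth-binned total intensity.** The total pixel intensity of each frame
is accumulated in physical depth bins below the detected tooth surface
(default: four 250 µm bins over the visible 1 mm), summed over the stack
and averaged per frame. Demineralization lowers the scattering signal, so
bin totals order healthy > partially demineralized > carious at every
depth. Bins are half-open and conserve the pixel sum of the analyzed range
exactly. A per-frame source-power compensation of at most ±5% can be
applied first.

**Threshold volumetry of the enamel residual.** Within a fixed rectangular
image window, each frame's pixels inside an inclusive intensity threshold
range (default 45 ≤ *TH*en ≤ 255) are counted as enamel. Each counted
pixel contributes one voxel of *l*x × *l*y × *l*z µm³
(12 × 12 × 7 µm = 1008 µm³ by default), giving

&nbsp;&nbsp;&nbsp;&nbsp;*V*tot = Σᵢ *N*ᵢ · *l*x · *l*y · *l*z ,

reported in mm³. (The published reference count/volume pairs imply a
constant effective voxel volume of ≈1348 µm³ instead of the nominal
1008 µm³; `volumetry_calibration_check()` documents this discrepancy
programmatically, and the effective voxel volume is overridable.)

**Phantoms.** `phantom_spec()` describes a layered tooth stack — enamel,
DEJ band, and dentin slabs with per-layer exponential attenuation, a
specular surface reflection, optional surface tilt and demineralization
lesions (reduced backscatter, eroded enamel), multiplicative gamma speckle
— and `generate_volume()` renders it with an analytic ground-truth record
(layer rows, enamel voxel count and volume).

## Worked example

```r
library(octenamel)

healthy <- phantom_spec(rows = 200, cols = 40, frames = 2, seed = 11)
gen  <- generate_volume(healthy)
prof <- averaged_profile(ascan_window(get_frame(gen$volume, 1), 5, 15,
                                      gen$volume$geometry))
estimate_enamel_thickness(prof, reference_um = 255.45)
#> <thickness_result> enamel 250.3 um (surface index 23, DEJ index 57)
#>   reduction vs reference 255.45 um: 2.0%
```

The phantom was built with a 250 µm enamel band; the profile analysis
recovers 250.3 µm (34 axial rows at 7.36 µm of tissue per row), a 2.0%
reduction against a 255.45 µm healthy reference. The full comparative
pipeline runs from one config:

```r
lesion <- phantom_spec(rows = 200, cols = 40, frames = 2, seed = 11,
                       lesions = list(lesion_spec(20.5, 40, 1000, 0.6, 100)))
cfg <- run_config(samples = list(healthy = healthy, lesion = lesion),
                  reference = "healthy", profile_start_col = 5, seed = 11)
run_analysis(cfg)
#> <comparative_report> reference: healthy  config: 1b870a91
#>   sample thickness_um reduction_pct  volume_mm3 total_count bin_0_250
#>  healthy     250.3067           0.0 0.007038864        6983  117280.0
#>   lesion     147.2393          41.2 0.004243680        4210   96330.5
#>  bin_250_500 bin_500_750 bin_750_1000
#>     126014.5     97374.5        16757
#>      52139.0     51371.0         1665
```

The lesion sample (backscatter scaled to 0.6, 100 µm of enamel eroded)
reports thinner enamel (147.2 µm, a 41.2% reduction), a smaller residual
volume, and lower intensity in every depth bin — the three signatures of
demineralization the methods are designed to capture. `write_report()`
persists the table as CSV plus a JSON with full provenance.

The same workflow is scriptable from a shell:

```sh
Rscript inst/cli/octenamel.R phantom   --spec spec.yaml --out stack.tiff --truth truth.json --seed 5
Rscript inst/cli/octenamel.R profile   --stack stack.tiff --frame 1 --col 5 --width 15 --out profile.csv
Rscript inst/cli/octenamel.R bins      --stack stack.tiff --out bins.csv
Rscript inst/cli/octenamel.R volumetry --stack stack.tiff --thresh 45:255 --out vol.json
Rscript inst/cli/octenamel.R analyze   --config run.yaml --out report_dir
```

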