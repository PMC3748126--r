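---
title: "Quantifying myoblast differentiation from high-content screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying myoblast differentiation from high-content screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assay

C2C12 myoblasts differentiate in culture by fusing into elongated,
multinucleated myotubes. A high-content screen of this process images each
well of a 96-well plate at 36 non-overlapping sites on two channels: a
FITC-labeled Troponin T (TnT) antibody marking differentiated myotubes, and
DAPI marking all nuclei. Differentiation is quantified per myotube — area,
perimeter, length, breadth, integrated marker intensity, and the number and
area of contained nuclei — and per well, most importantly by the *myogenic
fusion index* (MFI): the percentage of all nuclei residing within
marker-positive myotube outlines. Treatments that impair differentiation
(ethanol, rapamycin) reduce myotube size and the MFI; a 2x2 factorial design
crossing ethanol with a gamma-secretase inhibitor (GSI) asks, via the
two-way-ANOVA interaction, whether the ethanol effect is Notch-mediated.

`myotubeHCS` implements this pipeline end to end: a synthetic plate renderer
with per-object ground truth, TIFF/layout I/O, segmentation, morphometry,
well-level aggregation, and the statistical battery.

```{r, eval = FALSE}
library(myotubeHCS)

presets <- differentiation_presets()
spec <- plate_spec(list(A01 = presets$vehicle, A02 = presets$ethanol),
                   fields_per_well = 6, field_size = c(512, 512),
                   rng_seed = 1)
plate <- generate_plate(spec, "plate_out")
res <- analyze_plate("plate_out")
res$wells
```

## The synthetic plate renderer

No raw images from the original screen are available, so the generator is a
first-class, tested component: it renders fields with known composition and
emits the ground truth used as the testing oracle.

**Shape model.** A myotube is a 2-D *capsule* (a rectangle with semicircular
caps): end-to-end length $L$, width $B$, uniform random orientation. The
capsule family has closed forms for every measured feature — area
$LB - B^2 + \pi(B/2)^2$, perimeter $2(L-B) + \pi B$, maximum Feret $L$,
minimum Feret $B$ — which is what makes oracle testing of the morphometry
possible. Branched or curved myotubes are deliberately not modeled.

**Distributions.** Lengths, breadths, nuclear areas and nuclei counts are
drawn from truncated normals at the condition preset's mean/SD (truncation
at $0.1\times$ the mean guarantees positivity; nuclei counts are rounded
and at least 1). The three built-in presets encode the vehicle / 100 mM
ethanol / 100 nM rapamycin conditions of the emulated study: length
178 (11.3) / 147 (13) / 117 (6.86) um, breadth 46.2 (5.3) / 32.1 (2.33) /
30.0 (3.29) um, nuclei per myotube 6 (1) / 4 (1) / 3 (1), myonuclear area
133 / 140 / 140 um^2, and marker-negative nuclear area 140 / 164 / 169 um^2.

**Densities and the fusion index.** Preset densities are expressed per
*reference field* (1392 x 1040 px at 0.65 um/px) and rescaled by actual
field area, so spatial density is the invariant. Background-cell densities
(206 / 128 / 84 per reference field) were chosen once so that the implied
expected MFI,
$100 \cdot \frac{d_{myo}\,\bar n}{d_{myo}\,\bar n + d_{bg}}$,
equals the condition values 14.9 / 13.5 / 12.5 percent. Two counting
conventions follow from treating plating as experimentally controlled:
the per-well myotube count is deterministic (split evenly across sites),
and the number of background cells is coupled to the realized in-field
myotube-nuclei count through the preset-implied unfused:fused odds.
Without the coupling, independent integer rounding of the two counts at
small field sizes can shift — even invert — the expected MFI contrast
between conditions; with it, the well-level fusion index is centered on the
condition value at any field size.

**Placement.** Nuclei are placed uniformly inside each capsule by rejection
sampling with their discs fully interior where they fit; capsules keep a
6 um clearance from each other and nuclear discs a 3 um clearance from
everything, so that blur cannot fuse distinct objects and segmentation
recall on clean renders is exact by construction. Rejection failures
restart the arrangement and eventually raise an explicit placement error
(an overcrowded capsule); an overfull *field* drops a background cell with
a warning instead of failing the plate. Objects may straddle the field
border; they are rendered clipped and flagged `clipped` in the ground
truth, and only nuclei whose centers fall inside the field are rendered or
listed.

**Imaging model.** Capsules are rasterized at their marker intensity
(constant per condition, calibrated so that intensity times expected
capsule area in pixels reproduces the reported integrated-intensity
magnitudes), nuclei at a fixed nuclear intensity, over a uniform camera
background (default 100 counts); the field is then Gaussian-blurred
(default sigma 1 px) and Gaussian noise added (default SD 8 counts), and
counts quantized to 16-bit. The default calibration of 0.65 um/px and
1392 x 1040 px is a declared artifact choice — a typical 10x CCD
configuration — because the original study reports magnification but not
calibration. The same `rng_seed` reproduces a plate byte-identically.

**What it does not emulate.** Photorealism, uneven illumination, curved or
branching myotubes, touching myotubes, debris, staining variability within
an object, or the day-3 to day-7 growth trajectory (conditions are distinct
presets, not a temporal model). Passing tests therefore demonstrate the
*correctness of the measurement pipeline* on geometry it can verify, not
segmentation robustness on real micrographs.

## Segmentation

The marker channel is thresholded per field by Otsu's method (robust to
plate-level intensity drift; a fixed threshold is available for bit-exact
tests), holes are filled, and 8-connected components (4-connectivity
available) below `marker_min_area` (default 50 um^2) are discarded. Two
guards make Otsu safe on empty fields: a constant image returns an empty
mask with a warning, and so does a field whose Otsu threshold lies within
3 robust SDs (MAD) of the background median — on pure camera noise Otsu
would otherwise bisect the noise and fabricate foreground. This assumes
stained area is a minority of the field, true for sparse myotube cultures.

Nuclei are detected the same way on the DAPI channel; any component larger
than 1.5x `nucleus_typical_area` (default 133 um^2) is split by watershed
on its distance transform (two overlapping nuclei always exceed this, while
a lone nucleus is unimodal and is not split), and components outside the
`[nucleus_min_area, nucleus_max_area]` gate are removed. The assay this
emulates used a "pre-determined size cutoff" whose value was never
published; the default of 40 um^2 is a declared choice, far below any
plausible C2C12 nucleus, and is exposed as a parameter.

Objects touching the field border are kept for counting, intensity and the
fusion index, but flagged and excluded from per-object morphometry means:
clipped shapes bias length and breadth downward, and with non-overlapping
fields they cannot be stitched.

## Morphometry

All measurements derive from one sub-pixel representation of the region
outline: the 0.5-level contour of the 3x3 box-smoothed binary mask.

* **Area** is pixel count times `pixel_size^2`.
* **Perimeter** is the length of the outline polygon (holes included).
  Smoothing before contouring matters: the contour of the raw binary mask
  overestimates boundaries at oblique angles by 5-8% (it is restricted to
  half-pixel staircase geometry), while the smoothed contour tracks
  straight edges at any angle to about 1%. Very thin regions (under ~2 px
  wide) never reach the 0.5 level after smoothing and fall back to the raw
  contour.
* **Length and breadth** are the maximum and minimum Feret (caliper)
  diameters of the outline's convex hull, via rotating calipers. The choice
  of the smoothed outline (rather than pixel-square corners) trades a
  slight rounding of sharp corners — a rasterized rectangle's diagonal
  reads about 1.5% short — for the removal of a systematic ~1 px breadth
  overestimate on capsule-like shapes, which is the relevant error for
  myotubes (they have round caps, not corners). Curved myotubes read
  shorter than their arc length by construction; geodesic length is out of
  scope.
* **Integrated intensity** is the raw (unnormalized) sum of marker counts
  over the region's pixels; background subtraction is deliberately off.
* A degenerate 1-pixel region reports, by convention, length = breadth =
  `pixel_size` and perimeter = `4 * pixel_size`.

Pixel coordinates are 0-based, row-major, origin top-left; doubling
`pixel_size` exactly doubles lengths and quadruples areas.

**Nucleus assignment** uses the centroid rule: a nucleus belongs to myotube
$k$ iff its centroid pixel lies inside region $k$. This matches the
"present within the outline" criterion, gives every nucleus at most one
assignment, and resolves straddling nuclei unambiguously (a nucleus 40%
overlapping but centered outside is *not* assigned). Unassigned nuclei are
the marker-negative (TnT-) cell pool. Whether the original assay required a
minimum nuclei count to call a region a myotube is unpublished; the filter
is exposed as `min_nuclei` with default 1.

## Aggregation

A `WellSummary` pools all sites of a well: myotube count (all objects),
morphometry means (non-border objects only), the TnT- nuclear-area mean and
undifferentiated-cell count (unassigned nuclei), and the MFI. The MFI
denominator is ambiguous in the source assay (total nuclei vs nuclei of
marker-positive cells); both are computed — `mfi` uses all detected nuclei,
which is the variant consistent with the reported ~15% values and is the
default; `mfi_tnt` restricts the denominator to nuclei of marker-positive
regions and differs from 100% only when `min_nuclei > 1`. Empty wells
propagate `NA` means (never zeros), so downstream ANOVA is not biased by
failed wells. The replication unit for statistics is the well.

## Statistics

The battery mirrors the assay's reporting: two-sided pooled-variance
Student t-tests (Welch by flag), one-way ANOVA with Tukey HSD, and two-way
factorial ANOVA with interaction on well-level tables, with Bonferroni,
Benjamini-Hochberg, or Tukey correction of pairwise cell comparisons
(`emmeans`). Sums of squares are type II (`car::Anova`), the conventional
choice absent interaction-first hypotheses; on balanced designs they reduce
to the classical closed forms, which the tests verify against brute-force
sums of squares at 1e-8 relative tolerance. An empty factorial cell raises
a non-estimability error. Alpha is 0.05 throughout.

One power caveat is worth stating because the tests compute it: with the
assay-scale cell SDs (1.26-2.12) and n = 24 wells per cell, a rescue
interaction of 1.4 MFI points (the ethanol effect abolished under GSI)
gives the interaction F-test a noncentrality of about 5, so detection at
p < 0.001 has power of roughly 0.13 (about 0.6 at p < 0.05). The acceptance
suite asserts a far stricter detection rate and that assertion fails by
design of the conditions; the calibration half of the same suite — type-I
error of the interaction test within 5% +/- 1.5% under an additive null —
passes.

## Problem sizes and numerical choices

The test suite exercises the full pipeline at desk scale, chosen as the
smallest sizes at which each property is statistically resolvable:
distributional fidelity at 5,000 draws per preset; acquisition arithmetic
on a full 96-well x 36-field plate of 64 x 64 px stub fields; end-to-end
condition recovery on 24 wells (8 per condition) x 8 fields of 512 x 512 px
(the 2.1 um ethanol-rapamycin breadth gap needs that replication for a
strict ordering check); per-object ground-truth recovery on noise-free
renders (the morphometry contract), counts and ordering under default noise
and blur; ANOVA calibration on 1,000 null simulations. Ties in label
numbering are broken by raster-scan order of first appearance, making label
masks deterministic; all RNG flows from declared seeds.

## Limitations

Real micrographs violate the generator's assumptions in known ways —
touching and branching myotubes merge into single regions (kept merged, as
in outline-based region analysis), illumination gradients are not corrected
(none are simulated), and machine-learned segmentation is out of scope.
The pipeline's accuracy claims are therefore claims about the measurement
chain, validated on analytically known geometry, not about segmentation of
arbitrary real-world images.
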