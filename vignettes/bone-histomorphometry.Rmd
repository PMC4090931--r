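---
title: "Automated bone histomorphometry: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated bone histomorphometry: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

Dynamic bone histomorphometry quantifies steady-state bone remodeling from
sections of non-decalcified bone. Mice receive two fluorochrome injections
(by convention here: the first label 7 days and the second label 2 days
before sacrifice); each is incorporated at sites of active mineralization,
so the section carries two fluorescent lines under the trabecular surface.
The distance between the lines divided by the inter-injection interval is
the mineral apposition rate (MAR, µm/day); the fraction of surface carrying
labels gives the mineralizing surface (MS/BS); their product is the bone
formation rate (BFR). Enzymatic stains provide cellular surrogates:
tartrate-resistant acid phosphatase (TRAP, osteoclasts) and alkaline
phosphatase (AP, osteoblasts), imaged as separate fluorescence scans.

`bonemorph` automates the full chain from per-channel fluorescence rasters
to the measurement report:

1. **assembly** — stitch overlapping microscope tiles into a whole-section
   image (k-th law nonlinear correlation);
2. **registration** — map the TRAP/AP stain scans onto the mineral/label
   reference scan using fiducial beads (similarity transform);
3. **shade correction** — remove slowly varying illumination
   (median-filter background subtraction);
4. **segmentation** — binarize each channel (cascaded Otsu thresholding);
5. **surface and ROI** — smooth the bone surface, repair broken cortices
   with an elastic template, select the femoral or vertebral region of
   interest;
6. **projection** — relate labels and cells to the trabecular surface along
   surface normals;
7. **metrics** — the static, dynamic and cellular measurement set, with
   paired group comparison.

A phantom generator renders synthetic sections with analytic ground truth,
so every stage is validated without any scanned data.

# Stage models and the parameters that matter

## Tile assembly (k-th law correlation)

Adjacent tiles are scanned with a 10–15 % overlap. For tiles $a$ and $b$
the cross-power spectrum $C = F_a \overline{F_b}$ is weighted as
$C\,|C|^{\,k-1}$ and inverted; the argmax of the resulting surface is the
inter-tile shift. $k = 1$ keeps full magnitude weighting (classical
cross-correlation), $k = 0$ is pure phase correlation, and the default
$k = 0.3$ balances intensity against phase/outline information. The exact
term carrying the exponent is a convention choice; the one used here
reproduces both stated limits. Peaks are searched only inside the window of
offsets consistent with the nominal overlap ± 50 %, offsets are integer
(1 px stitching accuracy is far below any measured structure), spectrum
magnitudes are floored at $10^{-12}$ before exponentiation, and global
placements chain pairwise offsets row-then-column with a 2 px warning /
10 px error loop-closure check on every 2×2 grid cell. No blending beyond
first-tile-wins is applied.

## Bead registration

Stain scans are acquired after the slide leaves and re-enters the stage,
with possible rotation and isotropic tape shrinkage. Six-micrometre
calibrated fluorescent beads spotted next to the section appear in the
label channels of the reference scan and in the TRAP/AP channels.
`detect_beads()` keeps bright components whose equivalent diameter is
within ±50 % of 6 µm and whose solidity is ≥ 0.8, with intensity-weighted
centroids. Correspondences are mutually nearest pairs after coarse
principal-axis alignment (the principal axis of a near-isotropic cloud is
noise-driven, so the no-rotation alignment is also tried and the better
pairing kept). The transform — rotation, isotropic scale, translation, no
reflection — is the closed-form complex-plane least-squares fit; landmarks
give scale and rotation directly, which is why the bead mechanism is
implemented as landmark registration rather than image correlation. Two
beads determine the transform exactly; a QC warning fires below three.

## Shade correction

`output = clip(input − median_filter(input, window), 0)`, reflective
borders. The window (default 600 µm in the pipeline) must exceed the
largest trabecular feature, otherwise bone is erased by the subtraction; a
warning fires when a configured feature size violates this. Negative
residuals are clipped at zero because fluorescence intensities are
non-negative and thresholding assumes this.

## Cascaded Otsu segmentation

`otsu_threshold()` maximizes between-class variance over a 256-bin
histogram of the observed min–max range, ties broken toward the lower
threshold. TRAP/AP scans carry three intensity populations — background
outside the bone, marrow-space background, signal — and a single global
threshold merges the upper two. The cascade re-runs Otsu on the surviving
*foreground* pixels (the signal is the brightest population), so two steps
isolate the signal; masks are nested by construction. Role defaults:
mineral and label channels 1 step, TRAP/AP 2 steps. A step leaving fewer
than 16 pixels stops the cascade with a warning. No morphological cleanup
happens inside segmentation, keeping the thresholds testable against the
exhaustive-search oracle.

## Surface conditioning, cortex repair and ROI

Surface geometry uses a median-filtered, morphologically closed copy of
the bone mask; **area metrics always use the raw mask**. Ripped or chipped
cortices would break the endosteal cavity, so a closed elastic template —
initialized as the convex hull of the dominant cortical components
(components ≥ 10 % of the largest, so trabecular islands cannot capture
it), resampled to equal arc-length nodes — descends the distance transform
of the cortical boundary under a neighbour-mean curvature penalty (up to
500 iterations; non-convergence returns the best iterate with a warning).
Converged nodes on the contour are anchors; anchor-to-anchor runs spanning
gaps no wider than `max_gap_um` become 3-px-wide bridges unioned onto the
mask (output ⊇ input always); wider gaps are reported and left open.

The femoral ROI starts 400 µm below the growth plate row (a required
input — no automatic growth-plate detection is attempted), keeps at least
`inset_um` (default 250 µm, the midpoint of the customary 200–300 µm
range) from the endosteal surface, and is rasterized as 50 µm × 50 µm
tiles added row by row away from the growth plate until the 2.1 mm² target
area (± 15 %; tile quantization forbids exactness) is reached. The
vertebral ROI is read as the *central* region enclosed by the offset
contour 770 µm inside the endosteum — the peri-endosteal band reading is
available via `mode = "band"` — and is kept as the exact offset region
rather than tiled, so its boundary sits within one pixel of the stated
offset. Endosteal depth is computed by distance transform of the cavity
(the filled dominant cortex minus the cortex), which makes both ROI
contracts directly checkable.

## Projection onto the surface

Normals are the negative gradient of a Gaussian-smoothed mask indicator,
unit-normalized and oriented marrow-ward. The smoothing sigma defaults to
3 px: flat faces are exact for any sigma, and 3 px keeps digital-circle
normals within about 2° of radial where 2 px leaves up to 4° of
rasterization ripple.

Each connected signal component projects **rigidly**: its travel direction
is the (sign-adjusted) normal of the nearest surface pixel whose direction
lies within the component's 90° orientation cone; the component then moves
one pixel per step until contact. Mineralization lines sit inside the bone
and travel outward to the surface contour; cells sit in the marrow and
travel inward until they touch bone. The leading-edge distance is the step
count at first contact; the mid-point distance adds half the component's
thickness along the travel direction (a 4-px band with leading edge at 10
px has mid-point 12 px). Components travelling further than
`max_travel_um` (50 µm for labels; 3 × the cell proximity for cells) are
discarded and logged — an unbounded march would project marrow debris
across the cavity. A channel whose segmentation fragments into thousands
of speck components is declared signal-free and projected as empty rather
than flooding the surface with noise.

Inter-label thickness is, per double-labeled surface pixel, the first-label
distance minus the second-label distance (leading-edge convention by
default; mid-point available), converted to micrometres; inverted-order
pixels are logged and excluded, and "no double-labeled surface" is an
*absent* result, distinct from zero.

Surface classification sets L1/L2 flags from the label hit sets and
AP/TRAP flags only where the originating component travelled within
25.6 µm of the surface (the mouse proximity rule; 67.4 µm for rats is a
config switch). Composites follow the cellular definitions: AP over the
second label = active osteoblast, AP over unlabeled surface = lining or
inactive osteoblast, TRAP over unlabeled surface = eroding surface. AP
with only the first label is deliberately in neither composite, so
AP/BS ≥ AP_L2/BS + AP_only/BS.

## Measurements

Surface fractions are class pixel counts over total surface pixels within
the ROI. Derived fields: LS/BS = sLS/BS + dLS/BS; MS/BS = dLS/BS +
sLS/BS⁄2 (the standard half-weighting of single labels); MAR = mean
Ir.L.Th / label interval; BFR = MAR × MS/BS (fraction form). BV/TV is the
bone-area fraction of the ROI; Tb.Th is measured directly as twice the
mean distance-transform value on the medial axis (distance-map ridge) of
the bone; Tb.N = (BV/TV)/Tb.Th per mm and Tb.Sp = 1/Tb.N − Tb.Th follow
the parallel-plate model, the field standard for calculated indices.
Ratios with empty denominators are reported as absent (null), never zero —
"no labeled surface" and "zero fraction" are different biological
findings. Group contrasts use the paired two-sided t test with pairwise
deletion of absent values; zero-variance nonzero differences are flagged
degenerate instead of reporting an infinite statistic.

**The label interval.** The injection schedule (day −7 and −2) implies a
5-day interval, which is the package default. The published
method-comparison arithmetic for the same section divides the inter-label
thickness by 7 instead; the divisor is configurable
(`label_interval_days`) and both conventions are exercised in the tests.

# What the phantom emulates — and what it does not

`make_trabecular_phantom()` renders mineral, two label, TRAP, AP and DAPI
channels for a geometry of axis-aligned stripes (trabeculae), annuli and
rectangular shells (cortices, optionally with cut gaps), with label bands
at fixed sub-surface offsets, cell blobs anchored on or off specific
faces, 6 µm beads, and additive zero-truncated Gaussian noise on a 0–1000
intensity scale (the acquisition's intensity statistics are free
parameters; the three-level 30/110/700 background/marrow/signal layout
exercises the cascade). Geometry is restricted so that every truth
quantity is closed form: a stripe's digital perimeter is 2L + 2W − 4,
label spans are `round(fraction × face length)`, and the inter-label
distance is the offset difference — analytic oracles beat re-measurement.
Truth surface fractions refer to the trabecular (stripe) surface, because
cortical surface never lies inside an ROI. Label bands are inset 3 px from
stripe ends so sub-surface mineralization lines do not outcrop on end
faces.

The phantom does **not** attempt photo-realistic marrow texture, osteocyte
lacunae, autofluorescence gradients beyond linear shading, partial-volume
label blur, or 3-D sectioning artifacts. Passing the phantom suites
therefore demonstrates that the geometry, arithmetic and signal-routing of
the pipeline are correct under realistic noise — not that segmentation
thresholds are optimal for any particular microscope or stain chemistry.

# Numerical choices and degenerate inputs

- Histogram: 256 bins over the observed range regardless of bit depth;
  constant input is a "degenerate histogram" error.
- Correlation: magnitude floor 10⁻¹²; all-zero tiles are flagged
  degenerate; structureless overlap strips fail the peak-to-RMS score
  floor (default 5).
- Median filtering normalizes intensities to [0, 1] around the filter and
  rescales, with explicit reflective padding.
- Projection marches integer pixel offsets `round(t·d)`; ties in direction
  matching break toward smaller travel.
- Bilinear warping zero-fills out-of-field pixels and records them in a
  validity mask; the identity transform is bit-exact.
- Empty ROI, absent channel roles, insufficient fiducials (< 2 pairs) and
  a solid mask without interior all fail fast with named errors or
  warnings rather than producing numbers.

# Problem sizes used by the test and acceptance suites

Stripe phantoms are 300 × 400 px at 2.5 µm/px; femur-shell phantoms are
1150 × 950 px (a 2.9 × 2.4 mm section). The validation suites use 100
random histograms for the threshold oracle, three overlaps × 2 × 2 tile
grids for stitching, 50 random transforms with 6–10 beads at 0.5 px
centroid noise for registration, and 25 random phantoms for dynamic
recovery — sizes chosen so the full suite exercises every code path in a
few minutes on a laptop while keeping every oracle exact.

# Known limitations

- Registration models isotropic shrinkage only; non-rigid tape wrinkles
  are out of scope.
- Osteoclasts are quantified as total TRAP signal distribution, not
  per-cell counts via DAPI multinuclearity.
- The growth-plate row is operator input.
- The vertebral ROI depth (770 µm) and area are taken as given; their
  optimality is an open question in the field.
- Rigid per-component projection is exact for bands on flat and gently
  curved surfaces but approximates strongly curved label lines; the
  per-pixel alternative is not implemented.

# A minimal session

```{r example}
library(bonemorph)

spec <- phantom_spec(
  image_shape = c(300, 400), pixel_size_um = 2.5,
  trabeculae = list(
    list(type = "stripe", orientation = "horizontal", center_um = 250,
         extent_um = c(100, 880), width_um = 60, labeled = TRUE)),
  label1_offset_um = 15, label2_offset_um = 5, seed = 1)
ph <- make_trabecular_phantom(spec)

bone <- segment_channel(ph$stack, "mineral")
surf <- surface_normals(bone)
p1 <- project_signal(segment_channel(ph$stack, "label1"), bone, surf, 50)
p2 <- project_signal(segment_channel(ph$stack, "label2"), bone, surf, 50)
ir <- interlabel_thickness(p1, p2, surf)
cls <- classify_surface(surf, list(label1 = p1, label2 = p2))
dynamic_metrics(cls, ir, label_interval_days = 5)
```
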