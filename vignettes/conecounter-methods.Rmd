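---
title: "Counting cones on flat-mounted retinas: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting cones on flat-mounted retinas: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conecounter)
```

# The measurement problem

Cone photoreceptor survival is the readout of choice in studies of retinal
degeneration. On a flat-mounted retina the cone outer segments, labelled
with a fluorescent lectin such as PNA, appear as bright, roughly circular
spots a few micrometres across, at local densities anywhere from a few tens
to ~400 per microscope field. An automated platform tiles the retina into
~300 fields of 0.0376 mm² (CoolSNAP FX camera: 217.75 × 172.53 µm at
650 × 515 px; HQ: 224.46 × 167.70 µm), acquires a nine-plane Z-stack per
field (0.7 µm spacing) after a per-field two-stage autofocus, and counts
the cones in each field by image analysis. `conecounter` implements the
analysis chain and a simulator that stands in for the microscope, so the
chain can be validated against exact ground truth.

# The synthetic retina

`synthetic_params()` / `generate_scene()` model the specimen as a disc of
radius 1.9 mm (the flattening produces four shallow wedge incisions, which
only affect the tissue mask) carrying:

* **Cones** placed by a hard-core point process: candidate positions are
  drawn uniformly, thinned to the target intensity surface, and rejected
  when closer than `hardcore_radius_um` (default 6 µm, a touch more than a
  cone diameter) to an accepted cone. The target count is Poisson with mean
  equal to the integral of the intensity over the mask; if the requested
  density is infeasible against the hard-core constraint (random sequential
  packing jams near 55 % disc coverage) generation fails with an explicit
  error rather than silently under-delivering. A configurable fraction of
  cones (default 5 %) is attached in contact with an anchor cone, exempt
  from the hard-core rule, to emulate touching pairs and triples.
* **Density gradients**: a multiplicative centre-to-periphery factor,
  linear in radius, and a ventral/dorsal ratio realized as a narrow
  logistic transition across the horizontal midline. The transition band is
  R/24 so that the half-retina count ratio tracks the nominal ratio
  closely; a wide band would transfer enough mass across the midline to
  bias the ratio visibly toward 1.
* **Nuisance structure**: dark patches (retinal-pigment-epithelium residue)
  as discs of 30–80 µm radius covering a configurable area fraction, which
  attenuate the background to 25 %; off-tissue area attenuated to 15 %; a
  planar background gradient across the retina.
* **A focal surface** `z(x, y)`: three superposed sinusoids with ±20 µm
  total amplitude and 3–6 mm wavelengths. The amplitude makes per-field
  focusing meaningful across the retina; the wavelengths keep the focal
  tilt *within* one 218 µm field small compared with the stack's ±2.8 µm
  axial range, which is the physically relevant regime for a flattened
  specimen — residual topography varies over millimetres, not within a
  single field. (With wavelengths ~1 mm the corner cones of a field
  defocus beyond the stack range and vanish from the projection; the
  simulator is deliberately not in that regime.)

Rendering (`render_field_stack()`) integrates, per pixel, a Gaussian cone
profile whose width is σ(z) = r/1.5 + 0.35·|z − z_cone| µm — the simplest
monotone defocus model, sufficient to exercise autofocus and projection —
with peak amplitude scaled by (σ₀/σ)² to conserve flux. Photon noise is
Gaussian with variance proportional to the signal (`noise_scale`, default
1.0, i.e. shot-noise-like at unit gain); pixel values are rounded and
clipped to 16 bits. Scenes and stacks are bit-reproducible functions of
their parameters and seed.

What the simulator does **not** emulate: optical point-spread physics
(only monotone Gaussian blur), spectral channels, rod interference at
early postnatal ages, vignetting, or stage positioning error. Passing the
package's recovery tests therefore demonstrates the algorithmic chain is
correct and unbiased under controlled imaging physics; it does not
certify performance on any particular real microscope.

# Acquisition model

`build_grid()` tiles the retina's bounding box with camera-sized fields
(origin at the grid top-left; x rightward, y downward; 0-based row/column
indices; stage coordinates in µm with the origin at the retina centre),
keeping cells that intersect the tissue disc. The draughtboard mode keeps
the checkerboard half with even row + column, used by the automated
stereological method. A 1.9 mm retina yields ~340 FX fields, the order of
magnitude the platform was designed around.

`two_stage_autofocus()` maximizes a sharpness metric over 6 coarse planes
spaced 60 µm (three below the start position, the start, two above), then
over 8 fine planes spaced 15 µm around the coarse argmax. The metric is
the plain intensity variance of the rendered plane: offset-invariant (a
constant illumination shift cannot move the optimum) and monotone under
the simulator's defocus model. Ties — e.g. a structureless field — return
the start position with a flag, and the lowest probed z wins among exact
ties. Probe planes are rendered noise-free so the decision is
deterministic; the acquired stack itself carries noise.

Stacks are written as uncompressed multi-page 16-bit grayscale TIFF named
`YYYYMMDD_<index>.tif`. The installed TIFF writer does not expose the
ImageDescription tag, so stage coordinates are carried by the
per-acquisition `stack_index.csv` (one row per stack: indices, grid
position, stage µm, z, filename), from which `read_stack()` restores them;
a write/read round trip is bit-identical, and page-count or bit-depth
mismatches are format errors naming the offending file.

# The detection chain and its eleven variables

`count_field()` runs, in order:

1. **Best-focus projection** — pixelwise maximum over the nine planes.
   Each cone, whatever its orientation and twist in depth, contributes one
   sharp transversal section to the composite.
2. **Auto-threshold** — Otsu's criterion evaluated exhaustively on the
   integer histogram. When the between-class variance is maximized on a
   plateau (a gap between background and signal populations) the plateau
   midpoint is returned, which places the cut between the classes rather
   than at the edge of the background.
3. **Field quality control** (`field_qc()`) with all failed gates
   recorded: mean projection intensity below `dark_max` (pigmented
   residue; a pixel-fraction variant of this gate is available via
   `dark_gate = "fraction"`), mean intensity below
   `best_focus_avg_intensity`, percentage of above-threshold pixels
   outside `autothreshold_area_pct`, fewer preliminary connected
   components than `prelim_cells_min`/`nb_objects_min`, or
   between-object background brighter than `fond_max`. Excluded fields
   carry reasons and **no count** — never a count of zero, which would
   bias densities downward.
4. **Tile-local thresholding** (`local_threshold_enhance()`) — the image
   is split into `tile_grid`² tiles (default 4²), each thresholded at its
   own Otsu level to overcome brightness differences within a field;
   sub-threshold pixels are zeroed. Tiles whose local level is degenerate
   *or lower than the global level* inherit the global level: a
   background-only tile has no second class, and a local Otsu there would
   split the noise in half. `tile_grid = 1` reduces exactly to global
   thresholding.
5. **find-spot** (`find_spots()`) — a white top-hat with a disc element
   (radius 35 px ≈ 12 µm, larger than any single cone footprint and than
   the `cluster` rejection diameter) suppresses residual slow background;
   connected components are labelled; components larger than `spot_size`
   are dissociated by watershed on the distance transform (touching
   cells); each object is then filtered: area above `cluster` (an
   unsplittable cell cluster), area above `surf_spot`, mean intensity
   below `int_min`, circularity 4πA/P² (capped at 1 against discretization)
   below `spot_cutoff`. Objects touching the image's left or top edge are
   marked `EXCLUDED_FRAME`: this applies the unbiased counting-frame rule
   at the field border, so that fields tiling the retina count each cone
   exactly once — without it, cones straddling field boundaries are
   double-counted (+4 % at typical densities on the simulator). Output is
   deterministically ordered by (y, x) centroid.

Defaults for the eleven variables were fixed once against the simulator
and ship in `detection_params()` / the packaged configuration; with them,
per-field counts recover ground truth within a few percent across the
45–405 cones/field design range (the test suite holds every field within
10 % and the 50-field mean within 3 %). `spot_size` (320 px) sits between
a large single-cone footprint and a touching pair, so watershed runs on
pairs but rarely on singles; `surf_spot` < `cluster` so oversized objects
are classified as surface rejects before the cluster rule takes over.

# Density estimators

* **Global**: mean per-field count over accepted fields
  (`global_density()`), reported per 0.0376 mm² field and per mm².
* **Automated stereological**: a 30 × 30 µm unbiased counting frame
  centred in each draughtboard field (`frame_count()`). Objects whose
  footprint intersects the frame are counted unless they touch one of the
  two forbidden edges (left and top; any consistent pair preserves
  unbiasedness). Contact is evaluated on the object's equivalent-disc
  footprint (centroid plus radius √(A/π)) — identical to the pixel
  footprint for circular cones and cheap enough for Monte-Carlo
  validation; over a tiling of the plane each connected object is counted
  exactly once, the defining property of the rule, and the mean frame
  count over random placements is an unbiased estimate of density × frame
  area. Densities are reported per 900 µm² frame and rescaled to the
  field-area unit, since the convention used for the printed automated
  stereological densities is not fixed by the frame geometry alone.
* **Systematic random sampling**: a square lattice with stride
  ⌈√(disc area / 65)⌉ µm and a seeded random start offset places 50–80
  non-overlapping 35 × 35 µm (1,225 µm²) fields inside the tissue within
  2 mm of the optic nerve (`systematic_random_sample()`); too small a
  mask is an error naming the achievable maximum.

On homogeneous simulated retinas the three estimators agree within
Monte-Carlo tolerance (the suite checks global vs frame-based agreement
within 10 % at ≥ 100 fields, using ground-truth-derived field results so
the comparison isolates the estimators from detection noise).

# The virtual eye fundus

`build_fundus()` centres the map on the optic nerve — by default the
centroid of the accepted fields' stage coordinates, operator-overridable —
and assigns each field to one of 9 concentric annuli of equal radial width
(the paper-style "9 rows"; outermost is row 9) and to a grid-aligned
angular segment (fields within an annulus, ordered by angle; the segment
count per annulus is therefore the number of fields the annulus holds).
Densities are colour-binned at multiples of 45 — (0, 45], (45, 90], …,
(360, 405] — with edge values going to the lower bin, zero counts to the
lowest bin, and values above 405 saturating in the top bin; excluded
fields render grey. `radial_profile()` averages per annulus;
`regional_comparison()` builds the mirrored 6 × 11 dorsal and ventral
blocks (66 fields, 2.48 mm² per region), separated by a two-row gap
centred on the optic nerve (2 × 167.70 µm = 335.4 µm with the HQ camera;
with the FX camera the gap in µm follows its field height and is reported
as computed), and hands the per-retina means to `paired_t()`.

# Statistics

`welch_t()` (unpaired, Satterthwaite df) and `paired_t()` wrap the
standard tests, with the degenerate zero-variance cases given explicit
conventions (equal constants: p = 1; constant non-zero difference:
p reported as 0 with a flag) since the underlying fitters reject constant
input. `two_way_anova()` fits density ~ day × method; balanced designs use
the classical sequential decomposition, unbalanced ones type-II sums of
squares; F and p are recomputed from the sums of squares so that a
vanishing effect is reported as F = 0, p = 1 even when the residual is
also zero.

`quantile_equalize()` implements quantile–quantile normalization across
counting methods: sort each method's measures, replace every rank-r value
by the across-method mean at rank r, and return values to their original
positions (stable ties). Afterwards all methods share one multiset, so
their marginal means are equal and the ANOVA method factor is *exactly*
null — p = 1 for any input, which is the identity the method-comparison
figure rests on. Normalization pools over days by default; a per-day
variant (`per_day = TRUE` in `cmd_stats()`) is provided, but the exact
identity is guaranteed for the pooled reading. When methods yield unequal
group sizes, `enumerate_equalizations()` enumerates every deletion choice
that resizes them to a common n (with a 10⁶-combination guard), so the
normalization + ANOVA can be run over all resizings; the historical count
of such combinations for any given study depends on its exact per-group
sizes and is not asserted here.

# Numerical conventions and edge cases

* Threshold semantics: background is `x ≤ level`, signal `x > level`;
  "zeroing below the (local) threshold" is the implemented contrast
  adjustment. Degenerate (constant) images flag the threshold and fall
  back to the global level in the local stage.
* Argmax ties in autofocus take the lowest z; Otsu plateau ties take the
  midpoint; object ordering is (y, x); sorting ties in equalization keep
  original order.
* Excluded fields propagate as absent values, never zeros; a run with no
  accepted field is an error, not a zero density.
* All intensities are integer 0–65535; physical units are µm, mm², and
  cones per field area or per mm², converted only at the reporting
  surface (field area displayed rounded to 4 decimals, computed at full
  precision).

# Problem sizes used in the validation suite

The test suite and the acceptance script are sized for a laptop-class
single CPU: single-field scenes for detection accuracy (50 rendered fields
across 45–405 cones/field), ~10⁴ random frame placements for the
unbiasedness check, and ground-truth field results (no rendering) for the
estimator-consistency comparison at a few hundred fields. Full-retina
simulation at the instrument's native scale (~300 rendered stacks) runs in
minutes via `cmd_simulate()` but is not exercised by the default tests.

# Known limitations

* The vendor "find-spot" and "autothreshold" internals of the original
  platform are proprietary; this package implements the described
  behaviour (Otsu threshold, top-hat + components + watershed, circularity
  cutoff) rather than a byte-level re-creation.
* The equivalent-disc contact rule of the counting frame is exact for
  circular objects; for strongly elongated objects a pixel-footprint rule
  would differ near the frame edges.
* Simulator realism stops at monotone defocus and shot noise (see above).
* The dorsal/ventral regional geometry assumes the acquisition grid covers
  both blocks fully; partial coverage is an error rather than a silently
  smaller region.
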