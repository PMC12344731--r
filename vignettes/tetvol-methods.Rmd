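---
title: "Methods: physician-guided TET volumetry and its evaluation"
author: "tetvol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: physician-guided TET volumetry and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetvol)
```

## The problem and the approach

Metastatic thymic epithelial tumors (TETs) spread through the thoracic
cavity as a mixture of mediastinal masses, parenchymal nodules and
curvilinear pleural deposits. The pleural lesions in particular defeat
one-dimensional longest-diameter measurement, so response assessment
benefits from volumetry — but fully automatic whole-scan segmentation of
these lesions is unreliable, and clinical viewers often cannot accept
free-form bounding boxes. The workflow implemented here therefore keeps a
physician in the loop in one of two ways:

* **Box crops**: the reader draws a 3D box around the maximal extent of
  each lesion of interest; one box per lesion.
* **Cell crops**: a 5×5×5 grid is spanned over the lung bounding box and
  the reader picks the cells containing the lesions. The chosen cell
  *indices* are stored per patient and reapplied to later scans, with the
  grid rebuilt on each scan's own lungs. Because the grid is defined
  relative to the lungs, cell indices approximately retain anatomical
  correspondence across scans without any image registration.

A segmenter (pluggable; the package ships a deterministic reference
threshold segmenter) runs inside each crop; per-crop predictions are
pasted back onto the scan canvas by voxelwise OR, and everything
downstream — anatomical classification, matching, metrics, longitudinal
volume tables — operates on the reassembled masks.

## Coordinate conventions

All volumes are reoriented on load to the DICOM patient convention LPS:
axis 1 increases toward the patient's left (X), axis 2 toward posterior
(Y), axis 3 toward superior (Z). This is not cosmetic: the mediastinal
rule below compares the lesion center's Y against the lungs' 75th Y
percentile, and "anterior of" only has a fixed meaning once the Y
direction is fixed. Tests assert that classification is invariant to how a
file happened to be stored on disk (RAS, LPI, ... all canonicalize to the
same array). The convention is recorded in every report.

Voxel indices in user-facing tables are 0-based, and bounding boxes are
half-open `[lower, upper)` — so a box's extent is `upper - lower` and the
center `(lower + upper - 1) / 2` may be fractional. Internally R's 1-based
arrays are used; the 0-based convention keeps the grid arithmetic (which
intervals of the real-valued cell boundaries contain a voxel) free of ±1
adjustments.

NIfTI stores voxel spacing as 32-bit floats; on read the spacing is
snapped to 7 significant digits so that values such as 0.8 mm round-trip
exactly. DICOM series with irregular slice gaps (beyond 1e-3 mm between
consecutive gaps) are rejected rather than resampled, since silent
resampling would corrupt volume measurements; oblique acquisitions are
likewise rejected rather than approximated.

## Anatomical classification

For each ground-truth lesion the cascade is, in order:

1. **Parenchymal** if the lesion does not border the lung segmentation
   boundary. The boundary is the one-voxel shell of lung voxels with at
   least one 6-neighbor outside the lung (volume edges count as outside);
   "borders" means any lesion voxel lies on the shell or is 26-adjacent to
   it. The adjacency form admits lesions lying just *outside* the lung
   mask, which is where pleural and mediastinal lesions mostly live; a
   strict mode (the lesion must intersect the shell itself) is available.
2. **Mediastinal** if the lesion borders the boundary and its bounding-box
   center satisfies `x25 ≤ Xt ≤ x75` and `Yt ≤ y75`, where the quartiles
   are linear-interpolation (type 7) percentiles of the lung foreground
   voxel coordinates, combined over both lungs. With two lungs either side
   of the midline, `x25` falls inside the right lung and `x75` inside the
   left, so the X band singles out the central compartment; `Yt ≤ y75`
   excludes the posterior-most band, consistent with TETs arising in the
   anterior mediastinum.
3. **Pleural** otherwise.

Two edge cases deserve note. The center is the *bounding-box* center, not
the voxel centroid — for a crescent-shaped cap these differ materially,
and the bounding-box center is the documented choice. And a lesion far
from the lungs never borders the boundary, so the literal rule labels it
parenchymal; the classifier emits a warning whenever a "parenchymal"
lesion has zero overlap with the lung mask, rather than silently
relabeling it. The percentile method and Y-direction are configuration
switches recorded in output metadata.

## Evaluation metrics

With `|G|`, `|S|` the foreground voxel counts of ground truth and
inference and `v` the voxel volume in cm³:

* `DSC = 2|G∩S| / (|G|+|S|)`;
* `AVD = v·||G|−|S||` — a *count* comparison, so two disjoint equal-volume
  masks have AVD 0 (a documented property of the definition, not a bug);
* `RVD = ||G|−|S|| / |G|` — dimensionless, unbounded above; overshooting
  to twice the volume scores the same as missing everything.

Aggregation levels: **scan** (all tumors pooled as one foreground),
**crop** (each cropped region a separate unit, which may contain several
tumors or parts of tumors), and **tumor** (per ground-truth tumor, after
matching). Matching attributes every inference connected component to each
ground-truth tumor it shares at least one voxel with; a component
overlapping k > 1 tumors contributes its full voxel set to each (the
matching is a matching, not a partition — any splitting rule would be
invented, and multi-matched components are counted and logged). Components
overlapping no tumor are false positives: they are excluded from tumor-
and location-level summaries but still depress scan-level DSC, and both
facts are tested by injecting a spurious component and asserting the
divergence. Per-tumor S is the *union* of matched components; tumor-level
summaries average unweighted over tumors.

Degenerate inputs are resolved by convention, not by NaN propagation: DSC
of two empty masks is 1.0 (the raters agree there is nothing), and RVD of
an empty ground truth is an error rather than an infinity, so undefined
values cannot leak into means.

Cell- and box-based performance is compared with a two-sided
Mann–Whitney–Wilcoxon rank-sum test. For combined n ≤ 12 the p-value is
computed by exact enumeration of all rank assignments, which stays valid
under ties (midranks); larger samples use the tie-corrected normal
approximation with continuity correction. The method used is reported
alongside the p-value. The unpaired test is applied as named; the package
does not pair crops across strategies.

Axial axis measurements mimic how diameters are drawn on an axial slice:
per constant-Z slice, the major axis is the maximum pairwise distance
between foreground voxel centers (physical mm), the minor axis the maximum
extent perpendicular to the realized major-axis direction in the same
slice, and the reported slice maximizes the major axis. Ties — both
between point pairs and between slices — are broken deterministically
(lexicographically first pair, lowest slice), so reports are reproducible.
Variants that place the short axis on a different slice are out of scope.

## The grid and its numerical choices

The lung grid partitions the (optionally padded; default pad 0, i.e. the
tight box) lung bounding box into `divisions³` cells with *real-valued*
boundaries: each axis span is divided into equal real intervals, and a
voxel belongs to the interval containing its 0-based coordinate, half-open
with the last interval closed. Rounding cell boundaries outward to whole
voxels makes adjacent cells share no voxel while tiling the bounding box
exactly, even when the span is not divisible by 5 — both properties are
tested exhaustively. Cell labels are `"X{i}-Y{j}-Z{k}"` with 0-based
indices; the labeling is this package's own scheme.

Selections are stored in a single JSON file per project (schema_version
1): one active record per patient plus full history. A desk-scale,
diffable text file was chosen over a server database deliberately. When a
stored selection is applied to a new scan and a lesion mask is available,
lesion voxels falling outside the union of the selected cells trigger a
coverage warning — tumor growth beyond the stored cells is the known
failure mode of index reuse, and the package surfaces it rather than
auto-growing boxes (automatic box growth is explicitly out of scope).

Box crops default to a 2-voxel margin per side: enough context for a
segmenter at the boundary, small enough not to swallow neighboring
structures. Connectivity defaults: 26 for lesion identity (diagonally
touching voxels are conservatively one lesion; the connectivity actually
used is always reported and configurable) and 6 for the boundary shell (a
thin one-voxel surface).

## The synthetic phantom: what it emulates and what it does not

The generator produces a 96³-voxel volume at 2 mm isotropic spacing (all
defaults configurable): two ellipsoidal lung fields either side of a
mediastinal gap, and lesions of the three categories placed so that their
intended class is unambiguous under the cascade:

* *parenchymal* — a sphere at least two voxels interior to a lung (the
  generator verifies this against a twice-eroded lung and refuses
  unrealizable specs by lesion index);
* *mediastinal* — an ellipsoid bridging the inter-lung gap, touching both
  inner lung surfaces, centered in the X band and anterior of y75;
* *pleural* — a curvilinear spherical-shell cap hugging the outer lateral
  lung surface. The cap straddles the surface — its thickness indents the
  lung, with a one-voxel outward protrusion — matching how pleural
  deposits grow in the pleural space and compress lung rather than
  expanding through the chest wall; this also keeps the cap inside the
  lung bounding box, as the grid workflow assumes for selectable lesions.

Intensities are HU-like but arbitrary (soft tissue ≈ 40, lung ≈ −700,
lesion ≈ 60) with independent Gaussian noise, default SD 4 — 20% of the
hardest contrast in the scene, lesion against soft tissue. The toolkit
never interprets absolute HU, so no calibration is claimed. The truth
table records each lesion's exact voxel count and volume; truth-table
consistency with the mask is tested for every seed used.

Cohorts add per-scan jitter of lesion sizes (±10%) and positions (±2
voxels, X held so the intended category stays valid), a rigid ±4-voxel
translation of the whole anatomy, and optional longitudinal pairs in which
each lesion's volume grows by a stated factor (spheres and ellipsoids
scale their radii by the cube root; caps scale thickness and angular
extent, which voxelizes more coarsely — the tests bound cap growth loosely
and sphere growth tightly).

What the phantom does *not* emulate — and hence what passing tests do not
show about real data: CT reconstruction physics and texture,
partial-volume effects at lesion boundaries, contrast enhancement,
respiratory deformation between scans (translation only), lung-mask errors
from an automatic segmenter, and lesions with ambiguous anatomical
category. The phantom validates the *machinery* (cropping, matching,
metrics, bookkeeping) exactly; it says nothing about how any particular
learned segmenter performs on patients.

The reference segmenter (threshold + small-component removal, defaults 50
and 5 voxels) is the pluggable segmenter's contract made concrete and
deterministic; it is not a claim about how tumors should be segmented.
External predictions can be supplied instead, either as full-scan masks or
per-crop patches, and are normalized through the same paste-and-score
path.

## Problem sizes and runtimes

The test suite and the acceptance script run on one CPU in a few minutes
total. Property tests use 100 seeds at 16³–24³ for the metric, component
and shell oracles; grid, translation and localization properties use 50
seeded 48³ phantoms; the end-to-end cohort evaluation and the longitudinal
tracking example use 96³ phantoms (5-scan and 50-scan cohorts). These
sizes were chosen so each oracle comparison remains exhaustive (brute
force over all voxels or all pairs) while the full suite stays fast enough
to run on every change.

## Known limitations

* Location classification inherits every assumption of the lung mask; a
  mask that clips a lung shifts the quartiles and can flip
  mediastinal/pleural calls near the band edges.
* Index-based cell reuse tolerates rigid anatomy shifts but not large
  deformation or effusion-driven lung collapse; the coverage warning is
  the only guard.
* AVD/RVD compare counts, not positions: a segmenter that hallucinates
  volume elsewhere inside the same tumor's matched components goes
  unpunished by volume metrics (DSC catches it).
* Surface-distance metrics (HD95, ASSD), volumetric response thresholds
  and survival analyses are out of scope.
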