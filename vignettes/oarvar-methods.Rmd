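---
title: "Quantifying interobserver delineation variability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying interobserver delineation variability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

When several radiation oncologists outline the same organ at risk (OAR) on
the same CT scan, the contours differ. For highly conformal radiotherapy
this interobserver variability propagates directly into dose-volume
statistics and normal-tissue complication modelling, so it has to be
measured, localized and, where possible, reduced. `oarvar` implements a
complete analysis pipeline for multi-observer, multi-scan contour studies
of head-and-neck OARs (spinal cord, parotid and submandibular glands,
thyroid cartilage, glottic larynx), built around three complementary
endpoints:

* the **intraclass correlation coefficient (ICC)** — agreement in the
  *size* of the delineated volumes, ignoring position;
* the **concordance index (CI)** — the Jaccard volume overlap
  $|V_1 \cap V_2| / |V_1 \cup V_2|$ of observer pairs, sensitive to both
  size and position;
* the **3D SD** — the per-point standard deviation of the observers'
  signed distances to a median contour surface, summarized globally and
  per anatomical sub-region.

Reading the endpoints together separates failure modes: ICC much larger
than CI indicates positional scatter of similar-sized volumes; CI much
larger than ICC indicates consistent placement with discordant sizes. The
pipeline flags organs as "volume-dominated" or "position-dominated" when
the two endpoints differ by more than a configurable threshold (default
0.15).

# Data model

A `delineation` is one observer's contour stack for one organ on one scan:
closed planar polygons (implicitly closed vertex lists, even–odd rule for
holes and multi-part slices) at fixed axial positions in the DICOM LPS
patient frame (+x patient-left, +y posterior, +z cranial), all in mm.
Slice z values must be strictly increasing and spaced by integer multiples
of the slice spacing. A `delineation_set` collects the full
patient × scan-time × observer × organ design; the scan-time vocabulary is
fixed to `plan` (planning CT) and `rep` (repeat CT) because the variance
model needs exactly two time levels.

Sets are exchanged in a canonical JSON format (sorted keys, six-decimal
floats) so re-exporting an unchanged set is byte-identical; a minimal
read-only DICOM RT Structure Set adapter (`load_rtstruct()`) converts the
clinical format, supporting explicit and implicit VR little-endian
transfer syntaxes and planar axial contours only.

# Volumes and descriptives

The **volume endpoint is grid-free**: per slice the net even–odd polygon
area (shoelace formula, nesting resolved by containment parity) times the
slice spacing, summed over slices (slab rule). Rasterized masks are used
only where overlap demands voxels (CI, median surface); this keeps the
Table-1-style statistics free of voxelization artefacts. The slab rule is
exact for prisms and converges at second order for smooth shapes; a
property test holds the gap to a fine-grid voxel count under 3%.

Per organ the package reports the mean volume, its standard error, a
coefficient of variation, and a per-observer "OAR ratio" (the observer's
mean volume over the across-observer mean of those means, averaging to 1
on complete designs). The source study prints "CV" without a formula; we
read its description ("an observer relative standard deviation for
observing a volume") as the mean over (patient, scan) cells of the
across-observer SD/mean, and expose the pooled alternative
(`cv_method = "pooled"`). The SE is likewise not defined there; the
default is the sample SD over all records divided by √n, with a
per-patient-means alternative (`se_method`). Sample SDs use the n−1
denominator throughout.

A systematic observer effect is tested with **Friedman's rank test** on
the planning-CT volumes per organ (patients as blocks). The statistic uses
mid-ranks with the standard tie correction — `stats::friedman.test()`
omits the correction, which is why the package carries its own
implementation; on tie-free data the two agree exactly and the tests pin
the statistic to the classic rank formula.

# Variance components and the ICC

Volumes are modelled with a three-way mixed-effects ANOVA: patients and
observers random, scan time a two-level fixed effect, all interactions
included. With one observation per (patient, observer, time) cell the
three-way interaction is confounded with the residual, so
$\sigma^2_{res}$ absorbs it. The ICC is

$$\mathrm{ICC} = \frac{\sigma^2_P + \sigma^2_{PT}}
 {\sigma^2_P + \sigma^2_O + \sigma^2_{PO} + \sigma^2_{PT} + \sigma^2_{OT}
  + \sigma^2_{res}},$$

the correlation of two arbitrary observers measuring the same patient on
the same scan: patient and patient-time variation is "real" signal, all
other components are observer-related. The fixed time effect (mean volume
difference repeat − planning) is reported but never enters the ICC.

**Estimation.** Components are estimated by REML. Because the covariance
is linear in the variance parameters, the package uses Fisher scoring on
the variance scale: it converges in a handful of iterations to near
machine precision, and on balanced complete designs reproduces the
expected-mean-squares (EMS) method-of-moments solution exactly (a generic
deviance optimizer only gets within ~1e-6 relative, because the REML
deviance is flat at the 1e-13 level there). Non-negativity is enforced by
projection with an active-set rule on the score; steps are annealed after
iteration 20 so that boundary chattering on degenerate inputs (for
example, zero within-patient variance) settles rather than cycles. The
unbalanced case — an organ excluded for one patient, as happens when a
gland is infiltrated by tumour — is handled by the same estimator and
cross-checked against `lme4::lmer()` in the test suite; `lme4` also
serves as a runtime fallback on pathological inputs. How negative variance
estimates were treated in the original analysis is not stated anywhere;
truncation at zero is this package's decision. If every component is zero
the ICC is 0 by convention.

ICC values are classified into the conventional verbal bands
(0.00–0.10 virtually none, 0.11–0.40 slight, 0.41–0.60 fair, 0.61–0.80
moderate, 0.81–1.00 substantial), closed at the printed endpoints with
in-between values assigned to the upper band.

# Concordance index

`pairwise_ci()` computes intersection-over-union by voxel count on a
shared grid. One empty mask against a non-empty one scores 0 (an absent
structure is genuinely zero agreement, logged); two empty masks are an
error. Aggregation pools all observer pairs and all scans with equal
weight — for the full design, 10 pairs × 12 scans per organ — reporting
mean, minimum and maximum. The Dice coefficient is algebraically locked to
the CI (`dice = 2 ci / (1 + ci)`) and exposed as a cross-check utility.
The grid behind the published overlap values is unknown; the default
analysis grid is 1.0 × 1.0 mm in-plane with the axial spacing taken from
the data (close to the 0.97 × 0.97 × 2.0 mm acquisition), and is a
configuration knob.

# Median surface and the 3D SD

The **median contour surface** is the 0.5 iso-surface of the
mean-occupancy field (the fraction of observers covering each voxel),
which reproduces the ≥3-of-5 majority volume with sub-voxel placement.
Iso-surfacing uses marching tetrahedra: each cell is split into six
tetrahedra around a consistent main diagonal, which gives a watertight,
consistently oriented triangulation without the 256-case tables of
marching cubes, with the same linear sub-voxel interpolation. Occupancy
exactly 0.5 (possible with an even observer count) falls outside: the
interior is the strict majority.

For every surface vertex, the **signed distance to each observer's
boundary** (positive outside the observer's structure) is measured, and
the per-vertex SD (n−1) of the n distances about their mean is the local
3D SD; the global value is the unweighted mean over vertices
(area-weighted variant by flag, unsigned distances by flag). Two distance
constructions are available:

* `method = "normal"` (default): march along the median surface's outward
  normal through the observer's lightly smoothed occupancy field and
  bisect the 0.5 crossing. Normals are taken from the gradient of the
  occupancy field, not from mesh triangles (marching-tetrahedra vertex
  normals wiggle by ~20° and would inflate ray lengths). This is the
  classical construction for median-contour variability: an observer
  surface offset by d along the normal scores d regardless of surface
  roughness.
* `method = "nearest"`: evaluate the observer's exact signed Euclidean
  distance field at the vertex (point-to-mesh with a binned triangle
  search). This is a lower bound on the normal-ray distance; on rough or
  coarsely sliced surfaces it systematically understates the injected
  variation (about 20% at 3 mm noise on a 19 mm organ in our phantoms),
  which is why it is not the default for the SD endpoint.

`signed_distance()` exports the full voxel field of nearest-boundary
distances (negative inside, positive outside, anisotropic spacing
respected), where "boundary" is the 0.5 iso-surface of the box-smoothed
occupancy (one voxel in-plane; axially only for near-isotropic grids, so
CT-like grids keep their exact slice caps). If smoothing would erase a
very thin structure the raw binary field is used instead.

**Sub-regions.** Three rule families mirror the anatomy-specific
definitions: slice-count caps (5 slices for parotids, 3 for submandibular
glands, 1 for the glottic larynx) with the remaining vertices split into
axial quadrants about the per-slice centroid (medial facing the patient
midline per laterality); longitudinal landmark bands for the spinal cord
(cranial above C1-bottom, medial C2–T1, caudal from T2 on, with the
vertebral z positions supplied by the user since no image information is
available); and a closed-slice rule for the thyroid cartilage, where a
plane is "closed" iff the majority mask contains background fully
enclosed by foreground (a ring) and the caudal sub-region is the maximal
run of unclosed planes at the bottom. Caps take precedence over quadrants
by default (`caps_exclusive`), with every vertex's quadrant label kept in
an attribute. For midline organs both x-quadrants are labelled `lateral`;
the published table reports a "medial" region for the glottic larynx, but
its defining figure is not available to us, so this convention is ours.
The parotid's anterior/posterior sub-regions are anatomically anchored to
the mandible, which would require bone segmentation; the quadrant rule is
used as an image-free approximation.

# The synthetic cohort generator

No patient contours are deposited with the source study, so the package
ships a generator that emulates its design: 5 observers × 6 patients ×
2 scans × 7 structures at 2 mm slicing, with the right parotid gland of
one patient excluded, for 410 structures in total.

Truth anatomy is a star-shaped superellipsoid radial surface
$r(\theta,\varphi)$ per organ, sized to the clinical mean volumes
(parotids ≈ 28 cm³, submandibular glands ≈ 10 cm³, thyroid ≈ 11 cm³,
larynx ≈ 10 cm³, an elongated box-like cord). Patients differ by one
log-normal size factor (default SD 0.10 on the log scale, i.e. ±30%
volume spread, matching the between-patient spread of the published
volume ranges); a smaller per-scan factor (SD 0.02) models anatomy change
between planning and repeat CT — the study found no systematic
plan-versus-repeat trend, so no trend is injected.

Each observer re-draws the truth with:

* a **multiplicative radial bias** (defaults 0.97–1.03, i.e. volume
  ratios ≈ 0.91–1.09, the magnitude of the published per-observer OAR
  ratios outside the glottic larynx);
* a **systematic shift** (defaults 0.5 mm);
* a **smooth zero-mean random surface field** built from real spherical
  harmonics of bands 1–6 with band weights
  $\exp(-\ell(\ell+1)/(\ell_0(\ell_0+1)))$, $\ell_0 = 2$, scaled so the
  pointwise SD equals the configured regional value exactly (defaults:
  cranial 2.0 mm, caudal 1.6 mm, body 1.0 mm — the cranial > caudal >
  body pattern of the published regional table). The $\ell = 0$ band is
  excluded, so the noise is essentially volume-preserving and the volume
  decomposition stays attributable to the injected bias and jitter. The
  band scale is deliberately smooth (quadrant-to-hemisphere wavelengths):
  observer disagreement in this domain is regional, and the median-surface
  methodology assumes smooth surfaces. White per-vertex noise is
  explicitly avoided.

The noisy surface is sliced into 64-gon polygons on the global z-planes;
for each plane and azimuth the in-plane radius is found by bisection
(monotone and robust near the caps, where a fixed-point iteration can
fail and truncate the cap — the caps carry the largest clinical
variability, so they must survive slicing). Radii driven non-positive are
clipped at 0.5 mm with a warning; planes the surface no longer reaches
are dropped. The generator is bit-reproducible from (config, seed), and
the ground-truth sidecar records per-structure true volumes, all injected
parameters and the analytic ICC implied by the log-volume decomposition
($\sigma^2_P = (3 j)^2$ for patient jitter SD $j$, observer variance
$\mathrm{var}(3\log b_o)$).

**What a green test does not establish.** The generator produces smooth
star-shaped single-part anatomy; real organs have concavities, ragged
manual contours, multi-part slices and image-driven (not statistically
stationary) observer behaviour. The published table values were computed
on twelve undeposited CT scans and are not reproducible at desk scale;
the package's acceptance evidence is therefore property-based: design
counts (410 structures, 10 pairs), exact oracle agreement (rasterizer
vs. brute-force point-in-polygon; Fisher-scoring REML vs. the EMS
solution; Friedman vs. the rank formula), analytic phantoms (offset cubes
CI = 1/3; concentric balls 8–12 mm with global 3D SD √2.5 ≈ 1.58 mm), and
ground-truth recovery (ICC within 0.1, noise SD within 15%, regional
ordering, CI monotone in noise).

# Numerical choices and degenerate inputs

* Rasterization: voxel centre in even–odd interior, ties on edges
  resolved by the half-open lower-edge crossing rule (deterministic);
  self-intersecting polygons are accepted under even–odd semantics. The
  grid-free slab volume, by contrast, resolves nesting by containment
  parity and is exact only for non-crossing parts.
* Slices are matched to the nearest grid z-plane within half the axial
  spacing; a delineation whose bounding box exceeds the grid raises an
  error naming the overflowing axes.
* Degenerate masks (empty or full) have no distance field and are
  excluded from the local SD with a warning; a pair of empty masks has no
  defined CI.
* Surfaces with fewer z-planes than the configured caps split the caps at
  the midplane with a warning.
* Vertex z snapping clamps to the planes the surface actually encloses,
  so cap-face vertices (half a spacing beyond the outermost occupied
  plane) belong to that outermost slice.
* All randomness flows from a single recorded seed; analysis artifacts
  (CSV/JSON) are byte-stable across reruns of the same configuration.

# Known limitations

* The thyroid closed-slice rule needs a ring cross-section, which the
  star-shaped generator cannot produce; the rule is exercised on directly
  constructed ring masks in the tests, and the synthetic thyroid uses a
  caps rule in the default pipeline configuration.
* The exact CV/SE recipes and the negative-component policy behind the
  published tables are unstated; defaults are declared and configurable,
  not inferred as ground truth.
* No ICC confidence intervals (none are published); no post-hoc pairwise
  observer testing; no surface-distance agreement metrics beyond the 3D
  SD; no CT image handling, registration or contour editing.
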