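# oarvar

Interobserver variability analysis for organ-at-risk (OAR) delineations on
axial CT.

When several radiation oncologists contour the same organ — spinal cord,
parotid and submandibular glands, thyroid cartilage, glottic larynx — the
outlines differ, and that variability propagates into dose-volume
statistics and normal-tissue complication models. `oarvar` measures the
variability of a multi-observer, multi-scan contour study with three
complementary endpoints and localizes it on the organ surface:

* **ICC** — the intraclass correlation of delineated volumes from a
  three-way mixed-effects variance-component model (patients and observers
  random, planning-vs-repeat scan time fixed, all interactions):

  ICC = (σ²_patient + σ²_patient×time) / (sum of all six variance
  components),

  estimated by Fisher-scoring REML (exactly the expected-mean-squares
  solution on balanced designs; unbalanced designs, e.g. an organ excluded
  for one patient, are handled), and classified into the conventional
  agreement bands (0–0.10 virtually none, 0.11–0.40 slight, 0.41–0.60
  fair, 0.61–0.80 moderate, 0.81–1.00 substantial).
* **CI** — the pairwise concordance index (Jaccard overlap
  |A∩B| / |A∪B| of rasterized volumes), pooled over all observer pairs
  and scans per organ (mean, min, max).
* **3D SD** — per vertex of the median contour surface (the 0.5
  iso-surface of the observers' mean occupancy, i.e. the majority
  volume), the sample SD of the observers' signed distances measured
  along the surface normal; averaged globally and per anatomical
  sub-region (cranial/caudal caps, vertebral landmark bands, axial
  quadrants, thyroid closed-slice rule).

It also computes the Table-1-style descriptives (mean volume, SE, CV,
per-observer OAR ratio) and a tie-corrected Friedman test for a systematic
observer effect, reads and writes a canonical JSON contour format, adapts
DICOM RT Structure Sets, and ships a synthetic cohort generator
(superellipsoid truth anatomy, per-observer radial bias, smooth
spherical-harmonic surface noise with regional SDs, 2 mm slicing) with
full ground truth, so the whole pipeline is testable without clinical
data. The default generator reproduces the clinical design: 5 observers ×
6 patients × 2 scans × 7 structures, one organ of one patient excluded —
410 structures.

## Worked example

Simulate a small cohort (3 patients, 3 observers, 2 organs) and run the
full analysis:

```r
library(oarvar)
cfg <- analysis_config(
  simulation = cohort_config(
    n_patients = 3,
    observers  = default_observers()[c(1, 3, 5)],
    organs     = default_organs()[c(4, 7)],  # submandibular gland, larynx
    exclusions = list()),
  grid_spacing = c(1.5, 1.5),
  seed = 42)
bundle <- run_analysis(cfg)
print(bundle)
```

```
== interobserver variability report ==
source: synthetic cohort (seed 42)
36 volume records, 2 organs

endpoints (Table-2 style):
              organ   icc        band ci_mean ci_min ci_max sd_global
     glottic_larynx 0.680    moderate   0.717  0.632  0.791      1.18
 submandibular_left 0.935 substantial   0.686  0.614  0.773      1.40
 sd_anterior sd_caudal sd_cranial sd_lateral sd_posterior sd_medial
       0.992      1.37       1.77       1.09        1.177        NA
       1.194      1.63       1.88       1.01        0.899      1.27
        dominance
         balanced
 volume-dominated

Friedman test (planning scans):
              organ statistic dof p_value n_blocks
     glottic_larynx         6   2  0.0498        3
 submandibular_left         6   2  0.0498        3
```

Reading the output: both organs show moderate-to-substantial volume
agreement (ICC 0.68 and 0.94) with mean pairwise overlaps around 0.7. The
regional 3D SD columns localize the disagreement — largest at the cranial
caps (1.77 and 1.88 mm), exactly where the generator injected its largest
observer noise (2.0 mm cranially vs 1.0 mm over the body; the n = 3
observer sample and normal-sample-SD bias explain the rest). The
submandibular gland is flagged `volume-dominated` because its ICC exceeds
its mean CI by more than 0.15: observers agree on size more than on
overlap. The Friedman test picks up the injected systematic volume biases
(radial scales 0.97/1.00/1.03) at its minimum attainable p for 3 patients
and 3 observers. With an `out_dir`, the same run writes `volumes.csv`,
`organ_summary.csv`, `friedman.csv`, `icc.csv`, `ci_pairs.csv`,
`ci_summary.csv`, `sd3d.csv`, `endpoints.csv` and `metadata.json`,
byte-identically across reruns; `write_meshes = TRUE` adds one PLY surface
(with per-vertex SD and region) per analyzed structure group.

A YAML-driven command line covers the same flow:

```sh
Rscript -e 'oarvar::oarvar_cli()' simulate config.yaml cohort.json
Rscript -e 'oarvar::oarvar_cli()' analyze  config.yaml
Rscript -e 'oarvar::oarvar_cli()' report   out_dir
```

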