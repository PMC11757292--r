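# periostage

Staging periodontitis from landmark measurements on dental panoramic
radiographs, and evaluating how well raters — human or automated — agree on
those stages.

Periodontitis severity is graded radiographically by how much alveolar bone a
patient has lost around their worst-affected tooth. Given the three landmarks
of a tooth — the cemento-enamel junction (CEJ), the alveolar bone crest, and
the root apex — the percentage bone loss is

```
P = 100 · (d(CEJ, crest) − 2 mm) / (d(CEJ, apex) − 2 mm)
```

where 2 mm is the physiological biologic width. The patient stage follows the
worst tooth: `P < 15%` → Stage I, `15–33%` → Stage II, `P > 33%` → Stage III
with ≥ 20 teeth remaining, Stage IV otherwise.

The package provides:

* **Staging** — `measure_distances()`, `bone_loss_percent()`,
  `stage_patient()`, `assess_cohort()`, with explicit handling of
  unmeasurable teeth and a configurable `staging_policy()`.
* **Agreement statistics** — `binary_metrics()` (with `NA` markers for
  undefined metrics), `dichotomize()` for collapsing ordinal stage tables to
  disease-yes/no, linearly weighted Cohen's kappa (`weighted_kappa()`,
  `kappa_ci()`), exact Clopper–Pearson intervals (`proportion_ci()`), and
  mAP at IoU 0.5 for detections (`map50()`).
* **Sample-size planning** — `kappa_sample_size()` for two-rater agreement
  studies, with the Fleiss–Cohen–Everitt kappa variance as the default
  model.
* **Image enhancement** — `sharpen()` (unsharp masking), `equalize_hist()`,
  `gaussian3()` (3×3 binomial kernel), chained by `preprocess_image()`.
* **Phantom generators** — landmark cohorts with known stages
  (`gen_cohort()`), radiograph-like images with ground-truth masks and
  polygons (`gen_phantom_image()`), simulated rater pairs
  (`gen_rater_pair()`), perturbed detection sets
  (`gen_perturbed_detections()`).
* **Formats & plumbing** — LabelMe-style polygon JSON, YOLO-style normalized
  segmentation text, patient-level 70:10:20 dataset splits
  (`split_dataset()`), a pipeline driver (`run_pipeline()`), and packaged
  reference tables from the published rater study
  (`load_fixture_tables()`, `recompute_published_tables()`).

A thin command-line wrapper lives at `inst/scripts/periostage.R`
(`stage`, `phantom`, `preprocess`, `agreement`, `samplesize`, `published-check`).

## Worked example

```r
library(periostage)

# generate a 50-patient phantom cohort and restage it
spec <- phantom_cohort_spec(seed = 1, n_patients = 50, landmark_noise_mm = 0)
cohort <- gen_cohort(spec)
res <- assess_cohort(cohort$landmarks)
table(res$summary$patient_stage)
#>
#>   I  II III  IV
#>  12  10  16  12

merged <- merge(res$summary, cohort$truth, by = "patient_id")
mean(merged$patient_stage == merged$true_stage)
#> [1] 1

# agreement between two raters on the packaged 90-radiograph tables
fx <- load_fixture_tables()
wk <- weighted_kappa(fx$rater_tables$periodontist, "linear")
round(wk$kappa, 3)
#> [1] 0.634

binary_metrics(dichotomize(fx$rater_tables$periodontist, "0"))$accuracy
#> [1] 0.9111111

# how many subjects does an agreement study need?
kappa_sample_size(k0 = 0.766, deviation_percent = 25,
                  pi_e = 0.734, pi_0 = 0.766)$n
#> [1] 83
```

The phantom cohort restages perfectly because zero-noise landmarks invert the
bone-loss formula exactly; the kappa of 0.634 is the chance-corrected,
linearly weighted agreement between a periodontist and the expert reference
over five ordered stage categories; n = 83 is the number of radiographs
needed to detect a 25% relative improvement over a baseline kappa of 0.766
at 80% power.

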