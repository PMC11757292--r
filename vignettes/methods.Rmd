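---
title: "Staging periodontitis from radiographic landmarks: models, phantoms and agreement statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging periodontitis from radiographic landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periostage)
```

## The measurement model

Periodontitis destroys the alveolar bone supporting the teeth. On a panoramic
radiograph that destruction is visible as an increased distance between the
cemento-enamel junction (CEJ) of a tooth and the alveolar bone crest. Because
teeth differ in root length, the raw distance is normalized by the root: with
$d_c$ the CEJ-to-crest distance and $d_a$ the CEJ-to-apex distance (both in
mm), the percentage radiographic bone loss is

$$
P \;=\; 100 \cdot \frac{d_c - 2\,\text{mm}}{d_a - 2\,\text{mm}}.
$$

The 2 mm term is the *biologic width*: in periodontal health the crest
normally sits about 2 mm apical to the CEJ, so that offset is subtracted from
both numerator and denominator. A tooth is additionally *flagged abnormal*
when $d_c$ strictly exceeds 2 mm.

Distances are straight-line Euclidean lengths between landmark points in
pixels, scaled by the image calibration (mm per pixel). Coordinates are
0-based pixel positions and no axis projection is applied, matching how the
measurement lines are drawn on the radiograph. Two numerical choices make
staging a total function of measurable teeth:

* raw percentages below 0 (crest within the biologic width) clamp to 0, and
  above 100 (crest measured beyond the apex) clamp to 100 — both arise only
  from measurement artefacts;
* a root with $d_a \le 2$ mm is *degenerate* and raises an error rather than
  being clamped, and coincident landmark points make a tooth unmeasurable —
  such teeth are excluded and reported, mirroring the clinical exclusion of
  teeth whose bone loss cannot be assessed.

## Staging rules

The patient's stage follows the 2018 classification's radiographic bands,
driven by the **worst tooth** (maximum $P$ over all measurable teeth):

| condition | stage |
|---|---|
| $P < 15\%$ | I |
| $15\% \le P \le 33\%$ | II |
| $P > 33\%$, $\ge 20$ teeth remaining | III |
| $P > 33\%$, $< 20$ teeth remaining | IV |

Two genuinely open points were resolved as follows. The Stage II band is
treated as *closed* at 33% because the classification prints the band as
"15% to 33%". The III/IV split uses the remaining-teeth count with
$\ge 20 \Rightarrow$ III; the alternative tooth-*loss* criterion ($\le 4$ vs
$\ge 5$ teeth lost) is patient history that a radiograph alone does not
carry, and the remaining-teeth rule partitions cleanly. The policy object
(`staging_policy()`) exposes every threshold so either convention can be
switched in. A "healthy / stage 0" label is deliberately not produced by
default: the pipeline's scope is cohorts already diagnosed with
periodontitis, and its automated comparator never outputs a healthy class.
Per tooth, one landmark triple is assumed (no mesial/distal site split).

```{r staging-example}
lm <- tooth_landmarks("16", cej = c(0, 0), crest = c(0, 45), apex = c(0, 120),
                      mm_per_px = 0.1)
assess_tooth(lm)
```

## Image enhancement

Three classical operators prepare radiographs for annotation; each is exactly
specified so results are bit-reproducible:

1. **Unsharp masking** — `out = clip(I + a (I − G₃(I)), 0, 255)` with gain
   `a ≥ 0` (default 1) and `G₃` the 3×3 Gaussian below. The method itself is
   the canonical "edge enhancement" operator; the gain is the only tunable.
2. **Histogram equalization** — the standard CDF remap
   `out(v) = round((L−1)(CDF(v) − CDF_min)/(N − CDF_min))`, `L = 256`. The
   mapping is monotone, so intensity order is preserved; a constant image is
   returned unchanged.
3. **Gaussian smoothing** — convolution with the binomial kernel
   `(1/16)[1 2 1; 2 4 2; 1 2 1]`, the standard discrete 3×3 Gaussian.

Border handling defaults to mirror reflection (replication is available):
reflection avoids the dark rim that zero padding would create, which would
bias crest detection near image edges. All integer rounding is
half-away-from-zero, chosen over R's round-half-even for compatibility with
common image libraries. When chained, the default order is sharpen →
equalize → smooth; `preprocess_image()` takes an explicit step list since
selective application is plausible in practice.

## Agreement statistics

**Binary diagnostic metrics.** `binary_metrics()` implements the standard
confusion-matrix quantities. A metric whose denominator is empty (e.g. NPV
when a rater never calls negative) is `NA` — an explicit "undefined" marker —
never silently 0. Ordinal tables are collapsed to binary ones with
`dichotomize()`: the non-periodontitis category on the expert margin defines
condition-negative, the same category on the rater margin test-negative, and
counts are conserved.

**Weighted Cohen's kappa.** For a $K \times K$ cross-tabulation with cell
proportions $p_{ij}$ and marginals $p_{i\cdot}, p_{\cdot j}$,

$$
\kappa_w = \frac{P_o - P_e}{1 - P_e}, \qquad
P_o = \sum_{ij} w_{ij} p_{ij}, \qquad
P_e = \sum_{ij} w_{ij} p_{i\cdot} p_{\cdot j},
$$

with **linear weights** $w_{ij} = 1 - |i-j|/(K-1)$ as the default: on the
packaged five-category rater tables, linear weights reproduce all three
published kappas to three decimals while quadratic weights do not, which
pins down the scheme the original analysis used. Identity weights recover
unweighted kappa. Confidence intervals come either from a seeded percentile
bootstrap over subject resamples or from the large-sample (delta-method)
variance. Binomial proportions get exact Clopper–Pearson intervals by
default — the exact bounds reproduce the published interval for 82/90
agreement — with Wilson as the alternative.

**Detection scoring.** `map50()` scores axis-aligned detections against
ground truth: per class, detections are sorted by descending confidence and
greedily matched to the unmatched ground-truth box of highest IoU at a 0.5
threshold; AP is the area under the *all-point* precision envelope (the
convention of the modern detection tooling family), and mAP the unweighted
class mean.

Two published cells are knowingly irreproducible from the published counts
and are flagged as documented exceptions by `recompute_published_tables()`
rather than matched: the periodontist weighted agreement (printed 90.1%,
computes to 90.6% — the kappa itself, 0.634, matches exactly) and the
segmentation-model precision/F1 summary cells.

## Sample-size planning for a two-rater kappa study

The planning formula is

$$
n = \left[\frac{z_{1-\alpha/2}\sqrt{Q_0} + z_{1-\beta}\sqrt{Q_1}}{\kappa_1 - \kappa_0}\right]^2,
$$

where $Q = n\,\mathrm{var}(\hat\kappa)$ is the Fleiss–Cohen–Everitt (1969)
large-sample kappa variance evaluated on the 2×2 probability table induced
by the two raters' positive-call probabilities and the hypothesised kappa
($Q_0$ under $\kappa_0$, $Q_1$ under $\kappa_1$), $\alpha$ is two-sided, and
$n$ is ceiled. The variance model is pluggable (`q_model`), but the default
reproduces the reference design — $\kappa_0 = 0.766$, a 25% relative
deviation giving $\kappa_1 = 0.9575$, marginals $0.734$ and $0.766$ —
yielding exactly $n = 83$:

```{r samplesize}
kappa_sample_size(k0 = 0.766, deviation_percent = 25,
                  pi_e = 0.734, pi_0 = 0.766)
```

One subtlety: with unequal marginals the attainable kappa is bounded below 1
(here at ≈ 0.915), so $\kappa_1 = 0.9575$ makes one induced cell slightly
negative (−0.008). The implementation keeps the algebraic cell values and
warns, because clamping would silently change $Q_1$; a grossly infeasible
kappa still errors.

## What the phantoms emulate — and what they do not

Real cohorts of annotated radiographs cannot ship with a package, so every
module is exercised against synthetic inputs with known ground truth.

**Landmark cohorts** (`gen_cohort()`). Each patient draws a true stage from
`stage_mix` (uniform over I–IV by default, so every stage band is exercised
equally) and a worst-tooth bone-loss percentage uniformly inside that
stage's band; the crest landmark is then placed by *inverting* the bone-loss
formula at a root length drawn from a truncated normal (13 ± 1.5 mm on
[8, 20] mm — typical adult root lengths), so zero-noise recovery is exact by
construction. Stage I percentages are drawn from [2, 15) rather than [0, 15)
so small jitter cannot push a tooth below the measurable range; the III/IV
band is capped at 80% as larger losses are rare even in advanced disease.
Remaining-teeth counts are generated metadata (16–28, respecting the III/IV
rule), not inferred from rendered teeth. CEJ, crest and apex are collinear
on a random tooth axis — the measurement is of linear distances, so
collinearity loses nothing. Measurement error is isotropic Gaussian jitter
per landmark in mm (default 0): the simplest model of annotation
imprecision. Calibration defaults to 0.1 mm/px, a typical panoramic scale.

**Phantom images** (`gen_phantom_image()`). Bright convex vertex-jittered
elliptical blobs on a noisy darker background, placed on a jittered grid so
masks are disjoint by construction; each mask is the rasterization of its
own annotation polygon, so annotation round-trips are exact. Border-crossing
blobs are clipped, never dropped, with the clip count in the metadata.

**Simulated raters** (`gen_rater_pair()`). Subjects draw a true category;
each rater draws independently through a row-stochastic confusion kernel.
The expected cross-tabulation has a closed form
(`expected_rater_table()`), giving an analytic kappa that the empirical one
converges to — the oracle for the kappa estimator and its intervals.

**Perturbed detections** (`gen_perturbed_detections()`) translate
ground-truth boxes by a controlled shift, giving a detection set whose mAP50
degrades monotonically from 1 to 0 — a property check for the scorer.

What passing these tests does **not** show: the phantoms are not
photorealistic radiographs — no anatomy, no device artefacts, no occlusion,
no reader fatigue — so they validate the *measurement and evaluation
machinery*, not the difficulty of landmark detection on clinical images.
Published detection-level results on real radiographs (e.g. mAP50 ≈ 0.995)
are not reproducible without the clinical images and are out of scope.

## Problem sizes and numerical choices

The shipped tests stage a 500-patient noise-free cohort (exact recovery
required), restage a 120-patient cohort at 0.5 mm landmark noise against an
independent brute-force oracle (exact agreement required), compare agreement
metrics against brute-force recomputation on 100 random tables at 1e-12,
run 10,000-subject rater simulations for kappa convergence (tolerance 0.02),
and check 200-replicate interval coverage at n = 200 subjects. Dataset
splitting uses largest-remainder apportionment after a seeded shuffle, by
patient id — never by tooth — to prevent leakage; 2,000 ids split exactly
70:10:20 into 1400/200/400. All generators are deterministic functions of
their spec, seed included.

## Known limitations

* One landmark triple per tooth; mesial/distal site asymmetry is not
  modelled.
* Staging uses radiographic bone loss and remaining-teeth count only;
  clinical attachment level, furcation and complexity factors of the full
  2018 classification are out of scope.
* The kappa sample-size model is for two raters and a binary outcome, as in
  the reference design; multi-category planning is not provided.
* `map50()` assumes axis-aligned boxes; mask-level AP is not implemented.
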