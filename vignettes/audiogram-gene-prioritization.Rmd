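---
title: "Audiogram-based gene prioritization: models, assumptions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Audiogram-based gene prioritization: models, assumptions, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otogene)
```

## The problem

Autosomal dominant nonsyndromic hearing loss (ADNSHL) is genetically
heterogeneous: dozens of genes produce overlapping audiometric phenotypes,
and a clinical audiogram alone rarely identifies the causative gene. Many
of the well-characterized ADNSHL genes do, however, leave a recognizable
fingerprint — an *audioprofile* — in how pure-tone thresholds are arranged
across frequency and how they progress with age. `otogene` turns that
fingerprint into a ranked list of candidate genes over a 23-gene panel,
together with interpretability artifacts (audioprofiles, fitted
audioprofile surfaces, cluster geometry) and a dichotomous green/red
confidence flag, so that a reviewer can judge *why* a ranking should or
should not be trusted before committing to targeted sequencing.

Top-3 accuracy, not top-1, is the quantity of clinical interest: in gene
prioritization for validation sequencing, missing the true gene entirely is
far more costly than sequencing two extra candidates.

## Data representation

An audiogram is a patient age plus pure-tone air-conduction thresholds in
dB HL on the fixed 10-frequency grid 125, 250, 500, 1000, 1500, 2000,
3000, 4000, 6000, 8000 Hz — the standard audiometric span including the
half-octave interludes. Thresholds are single per-frequency values; ear
laterality and bone conduction are out of scope. Valid thresholds lie in
[−10, 130] dB HL, the physical range of clinical audiometers. A *patient
record* is a bag of one or more audiograms sharing a patient id, optionally
labeled with the causative gene.

Every model consumes the same 11-dimensional feature vector: age followed
by the 10 thresholds in grid order.

### Missing thresholds

Clinical audiograms are frequently incomplete. Gaps are filled by linear
interpolation against the *grid index* (audiometric frequencies are
near-logarithmically spaced, so index-linear interpolation is approximately
log-frequency-linear), and edge gaps by linear extrapolation from the two
nearest observed points, clamped to [−10, 130]. At least 3 observed
thresholds are required. Interpolating on the index rather than on raw Hz
is a deliberate, fully reproducible convention; observed values are never
modified, which makes imputation idempotent.

## The two classifiers and the routing rule

Patients with a **single audiogram** are scored by a partitioned
heterogeneous ensemble; patients with **two or more audiograms** by a
multi-instance bag classifier. The routing is recorded in every report.

### Single-instance ensemble

Training audiograms are partitioned along three axes:

* **gene data volume** — `high` if the gene's audiogram count is at least
  the median per-gene count, else `low`;
* **patient age** — young (< 20), mid (20–59), old (≥ 60) years;
* **audiogram shape** — flat / downsloping / upsloping / mid-dip, from the
  band means L (125–500 Hz), M (1000–2000 Hz), H (3000–8000 Hz) with a
  15 dB criterion, rules applied in that order and defaulting to flat when
  no rule matches (e.g. a mid-frequency bump).

Eleven submodels are bound to these strata: three k-nearest-neighbour
models on the age strata (k = 5, 15, 31), six adaptive-boosting models
(SAMME over depth-1 decision stumps, 100 rounds) on the volume × shape
grid with upsloping and mid-dip merged into "other", and two random
forests (200 trees) on the volume strata. The binding is a package
convention — the partitioning axes are the established design, the exact
submodel-to-stratum map is configurable in `si_config()`. An empty stratum
falls back to the full training set with a warning.

At prediction time *every* submodel scores the input — each having learned
only its own stratum's regularities — and a fusion stage combines the
eleven probability vectors. Two choices here were genuinely open:

* **Stacking.** The fuser is trained on out-of-fold submodel outputs
  (internal stratified 5-fold) so it never sees a submodel's prediction on
  that submodel's own training point; fusing in-sample outputs would let
  memorizing submodels dominate.
* **Fusion family.** A plain multinomial logistic regression over the
  11 × G stacked probability features (G = number of trained classes, up
  to 23) is heavily over-parameterized and numerically fragile at realistic
  class counts. The fuser is therefore ridge-regularized multinomial
  logistic regression (`glmnet`, α = 0) at a fixed small penalty
  (λ = 10⁻³), which keeps it deterministic (no internal cross-validation)
  and well-conditioned while remaining a logistic combiner.

Genes absent from training receive probability 0 and the output is
renormalized over the full panel, so every prediction is a proper
distribution over the 23 genes.

### Multi-instance bag classifier

For patients with repeated audiograms, one margin classifier (RBF support
vector machine) is trained per unordered pair of gene classes on the
standardized per-audiogram features, with a sigmoid (Platt) calibration of
its decision values. Per audiogram, the K(K−1)/2 calibrated pairwise
probabilities are coupled into a single K-class distribution by the
iterative Hastie–Tibshirani scheme (tolerance 10⁻⁸ on the largest update,
cap 1000 sweeps); the binary case reproduces the input pairwise
probability exactly, and the fixed point matches a brute-force search over
the probability simplex (this is tested).

Bag aggregation is the arithmetic mean of the per-audiogram coupled
distributions, then renormalization. The mean makes a bag of one equal the
single-instance coupled prediction and makes the output invariant to
audiogram order and duplication; max- and noisy-OR-style aggregation were
considered and rejected as less stable for 1–3-element bags. No
semisupervised mechanism is active: all training is on labeled audiograms.

### Determinism and order invariance

Both fits sort training rows canonically (gene, patient id, audiogram id)
before any stochastic step, and all randomness (stacking folds, boosting,
forests) is derived from the configured seed. Refitting with the same seed
is bit-reproducible, and permuting input records does not change
predictions.

## Audioprofiles and audioprofile surfaces

A gene's audioprofile is the mean (and SD) of imputed thresholds per decade
age bin [0,10), …, [90,100) — half-open, so age 30 belongs to [30,40) —
by frequency. Audiograms are weighted equally; whether patients rather
than audiograms should be the unit is unknowable from the available
description, and audiogram-weighting is the simpler convention (a patient
with three visits genuinely contributes three observations of the
phenotype).

The audioprofile *surface* models expected threshold as a bivariate
tensor-product polynomial in (age, frequency index), fitted by ordinary
least squares over all of a gene's audiogram-frequency observations;
default degree is cubic × cubic, evaluation is clamped to [−10, 130]. The
polynomial family is the simplest smooth surface that captures
gene-specific progression; fits degrade gracefully (the basis nests the
constant surface, so the fitted RMSE can never exceed the constant-surface
RMSE) and an underdetermined fit errors with advice to lower the degrees.

`profile_distance()` is the RMS difference over the 10 frequencies between
an audiogram and its age bin's profile row; when the bin is empty the
nearest populated bin is used and the result is flagged as a fallback.

## Cluster and embedding geometry

Labeled audiograms are partitioned into k = 23 groups (one per panel
gene, by design) with k-means: k-means++ seeding, Lloyd iterations, 10
seeded restarts keeping the lowest within-cluster sum of squares. Features
are z-scored first — age in years and thresholds in dB are not
commensurable, and unstandardized clustering would be dominated by
whichever axis spans more units. Stored assignments are recomputed as
nearest-centroid with a lower-index tie-break so the model invariant
("every point belongs to its nearest centroid") holds exactly.

The 3D map of the feature space is produced by classical metric scaling
followed by Sammon stress refinement, which up-weights errors on small
distances and therefore preserves local neighbourhoods; it is
deterministic given the input. Out-of-sample patients are placed by
inverse-squared-distance weighting of the 15 nearest training audiograms'
coordinates (a patient identical to a training audiogram lands exactly on
it), so a new case can be drawn into an existing map without refitting.
The neighbourhood size is the `n_neighbors` parameter; the map is
diagnostic, not inferential — no downstream computation consumes the
coordinates.

## Ranking, concordance, and the green/red flag

`top_genes()` ranks the panel by probability with deterministic
panel-order tie-breaks. For the top 3 genes, two concordance signals are
computed:

* `profile_rms` — mean over the patient's audiograms of the RMS distance
  to the gene's audioprofile (dB);
* `cluster_support` — mean fraction of audiograms in the patient's
  assigned cluster(s) carrying that gene label.

The flag is **green** iff at least one top-3 gene has
`profile_rms ≤ 15 dB` **and** `cluster_support ≥ 0.05`, else **red**.
Both thresholds are declared heuristics, exposed as arguments: clinical
case reviews describe "close similarity" as agreement within a few dB at
several frequencies, and 15 dB corresponds to that plus the ~10 dB
per-threshold noise observed in repeated audiometry; 0.05 support demands
only that the candidate gene be non-negligibly present in the local
cluster. The rule is monotone — improving either signal can never turn
green into red — and unavailable scores (a gene with no trainable profile)
never support green.

Evaluation metrics: top-k accuracy is the fraction of patients whose label
is among the k highest-ranked genes; precision and recall use top-1 as the
hard prediction and are macro-averaged over the classes present in the
labels (an never-predicted class contributes precision 0). Macro
averaging is the convention of record for imbalanced panels; it is
configurable by consuming the per-class table directly.

## The synthetic cohort generator

No public audiogram-with-genotype dataset exists at panel scale, so the
package ships a seeded generator whose defaults define the study
conditions used by the test suite and the acceptance script:

* **23 gene-specific progression models** — baseline thresholds at age 0
  plus per-frequency linear progression slopes, built from the
  audioprofile archetypes the field describes: low-frequency ascending
  (WFS1-like), mid-frequency cookie-bite (TECTA/COL11A2-like), flat
  progressive (EYA4-like), high-frequency downsloping (KCNQ4/COCH-like),
  with severity and speed variants filling the panel. At age 40 at least
  80% of gene pairs are ≥ 8 dB RMS apart (most far more; a few pairs are
  intentionally near-degenerate, as in real audioprofiles).
* **Noise** — i.i.d. Gaussian, SD 10 dB per threshold, clamped to the
  audiometer range. Real test–retest errors are correlated across
  neighbouring frequencies; the independence simplification makes the
  recognition problem slightly *harder* at fixed SD and is documented as
  such.
* **Class imbalance** — Zipf (1/rank) prevalence over the panel, giving a
  long tail of rare genes.
* **Visits** — 1, 2 or 3 audiograms per patient (55/30/15%), follow-ups
  1–3 years apart; first-visit age Uniform(5, 80).
* **Missingness** — optional independent per-threshold deletion at a
  configurable rate, never reducing an audiogram below 3 observed values.

What passing tests on this cohort do show: the full pipeline recovers
generating genes far above chance under realistic noise, imbalance and
missingness, and every structural contract holds. What they do not show:
clinical accuracy. Real audioprofiles overlap more irregularly, errors are
correlated, cohorts carry ascertainment bias, and region-of-origin labels
here are decorative draws from a fixed categorical distribution.

## Problem sizes and numerical choices

The reference synthetic study (used by `scripts/acceptance.R` and the
acceptance tests) is 1000 patients (~1600 audiograms) under 5-fold
patient-level cross-validation — large enough for stable top-3 estimates
on a 23-class problem while keeping a full run in a few minutes on one
core. Unit tests use cohorts of 40–250 patients and analytic toys.

Numerical conventions collected in one place: imputation and surface
evaluation clamp to [−10, 130] dB; pairwise probabilities are clipped to
[10⁻⁶, 1 − 10⁻⁶] before coupling; coupling stops at max update < 10⁻⁸ or
1000 sweeps; k-means convergence is delegated to Lloyd iterations
(`iter.max` 100) with inertia recomputed from final assignments; exact
centroid ties resolve to the lower cluster index; ranking ties resolve to
panel order; stacking folds, boosting reweighting and forest bootstraps
all derive from the configured seed; empty strata fall back to the full
training set with a warning; classes with fewer than 2 audiograms are
excluded from training with a warning and reported with probability 0.

## Known limitations

* The 23-gene panel is a closed world: a patient whose causative gene is
  outside the panel can at best be red-flagged, never correctly ranked.
* The shape taxonomy (flat/downsloping/upsloping/mid-dip at 15 dB) is a
  workable stand-in for richer clinical audiogram-shape classifications.
* Bag aggregation by arithmetic mean treats a patient's audiograms as
  exchangeable; longitudinal ordering information (progression rate within
  a patient) is only captured indirectly through age features.
* The confidence flag thresholds are heuristics; sites with different
  noise floors should recalibrate `tau_rms`/`tau_sup`.
* Synthetic validation bounds what can be claimed about clinical
  performance (see above).
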