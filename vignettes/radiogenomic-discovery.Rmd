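---
title: "Radiogenomic marker discovery: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiogenomic marker discovery: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(radgen)
```

## The problem

Head and neck squamous cell carcinoma is clinically and molecularly
heterogeneous, and few markers stratify patient risk. This package implements
a discovery pipeline that combines two data modalities per patient — PET/CT
radiomic features from the primary lesion and pathway-level mutation burden
from tumor-only whole-exome sequencing — into conjunctive *radiogenomic
markers*: binary indicators of the form "pathway X in state S **and** radiomic
feature F at level L". The pipeline screens such conjunctions for prognostic
value against overall survival (OS) and cross-validates multivariate models
on the selected features.

## Pipeline stages and their models

### 1. Tumor-only somatic filtering

Without a matched normal, germline variants must be filtered heuristically.
Four conjunctive rules are applied to an annotated variant table, with every
comparison strict:

1. **Cohort frequency** — keep variants carried by *less than* 10% of
   samples (a carrier counts once per variant regardless of multiplicity;
   the fraction is computed on the raw input table).
2. **Caller evidence** — keep variants reported by both callers with more
   than 10 supporting reads, or by a single caller with more than 20.
3. **Population allele frequency** — keep variants below 1% in *all three*
   population databases. A missing AF is treated as zero: absence from a
   population database is itself evidence of rarity. The choice is logged
   per variant by keeping the original NA in the retained table.
4. **ClinVar** — remove variants classified benign or likely benign.

The retained set is the intersection of the four single-rule pass sets, so
rule order is irrelevant to the result; the removal report attributes each
removed record to the first failing rule in the order above.

### 2. Pathway-level CADD disruption scores

Per-variant CADD PHRED scores (the conventional deposited scale; configurable)
are summed per (sample, gene), then gene scores are summed over each
pathway's gene set. A gene in several pathways contributes fully to each —
TP53, for example, feeds five of the nine default pathways. The default
roster has six cell-growth-and-death sets (cell cycle, apoptosis, p53
signaling, cellular senescence, ferroptosis, necroptosis) and three energy
metabolism sets (oxidative phosphorylation, nitrogen, sulfur). Only six of
the nine set identities are certain from the source material; the roster is
an explicit assumption, ships as a GMT, and is fully user-replaceable.

Because no uniform CADD cutoff separates functional from disrupted biology,
each pathway score is dichotomized at its own **survival-derived cutoff**
(below), yielding a binary functional/disrupted state per patient. The state
is "disrupted" iff score > cutoff; the strict inequality is a documented
convention (the source does not state which side is closed).

### 3. Radiomics

Volumes of interest arrive as 3D grids with a lesion mask and (PET) a
homogeneous reference-region mask. Preprocessing per modality:

* PET intensities are divided by the mean intensity of the reference region
  (background normalization) before interpolation; the anatomical identity
  of the region is a user/generator choice.
* Trilinear interpolation onto an isotropic 2 mm grid (4 mm available;
  which grid fed which feature is not stated in the source, so 2 mm is the
  default analysis grid). Masks are resampled nearest-neighbour.
* The lesion mask is dilated by 5 voxels, implemented as Chebyshev
  (cube) dilation — the literal reading of "into every spatial dimension".
  Lesions below 64 voxels are excluded.
* Intensities are discretized to 32 grey levels spanning the masked range
  (fixed bin number, invariant to affine intensity transforms; fixed bin
  size is available).

The default feature roster has 52 features per modality — 8 morphology, 18
intensity statistics, 14 intensity histogram, 12 grey-level size-zone
(GLSZM, 26-connected zones) — 104 in total, plus SUVmax/min/mean/peak, MTV
and TLG from the raw PET lesion. The family counts are the conformance
surface; the exact 52-name roster is this package's documented list, since
the source's supplement is not available. `PET.stat.sum`, the summed lesion
activity, is deliberately volume-confounded (it equals mean intensity times
voxel count) and tracks MTV by construction.

### 4. Survival machinery

* **Optimized-cutoff logrank**: candidate cutoffs are the midpoints between
  consecutive sorted distinct values; candidates leaving less than 15% of
  the cohort in either group are inadmissible; the returned cutoff minimizes
  the two-sided logrank p, ties broken toward the smallest cutoff. The scan
  is exhaustive by construction and the logrank core is validated against
  `survival::survdiff` in the tests.
* **Redundancy removal** precedes the univariate feature screen: from every
  feature pair with |Spearman| > 0.9 the member with the larger mean
  absolute correlation is dropped. Radiomic panels are massively redundant
  (all features derive from one image), and the published analysis screens
  the reduced panel, not all 104 features.
* Cox proportional hazards fits use `survival::coxph` with Efron ties
  (Breslow switchable); Mann-Whitney association uses the exact
  distribution when both groups have at most 8 observations and no ties;
  Bonferroni correction is `min(1, m p)` with the family size attached to
  every adjusted value. Families are per stage (screened features, nine
  pathways, pathways x features associations, retained markers).

**A caveat the package surfaces deliberately**: the minimized logrank p of an
optimized cutoff is a maximally selected statistic and is anti-conservative
if read as a fixed-cutoff test. Because pathway states *and* feature levels
are both derived this way on the same cohort, downstream marker p-values
inherit the anti-conservativeness; under a global null the large majority
of cohorts (~87% in the package's own 200-replicate calibration check)
yield some Bonferroni-surviving marker. The package's test suite
quantifies this (the null-calibration acceptance check fails by design and
is documented as such), and shows that with survival permuted and marker
definitions frozen the discovery rate collapses to near zero — the
machinery is correct; the selection-on-the-same-data protocol is what
inflates. Confirmatory use requires an independent cohort or
permutation-based correction, which is out of scope here.

### 5. Radiogenomic markers

Pathways and (non-redundant) radiomic features with raw optimized-cutoff
logrank p < 0.05 are combined: each (pathway, feature) pair yields four
binary markers — disrupted/high, disrupted/low, functional/high,
functional/low — which partition the cohort. Feature levels reuse the
univariate optimized cutoff (one cutoff per feature keeps the family
interpretable). Markers with less than 15% of evaluable patients in either
the present or absent group are discarded; the survivors are evaluated by a
*fixed-group* logrank (no second cutoff search), Bonferroni-corrected within
the retained family, and ranked. Selection uses raw p by design (the source
combines "most prognostic" items while reporting corrected significance
elsewhere); both modes are configurable. Note that a marker and its
complement corner (e.g. disrupted/high vs functional/low) describe the same
stratification from the risk and the protective side respectively; which
corner tops the ranking can flip between cohorts.

### 6. Machine learning

Three binary OS targets (strictly greater than 24 months, the cohort
median, and 36 months); patients censored before a threshold are excluded
from that model because their label is unknowable — cohort sizes per model
are reported so the choice is auditable. Up to 20 features are drawn from
the three families (top markers, pathway scores, radiomic features, each
ranked by univariate p). Validation is 100-fold Monte Carlo
cross-validation with stratified 80:20 splits; per split, standardization,
redundancy removal, and SMOTE oversampling (k = 5 minority neighbours) are
fitted on the training part only. The classifier is a stacked ensemble of

* a bagged random forest of depth-5 CART trees with sqrt(p) feature
  subsampling (50 trees),
* an RBF-kernel ridge classifier (median-distance bandwidth heuristic,
  ridge 0.5), and
* Gaussian naive Bayes wrapped in a genetic feature-subset selector
  (population 20, 10 generations, AUC fitness on an inner 70:30 split),

combined by a logistic meta-learner on 5-fold out-of-fold base
probabilities. All three learners are in-package implementations: the
original protocol's ensemble ran inside a proprietary AutoML whose random
forest/SVM/"multi-Gaussian genetic algorithm" internals are not
reproducible, and no SVM/tree package is assumed present. They are
substitutes filling the same roles, not replicas. ACC/SNS/SPC/PPV/NPV use
a 0.5 probability threshold; AUC is threshold-free. Feature importance is
the squared point-biserial correlation (R²) of each feature with the label
on every training split, averaged over the 100 splits and normalized to sum
to 100% per model; computing R² on training rather than test splits is a
documented choice (the source does not say which it used).

## The synthetic-study generator

`simulate_study()` generates cohorts whose statistical structure matches the
assumptions above, so every stage is testable without patient data:

* **Survival**: Weibull baseline, shape 1.2, scale tuned so the baseline
  median is 25 months (matching the study cohort's median OS); independent
  administrative censoring uniform on (0, 130) months (the study's observed
  OS range). Patients with the planted marker present have their hazard
  multiplied by `hazard_ratio` (default 3).
* **Latent structure**: each of the nine pathways is independently
  disrupted with probability 0.4. A latent size/texture driver is standard
  normal, shifted by `texture_shift` (default 1.5 SD) for patients whose
  planted pathway is disrupted. The planted marker is present when the
  pathway state matches and the driver is above the population mean.
* **Variants**: ~8 background somatic variants per patient over the pathway
  gene pool plus filler genes, CADD drawn from a 70/30 mixture of U(0,10)
  and U(15,40); each disrupted pathway adds ~4 deleterious variants
  (CADD U(20,40)) in its own genes, so pathway scores separate by state;
  germline-like contaminants (30% of the somatic count) carry population
  AFs U(0.05, 0.5) in all three databases and are half ClinVar-benign, so
  the filter cascade removes them; ~8% of records fail the caller-evidence
  rule; two recurrent artifact keys exceed the 10% carrier rule.
* **Images** (`level = "image"`): ellipsoidal lesions whose volume, base
  uptake and heterogeneity increase with the driver; intensities are base
  level plus spatially correlated noise (3D-smoothed white noise — size-zone
  features are degenerate under voxel-independent noise); a homogeneous
  reference block sits in a grid corner away from the dilated lesion. No
  scanner physics, attenuation, or partial-volume modelling.
* **Feature mode** (`level = "feature"`): for statistical calibration
  studies, the 110-column feature table is drawn directly from a 5-factor
  latent model (factor 1 = the driver; every feature loads ~0.97 on one
  factor), mirroring the within-family redundancy of real radiomic panels.
  Rendering volumes adds realism to the extraction path but no information
  to survival-statistics calibration, and costs ~200x more.

All draws flow from one base seed; per-patient substreams come from a stable
hash of the patient id, so studies are reproducible and order-independent.

A green recovery test on this generator establishes that the pipeline can
surface a planted conjunctive effect of the stated size under the stated
noise; it does not establish performance on real scanners, segmentations,
or mutation spectra, and the generator's single-lesion, single-centre,
covariate-free world is deliberately simpler than any clinical cohort.

## Degenerate inputs and numerical conventions

* Constant feature or pathway score: no admissible cutoff, flagged, excluded
  downstream.
* Empty lesion mask or non-positive reference mean: error at construction
  or normalization.
* Cohorts too small for the 15% rule (below ~7 patients per side at n = 20)
  produce empty marker stages with warnings, never silent output.
* Excess kurtosis of constant levels is a flagged missing value.
* Patient linkage across inputs is by exact string id; mismatches are
  excluded with a logged census, never imputed.

## Known limitations

* Marker p-values are anti-conservative by protocol (see above); the
  package reports them as ranking scores, not calibrated error rates.
* The 52-feature roster matches the source's family counts, not its exact
  (unavailable) list; GLCM/GLRLM/NGTDM families are out of scope.
* The ensemble is a documented substitute for a proprietary AutoML; its
  absolute AUCs are not comparable to the published 0.72/0.72/0.75.
* One lesion per patient; DICOM ingestion and delineation are out of scope.
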