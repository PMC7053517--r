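---
title: "Activation and exhaustion analysis of tumour-infiltrating lymphocytes: methods"
author: "tilax authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activation and exhaustion analysis of tumour-infiltrating lymphocytes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilax)
```

# Scope

`tilax` analyses quantified single-cell tables from multiplexed
immunofluorescence of melanoma tissue microarrays (TMAs): one row per
segmented cell carrying its image (core) and patient of origin, centroid
coordinates in pixels, and the mean fluorescence intensity (MFI) of each
marker in a 39-marker panel. Everything upstream — staining, registration,
autofluorescence subtraction, segmentation — is out of scope; the package
starts at the quantified cell table.

The pipeline has six analysis stages plus a synthetic-data generator used to
test them:

1. **QC and normalisation** (`filter_cells()`, `filter_markers()`,
   `zscore_trim()`): cells expressed in fewer than 3 markers and markers
   expressed in fewer than 1% of cells are removed, then each marker is
   z-scored and trimmed to [-5, 5].
2. **Activation scoring** (`activation_model()`, `predict()`): a PCA-derived
   gradient scores each CD8+ cell from activation (+1) to exhaustion (-1).
3. **Status classification** (`classify_cores()`, `classify_patients()`,
   `robustness_resample()`, `dichotomize_logrank()`).
4. **Consensus phenotyping** (`cluster_three_ways()`, `annotate_clusters()`,
   `consensus_assign()`, `functional_subcluster()`).
5. **Spatial neighbourhood analysis** (`build_neighbor_graph()`,
   `permutation_test_image()`, `integrate_images()`,
   `melanoma_neighbor_profile()`).
6. **Cohort statistics and external validation** (`activation_vs_factor()`,
   `composition_tests()`, `qpcr_classify()`, `assign_cell_types()`,
   `build_activation_signatures()`, `label_patients()`).

The exported functions, this vignette and the test suite are the interface;
there is no shell entry point because the package is used interactively or
from scripts, like its peers in the R analysis ecosystem.

# Normalisation

"Expression" for the QC filters means a raw MFI strictly above a threshold
that defaults to 0 (any signal after upstream background subtraction); the
threshold is exposed because different segmentation pipelines leave
different floors. Cells are filtered before markers, and z-scores are
computed after both filters, globally across the retained cells (a per-core
mode exists behind `per_core = TRUE` for sensitivity analysis). The sample
standard deviation (n-1 denominator) is used. Trimming at ±5 limits the
leverage of segmentation artefacts; the number of clamped values is
reported in the `"n_clipped"` attribute because a large count signals a
problem upstream, and re-applying the normalisation is only a no-op when
nothing was clipped.

# The activation gradient

Four functional markers are measured on CD8+ (Tcy) cells: CD69 and OX40
(activation), TIM3 and LAG3 (exhaustion). PCA on their z-scores yields a
first component on which all four markers load with the same sign — a
common-mode axis reflecting each cell's overall functional staining
intensity, not its functional state. Components 2 and 3 are therefore
retained; the model checks the common-mode property of PC1 and, when it
fails, warns and falls back to the component pair that maximally separates
the CD69 and TIM3 loading directions in angle (the selection is data-driven,
so the fallback keeps the model usable on atypical inputs).

Within the retained plane the model defines two **anchors**: the unit CD69
loading direction (maximal activation, score +1) and the unit TIM3 loading
direction (maximal exhaustion, score -1). LAG3 and OX40 participate in the
fit but not in the anchors: LAG3's rotation vector is not aligned with TIM3
and few cells express it, so it contributes little to the exhaustion
direction. PCA sign indeterminacy is resolved by requiring the CD69 loading
to be positive on the first retained axis and the TIM3 loading negative on
the second; anchors are recomputed after the flip, so refits are
bit-reproducible.

A cell's score depends only on the **direction** of its centred projection:
the angle from the active anchor, measured along the shorter arc towards the
exhausted anchor, is mapped linearly to [+1, -1] and clamped beyond the
anchors; directions in the reflex region are clamped to the nearer anchor.
The centroid itself (and any projection within 1e-9 of it, numerical noise)
scores 0, as does the angular midpoint of the arc. Radial invariance is a
modelling choice: distance from the centroid mostly encodes staining
intensity, which the common-mode argument already discards. The exact
interpolation between the anchors and the centroid is not uniquely
determined by the geometry alone, so `method = "axis"` provides the obvious
alternative (cosine of the angle to the anchor-difference axis); both agree
on the anchors, the centroid and the bisector, and differ only in the
speed at which scores change between them. The arc map is the default
because it is linear in the quantity the gradient is defined on.

One consequence worth knowing: cells with *low everything* ("anergic")
have no meaningful direction — their small residual vector points wherever
noise sends it, often towards the active side because they lack TIM3. The
score is a statement about the activation-exhaustion axis only; anergic
cells are identified by the functional subclustering, not by the score.

# Core and patient status

Each unit (core, or patient after pooling all the patient's cells) is
compared against the background distribution of all scored cells — the
unit's own cells included, matching the definition of the background as the
combination of all images; a leave-one-out background is available behind a
flag. Two one-tailed two-sample t-tests are run per unit (unit mean greater
/ smaller than background mean). Welch's form is the default because cores
differ in size and variance; the pooled form sits behind `var_equal`. Raw
p-values are collected across units and Benjamini-Hochberg adjusted,
separately within the Active-side and Exhausted-side families (the joint
family is available; with one-tailed pairs on the same mean the per-side
structure keeps the two decisions symmetric). A unit is Active or Exhausted
when the corresponding adjusted p-value falls below 0.001, Transition
otherwise; the guard case of both sides significant is labelled Transition
with a warning.

The resampling robustness analysis reclassifies a patient 100 times at each
subsample size from 10 to 1000 cells (step 10, capped at the patient's cell
count, sampling without replacement) and reports the smallest size at which
at least 95% of replicates reproduce the full-data label. A single
resampled unit has no family to adjust over, so replicates are labelled
from the raw one-tailed p-values.

For survival, each patient is represented by the mean activation of its
cells and dichotomised at 0 (mean exactly 0 goes to the exhausted group);
Kaplan-Meier curves and the log-rank test come from the `survival` package.

# Consensus phenotyping

Three clustering algorithms run over the phenotypic-marker z-scores:

* `stats::kmeans`, with k chosen by mean silhouette width over a candidate
  range (default 10-30, matching a ~17-phenotype panel; the silhouette
  search subsamples at most 2000 cells because its cost is quadratic);
* a PhenoGraph-style method: exact k-nearest-neighbour graph (k = 30),
  Jaccard edge weights from shared neighbourhoods, Louvain community
  detection via `igraph`;
* a ClusterX-style method: density-peak clustering (Gaussian-kernel local
  density at a bandwidth set to the 2% distance quantile, separation =
  distance to the nearest denser point, centres selected where the
  normalised density-separation product exceeds a threshold, remaining
  cells inheriting the cluster of their nearest denser neighbour).

Each method's clusters are represented by their mean z-vector and annotated
with an ordered **rulebook** — the explicit, externalised form of expert
cluster reading. A rule lists required-high and required-low markers; the
first matching rule (by priority) wins, and clusters matching none are
"unassigned", mirroring the discarded clusters of real analyses.
Thresholding is baseline-aware: a cluster's overall staining brightness
shifts all its marker means together, so "high" means above +0.5 absolutely
*or* 0.5 above the cluster's across-marker median, and "low" means below
-0.1 *or* within 0.2 of that median. A genuinely co-expressed marker sits
far above the median and still disqualifies a required-low rule. Without
the baseline terms, brightness-split subclusters of one phenotype are
systematically unassigned.

A cell keeps a phenotype only when at least two methods annotate it
identically ("unassigned" never counts); the retained fraction is reported.
Functional subclustering then reruns the PhenoGraph-style method per
phenotype over the functional markers — Tcy cells use their personalised
panel (CD8, CD69, OX40, LAG3, TIM3, PD-1, Ki-67) — and annotates the
subclusters with a functional rulebook (active, transition, exhausted,
proliferating, anergic).

Density-peak clustering is the weakest of the three on wide panels: with
dozens of noisy dimensions, within-cluster distances approach
between-cluster distances and the density-separation contrast degrades.
That is precisely the failure mode the two-of-three consensus absorbs, and
why the consensus rather than any single method is the unit of validation.

# Neighbourhood analysis

Two cells are neighbours when their centroid distance is at most 30 px
(boundary inclusive); the graph is built with grid bucketing and matches a
brute-force all-pairs oracle exactly in the tests. Per image, the statistic
for an ordered pair (i, j) is the mean number of type-j neighbours per
type-i cell (a total-count variant sits behind a flag). The null
distribution permutes the phenotype labels over the fixed positions — the
point pattern and the composition are preserved, only the labelling is
randomised. One-sided empirical p-values use the add-one estimator
(r + 1) / (n + 1); with 1000 permutations and a threshold of 0.001 a call
therefore requires the observed statistic to be more extreme than every
permutation. Calls are tri-state: proximity (+1), avoidance (-1),
non-significant (0); phenotypes absent from an image are not evaluable
there and contribute nothing to the integration.

Across images, calls are integrated as a weighted mean,

$$P_{ij} = \frac{\sum_k c_{ijk} N_{ijk}}{\sum_k N_{ijk}},
\qquad N_{ijk} = \sqrt{n_{ik}\, n_{jk}},$$

so images contribute in proportion to the geometric mean of the two
phenotypes' cell counts. |P| > 0.75 is a strong interaction (strictly:
0.75 exactly is moderate), 0.5-0.75 moderate, 0.25-0.5 weak, otherwise
non-significant. The statistic is directional — j around i is not i around
j — so both directions are computed and reported; no symmetry is imposed.

Dominant cell types growing in packed nests (melanoma) violate the
permutation model's sensitivity, so melanoma contacts are profiled
directly: for each other subpopulation, the number of its cells within the
radius of a melanoma cell is summed over the cores where the subpopulation
occurs and divided by the geometric mean of the melanoma and subpopulation
counts over those cores.

# Cohort statistics and external validation

Per-core activation (the mean of the core's cells) is tested against
histopathological factors: two-level factors by t-test, multi-level factors
by all pairwise t-tests with a pooled standard deviation and Holm
adjustment, continuous covariates by the slope of a linear model.
Composition differences use the Wilcoxon rank-sum test for two groups and
Kruskal-Wallis for three or more, flagged at p < 0.05. All of these call
the base R implementations and are verified in the tests against
hand-computed textbook oracles on small fixtures.

qPCR samples of microdissected TILs are classified as *active* when
log(IFNg / CD45) is strictly positive and as *exhausted* when LAG3 and/or
TIM3 is expressed while both IFNg and CD40L are not; "expressed" means
above a configurable floor, default 0, because the assay normalisation does
not fix a universal floor.

For transcriptomic validation, single cells are assigned to signature
profiles (an LM22-style matrix, plus constructed profiles) by Spearman
correlation over the shared genes, keeping the best-correlated type when
the correlation reaches 0.25 — rank correlation makes the assignment
invariant to any monotone transform of a cell's expression. Active and
Exhausted CD8 signature profiles are built by aggregating the activation
transcripts to the four marker channels, z-scoring, fitting the activation
model, splitting at score 0 (0 itself is Exhausted), and averaging each
class's expression of the activation genes. The default six-transcript
mapping (CD69; TNFRSF4/TNFSF4 for OX40; LAG3; HAVCR2/LGALS9 for TIM3) is a
synthetic best guess shipped for convenience and clearly marked
non-authoritative — supply the study-specific list when one exists. A
patient is labelled Active when the Active CD8 fraction is at least the
Exhausted fraction.

# The synthetic-data generator

`simulate_cohort()` produces cohorts with the statistical structure the
pipeline assumes, so every stage can be tested without any external data.
Its defaults mirror the study design the pipeline targets: 29 patients,
1-3 TMA cores each (about 60 cores), thousands of cells per core, and a
third of cores planted per status.

* **Marker intensities** are log-normal around per-(phenotype, marker)
  means — MFIs are non-negative and right-skewed, and no generative model
  is prescribed by the assay, so multiplicative noise is the natural
  choice. Lineage markers of a phenotype sit at 40 (arbitrary units)
  against a background of 5, with log-sd 0.4.
* **Staining variability** enters as two per-cell multiplicative factors: a
  mild global factor (log-sd 0.15, cell size / staining efficiency) and a
  stronger factor on the four activation markers only (log-sd 0.8, the
  overall functional staining intensity). The second factor is what gives
  the activation PCA its common-mode first component, reproducing the
  structure observed in real MFI data; it was separated from the global
  factor because a global factor strong enough to dominate PC1 would also
  dominate cell-to-cell distances and destroy phenotype clustering, which
  real data does not show.
* **Functional classes** for CD8 cells shift (CD69, OX40, LAG3, TIM3) means
  multiplicatively: active (4.0, 2.8, 0.7, 0.7), transition (2.0, 1.6,
  1.0, 2.0), exhausted (0.7, 0.7, 2.0, 4.0), anergic (0.7 throughout).
  Core statuses draw class mixes from `status_activation_profiles()`;
  statuses are planted per core by default (real patients are
  heterogeneous) or per patient behind `status_level = "patient"`.
* **Spatial structure** is a uniform (CSR) background per core; planted
  attraction relocates a fraction of type-j cells into the radius of a
  random type-i cell, planted avoidance rejection-samples them outside all
  type-i radii with a bounded number of attempts. CSR admits the
  closed-form neighbour expectation $n_j \pi r^2 / A$ used as an oracle.
* **Survival** times are exponential with status-dependent medians (70 /
  45 / 25 months for Active / Transition / Exhausted) under uniform
  censoring at 60-120 months.

The generator does **not** emulate segmentation errors, marker spillover,
spatial gradients within a core, batch effects across staining rounds, or
doublets. Passing tests therefore demonstrate that the pipeline's
inference machinery is correct under its own assumptions — calibrated
permutation tests, exact integration arithmetic, recovery of planted
structure — not that those assumptions hold in any particular tissue
dataset.

# Numerical choices and problem sizes

Degenerate inputs fail loudly: zero-variance markers name themselves,
rank-deficient activation input names the constant column, empty dichotomy
groups and empty rulebooks are errors, units below 2 cells are excluded
with a message. Ties in the density ordering of the density-peak method
break by index so exact duplicates chain into one cluster. The neighbour
radius is boundary-inclusive (distance = 30 connects). Empirical p-values
never reach 0 by construction.

The test suite and the acceptance script run everything at reduced but
statistically meaningful sizes chosen once: 60-core cohorts with 400 cells
per core for status recovery, 5000 cells for consensus phenotyping, 500
CSR images at 200 permutations for calibration, 100 images per planted
interaction mode at 1000 permutations, 1000 random fixtures for the
integration oracle. Full-scale cohorts (~240k cells) run through the same
code paths unchanged.

# Known limitations

* The activation score is directional; it cannot distinguish anergic from
  active cells by itself (see above).
* The silhouette-based k selection subsamples, so the chosen k can vary
  between machines only through the seeded RNG — it is deterministic for a
  fixed seed.
* Density-peak clustering degrades on wide marker panels; it is retained
  as one voice in the consensus, not as a standalone method.
* The per-side FDR family structure is a documented choice; the joint
  family is one flag away and slightly more conservative.
* External accession-based validation (public single-cell melanoma data,
  LM22) is supported by the deconvolution functions but not executed
  anywhere in the package: no data are downloaded, and the shipped
  six-transcript mapping is a placeholder.
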