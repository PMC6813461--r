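---
title: "Methods: differential leukocyte subpopulation discovery from mass cytometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential leukocyte subpopulation discovery from mass cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

cytoforge implements a whole-blood mass-cytometry (CyTOF) analysis chain for
case/control cohorts: clustering of all leukocytes, categorical phenotyping
and rule-based annotation of clusters, differential cluster abundance
between disease and control groups, quantification of candidate
subpopulations in isolated parent populations, correlation of subpopulation
abundance with clinical covariates, and quantification of cytokine
responses after TLR stimulation. A synthetic cohort generator with planted
ground truth drives validation: every statistical claim the test suite
makes is checked against quantities the generator controls.

The motivating use case is a rheumatoid-arthritis (RA) immunophenotyping
design: nine treated RA patients and five healthy donors, each measured on
a 33-marker panel, with paired TLR-stimulated/control samples for the
functional arm. Two candidate subpopulations structure the analysis: a
CD11b-low CD16-high neutrophil subset whose within-neutrophil share grows
with disease duration, and a CD11a-high Granzyme-B-high T-cell subset
present in only part of the patients and inversely related to the DAS28
activity score.

# Preprocessing model

Input samples are cells-by-markers tables (FCS 3.0/3.1 or CSV). Ion counts
are variance-stabilized with `asinh(x / cofactor)`; the cofactor defaults
to 5, the CyTOF community convention, and is a configuration key because
fluorescence data conventionally uses larger cofactors. Bead-based
normalization is assumed already applied upstream; the package neither
implements nor requires it, and the simulator emits post-normalization
intensities by construction. Marker names match exactly after whitespace
trimming — silent aliasing corrupts panels, so none is attempted.

# Clustering stage

Clustering follows the SPADE recipe: density-dependent downsampling,
agglomerative clustering of the downsampled pool, a minimum spanning tree
over cluster medians for visualization, and upsampling of all cells.

* **Density.** The density of a cell is the number of cells within L1
  distance `alpha * d_med` of it over the clustering markers, where
  `d_med` is the median nearest-neighbour distance of a 2,000-cell seeded
  subsample. `alpha = 5` and the L1 metric follow the original SPADE
  description; both are exposed as parameters. Densities are estimated per
  sample (each sample is one acquisition), which also keeps the quadratic
  scan tractable.
* **Downsampling.** Each cell is retained with probability
  `min(1, TD / density)`; the target density TD is solved by bisection so
  the expected retained fraction equals the target (5 % by default). This
  thins dense regions while keeping rare phenotypes, which is the entire
  point: rare disease-associated subsets survive to the clustering step.
  An optional low-density outlier floor (percentile cut) exists but is off
  by default.
* **Clustering.** Average-linkage agglomerative clustering on L1 distances
  of the pooled downsampled cells, cut at `k` clusters: `k = 500` for the
  main arm and `k = 100` for the stimulation arm in the reference design.
  All samples and conditions are clustered jointly so cluster ids are
  comparable across samples.
* **Upsampling.** Every cell of every sample is assigned to the nearest
  cluster median (L1); ties break toward the lower cluster id so
  assignment is total and deterministic. Clusters that end up empty are
  retained with zero abundance rather than renumbered, keeping ids stable.

# Categorical phenotyping and annotation

For each marker, the expression range is the 5th–95th percentile
(linear-interpolation quantiles) over all pooled cells. The range is split
into five uniform categories — negative, low, medium, high, bright. A
cluster's category for a marker bins the mean over samples of its
per-(cluster, sample) expression medians; samples where the cluster is
empty do not contribute. Bins are left-closed/right-open with the last bin
closed, and out-of-range values clamp to the extreme categories, so
categorization is total and monotone. Whether the original heatmap
computed percentile ranges over cells or over cluster medians is ambiguous
in its description; this implementation uses pooled cells and documents the
choice here (a switch would be a one-line change in `marker_ranges()`).

Annotation applies category-scale rules over the nine annotation markers
(CD3, CD11c, CD14, CD16, CD19, CD66, CD123, Granzyme B, HLADR) in priority
order: neutrophil CD66≥3; T-cell CD3≥3 & CD66≤1; B-cell CD19≥3; pDC
CD123≥3 & HLADR≥3; basophil CD123≥3 & HLADR≤1; monocyte CD14≥3; NK CD16≥3
& CD3≤1 & CD66≤1; cDC CD11c≥3 & HLADR≥3 & CD14≤1. The reference study
annotated manually; these rules encode its marker list with canonical
immunology, and the priority order resolves the deliberate overlaps (a
neutrophil is CD16-positive but CD66 decides first). The stimulation arm
swaps Granzyme B for CD64.

# Differential abundance

Cluster abundance is the fraction of a sample's cells in the cluster. A
cluster trends disease-enriched when its mean abundance over RA samples
exceeds the healthy mean. Significance uses a group-label permutation
test with the absolute difference of group means as statistic; all
C(14, 9) = 2,002 relabelings are enumerated exactly for the reference
design, and enumeration is automatic up to 10^6 relabelings with a
Monte-Carlo fallback beyond. The p-value counts relabelings at least as
extreme as the identity, identity included, so it is never zero and never
below 1/total. No multiplicity correction is applied by default, matching
the per-cluster reporting convention of the source analysis;
Benjamini–Hochberg is available behind a flag.

# Subpopulation quantification

All cells of an annotated population are isolated via their clusters and
embedded in 2-D with t-SNE on the markers that define the candidate
phenotype (CD11b + CD16 for neutrophils; CD11a + CCR5 + Granzyme B for
T-cells), after equal per-sample subsampling so every sample contributes
the same weight. The embedding here is an exact-gradient t-SNE
implementation (Gaussian affinities calibrated per point to the target
perplexity, Student-t output kernel, early exaggeration, momentum with
adaptive gains). Exact gradients are quadratic in cell count, so the
default equal subsample is moderate; perplexity 30 and 1,000 iterations
are the defaults.

The original analysis delineated areas on the embedding by eye. An
operative replacement is required for reproducibility, so areas are
explicit objects: polygons in embedding space (boundary counts as inside;
overlapping polygons are rejected) or marker rules on the transformed
scale. The shipped defaults are marker rules with thresholds midway
between the generator's parent and subpopulation modes: CD11b ≤ 2.5 and
CD16 ≥ 5 for the neutrophil subset, CD11a ≥ 4.25 and Granzyme B ≥ 3.15 for
the T-cell subset. Cells matching no area fall into a "rest" area, so the
assignment is a partition. Because per-group cell percentages can be
computed by pooling cells or by averaging per-sample percentages — and the
original report is ambiguous — both are reported.

Mean signal intensity (MSI) is the mean transformed intensity over an
area's cells. Between-area MSI tests permute per-sample means, not cells:
the sample is the independent unit, and permuting cells would
pseudo-replicate.

# Clinical correlation

Spearman's coefficient is the Pearson correlation of mid-ranks. With no
ties and n ≤ 10 the two-sided p-value comes from the exact permutation
null of the rank statistic S (all n! rank orders enumerated in compiled
code; two-sided p = min(1, 2·min(lower tail, upper tail))). With ties or
larger n it falls back to the Student-t approximation
`t = rho * sqrt((n-2)/(1-rho^2))` on n − 2 degrees of freedom. This
exact-when-possible behaviour mirrors the default of standard statistical
environments, which matters for reproducing reported values: in the
reference design the DAS28 covariate is tie-free (exact path) while
disease duration carries a tie at 76 months (t path). Healthy donors carry
no clinical covariates and are excluded from correlations automatically.

# Stimulation arm

The stimulation analysis re-clusters all stimulated and control samples at
k = 100 on the 20-marker subset, annotates with the CD64 rule variant, and
isolates monocytes, cDCs and pDCs. Cytokine positivity (MIP-1β, TNF-α,
IL-8) is gated at the 99th percentile of the matched population in the
same patient's PBS control, falling back to the pooled control when the
per-sample population has fewer than 100 cells; control samples therefore
score ≈1 % positive by construction. Responses are compared with the same
permutation machinery: stimulated vs control per population and cytokine,
and RA vs healthy among stimulated samples.

# The synthetic cohort generator

The generator emulates the measured structure the pipeline assumes, with
every parameter explicit:

* Eight major populations at blood-norm fractions (neutrophils 55 %,
  T-cells 25 %, monocytes 8 %, B and NK 5 % each, cDC 1 %, pDC and
  basophils 0.5 % each), each defined by arcsinh-scale marker modes on the
  annotation markers (e.g. neutrophils CD66/CD16/CD11b high; the planted
  neutrophil subset identical except CD11b low, CD16 very high).
* Marker noise is Gaussian (SD 0.35) on the arcsinh scale, truncated at
  zero by redraw; unexpressed markers sit at a zero-inflated background
  mode (mean 0.3, 40 % exact zeros), reflecting the strong zero inflation
  of mass cytometry. Exact zeros are reserved for the inflation mask so
  the zero rate is testable.
* The neutrophil subset's within-neutrophil fraction follows a logit-linear
  link in disease duration (intercept logit 0.30, slope 0.6 per ~80
  months, noise SD 0.2), with healthy samples fixed at 9.2 %. The T-cell
  subset is present per patient with probability 5/9 (reproducing the
  observed bimodal patient split) and follows a negative logit link in
  DAS28, with a 3 % healthy baseline.
* Each sample receives a Gaussian batch shift (SD 0.05) on every marker.
* Under TLR stimulation, 40 % of monocyte/cDC/pDC cells are responders
  whose cytokine channels shift upward by 4 noise-SDs; responder cytokine
  production overrides zero inflation (a producing cell is not null).
* The clinical table ships as a fixed 9-patient reference fixture
  (durations 28–304 months, DAS28 1.89–6.85, treatment and serology
  flags); sampled mode draws from the fixture's ranges and empirical
  frequencies for other cohort sizes.
* Per-sample depth defaults to 10,000 cells — absolute yields are
  unreported in the motivating study, so this is a desk-scale choice that
  keeps binomial noise on a 10–30 % subpopulation well under one
  percentage point.

What the generator does *not* emulate: bead events, doublets, acquisition
drift, isotope spillover, and ion-count (Poisson) noise — data are
generated directly on the transformed scale. Passing tests therefore
demonstrate that the pipeline recovers structure of this statistical form;
they do not certify behaviour under instrument artefacts that upstream QC
normally removes.

# Numerical choices and degenerate inputs

* All clustering distances are L1; categorization/heatmap ordering uses
  Euclidean distance on category vectors.
* Upsampling ties break toward the lower cluster id; category bins are
  left-closed with a closed last bin; boundary cells of polygons count as
  inside — every tie rule is stated and tested.
* A degenerate marker range (5th = 95th percentile) maps in-range values
  to the middle category.
* Exact permutation counts compare statistics with a relative 1e-12
  tolerance so floating-point noise cannot drop the identity relabeling.
* Seeds: one master seed expands into per-stage seeds by fixed offsets
  (`derive_seed`), so any stage reruns in isolation with identical output.

# Problem sizes used in validation

The shipped validation runs the full 9 + 5 cohort at 10,000 cells per
sample with a 100-cluster tree (the tree size scaled down from the
reference 500 — at 100 clusters every major population still maps to many
clusters, and cluster purity, not count, drives the checks), and the
stimulation arm at 3,000 cells per sample with its standard k = 100.
Embeddings in examples use a few hundred cells per sample, matching the
quadratic cost of exact t-SNE gradients.

# Known limitations

* Exact t-SNE limits embeddings to tens of thousands of cells; the
  quantification path (marker-rule areas) is independent of the embedding,
  so scale limits affect visualization only.
* FCS support covers 3.0/3.1 list mode with float, double or
  fixed-width-integer data — not FCS 2.0, analysis segments, compensation
  or GatingML.
* Annotation rules are fixed decision lists; they encode the reference
  marker logic and are not learned from data.
* The permutation test conditions on group sizes; with 9 + 5 samples the
  smallest attainable p is 1/2002, and per-cluster tests are reported
  uncorrected by default.
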