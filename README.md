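# cytoforge

Differential leukocyte subpopulation discovery from mass cytometry
(CyTOF) cohorts.

Whole-blood immunophenotyping studies compare leukocytes of patients and
healthy donors across ~33 protein markers measured per cell. The questions
such a design asks are structural: which cell clusters shift in abundance
with disease, do the shifted clusters form a coherent subpopulation with a
nameable phenotype, does that subpopulation track clinical covariates, and
is innate immune function (cytokine production after TLR stimulation)
altered? cytoforge implements that analysis chain end to end for
case/control designs such as a rheumatoid-arthritis (RA) cohort of nine
treated patients and five healthy donors, and ships a synthetic cohort
generator with planted ground truth so every stage is testable.

The stages, each a tidyverse-style function over tibbles:

1. **I/O** — FCS 3.0/3.1 and CSV samples; `asinh(x / c)` transform
   (cofactor c = 5 by default).
2. **SPADE-style clustering** — per-cell L1 density, density-dependent
   downsampling to an expected 5 % (retain probability
   `min(1, TD / density)` with TD solved by bisection), average-linkage
   agglomerative clustering of the pooled downsampled cells cut at k
   clusters (k = 500 main arm, k = 100 stimulation arm), minimum spanning
   tree over cluster medians, nearest-median upsampling of all cells.
3. **Categorical phenotyping** — per-marker 5th–95th percentile ranges
   split into five uniform categories (negative…bright); a cluster's
   category bins the mean over samples of its per-(cluster, sample)
   medians; rule-based annotation to cell types over CD3, CD11c, CD14,
   CD16, CD19, CD66, CD123, Granzyme B, HLADR.
4. **Differential abundance** — per-cluster enrichment trend by group
   means and an exact group-label permutation test on per-sample abundance
   fractions (statistic `|mean_RA − mean_healthy|`, all C(14, 9) = 2002
   relabelings enumerated).
5. **Subpopulation quantification** — isolate an annotated population,
   embed with t-SNE on the defining markers, delineate areas as polygons
   or marker rules, report per-sample and pooled area percentages and
   per-area mean signal intensity (MSI) with permutation tests.
6. **Clinical correlation** — Spearman rank correlation with the exact
   n!-enumeration p-value when tie-free and n ≤ 10, otherwise the
   Student-t approximation `t = ρ√((n−2)/(1−ρ²))`.
7. **Stimulation response** — percent cytokine-positive cells
   (MIP-1β, TNF-α, IL-8) per population, gated at the 99th percentile of
   the matched PBS control, compared stimulated-vs-control and
   RA-vs-healthy.

## Worked example

Simulate a cohort with the planted CD11b-low CD16-high neutrophil subset,
cluster, annotate, quantify the subset with the shipped marker-rule area,
and correlate it with disease duration:

```r
library(cytoforge)

co   <- simulate_cohort(cohort_spec(cells_per_sample = 2000, seed = 1))
tree <- spade_tree(co$samples,
                   markers = clustering_markers(co$panel, "all33"),
                   k = 60, seed = 2)
ann  <- annotate_clusters(categorize_clusters(tree, marker_ranges(tree$events)))

neut <- isolate_population(tree, ann, "neutrophil")
neut <- assign_areas(neut, default_area_rules("neutrophil"))
(st  <- area_percentages(neut, mode = "exact"))
#> <area_stats>
#> pooled percentages:
#> # A tibble: 4 × 4
#>   group   area       n percentage
#>   <chr>   <chr>  <int>      <dbl>
#> 1 RA      Area 2  2943      30.4
#> 2 RA      rest    6746      69.6
#> 3 healthy Area 2   405       7.50
#> 4 healthy rest    4992      92.5
#> RA vs healthy permutation p per area:
#> # A tibble: 2 × 2
#>   area   p_value
#>   <chr>    <dbl>
#> 1 Area 2 0.00200
#> 2 rest   0.00200

a2 <- subset(st$per_sample, area == "Area 2")
correlate_abundance(tibble::tibble(patient = a2$sample_id,
                                   value = a2$percentage),
                    co$clinical, "duration_months")
#> Spearman correlation: rho = 0.954, p = 6.579e-05 (t_approximation, ties, n = 9)
```

Reading: about 30 % of RA neutrophils but only 7.5 % of healthy-donor
neutrophils fall in the CD11b-low CD16-high area ("Area 2"); the exact
permutation test puts the group difference at p = 0.002; and the
per-sample subset share rises strongly with disease duration (the
t-approximation is used because the duration column contains a tie).
`run_pipeline(pipeline_config(...))` chains all stages and writes
per-stage CSV outputs plus a log.

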