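# Population isolation, embedding, area assignment, area percentages, MSI.

test_that("isolation partitions cells by annotation", {
  tr <- small_tree()
  ann <- small_annotation()$annotation
  total <- 0
  for (ct in unique(ann$cell_type)) {
    total <- total + nrow(isolate_population(tr, ann, ct))
  }
  expect_equal(total, nrow(tr$events))
  one_label <- tibble::tibble(cluster = ann$cluster, cell_type = "x")
  expect_equal(nrow(isolate_population(tr, one_label, "x")),
               nrow(tr$events))
  expect_error(isolate_population(tr, ann, "astrocyte"),
               class = "cytoforge_empty_selection")
})

test_that("isolated neutrophils match ground truth", {
  tr <- small_tree()
  ann <- small_annotation()$annotation
  neut <- isolate_population(tr, ann, "neutrophil")
  truth_is_neut <- neut$.population %in% c("neutrophil",
                                           "neutrophil_cd11b_low")
  expect_gt(mean(truth_is_neut), 0.95)
})

test_that("the embedding preserves blob separation and is deterministic", {
  ev <- blob_events(120, n_markers = 2, delta = 8, seed = 13)
  emb <- embed_cells(ev, c("M1", "M2"), n_per_sample = 120,
                     perplexity = 15, iterations = 300, seed = 4)
  expect_equal(nrow(emb), 240)
  expect_true(all(is.finite(emb$tsne1)) && all(is.finite(emb$tsne2)))
  emb2 <- embed_cells(ev, c("M1", "M2"), n_per_sample = 120,
                      perplexity = 15, iterations = 300, seed = 4)
  expect_identical(emb$tsne1, emb2$tsne1)
  # silhouette of the ground-truth labels on the embedding
  xy <- cbind(emb$tsne1, emb$tsne2)
  lab <- emb$.blob
  dm <- as.matrix(dist(xy))
  sil <- vapply(seq_len(nrow(xy)), function(i) {
    same <- setdiff(which(lab == lab[i]), i)
    a <- mean(dm[i, same])
    b <- mean(dm[i, lab != lab[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
  expect_error(embed_cells(ev, character(0)), "nonempty")
  expect_error(embed_cells(ev[1:20, ], c("M1", "M2"), n_per_sample = 20,
                           perplexity = 30), "too few|perplexity")
})

test_that("every sample contributes equally to the embedding", {
  co <- small_cohort()
  ev <- dplyr::bind_rows(co$samples[c("PAT-1", "PAT-2", "HD-1")])
  emb <- embed_cells(ev, c("CD11b", "CD16"), n_per_sample = 100,
                     perplexity = 10, iterations = 120, seed = 2)
  expect_true(all(table(emb$.sample_id) == 100))
})

test_that("polygon areas honour the boundary-inside convention", {
  ev <- tibble::tibble(tsne1 = c(0.5, 2, 0, 1, 5),
                       tsne2 = c(0.5, 2, 0, 0, 5),
                       .sample_id = "s")
  sq <- area_polygon("A", c(0, 1, 1, 0), c(0, 0, 1, 1))
  out <- assign_areas(ev, list(sq))
  # interior, outside, vertex, edge midpoint, far outside
  expect_equal(out$.area, c("A", "rest", "A", "A", "rest"))
  all_plane <- area_polygon("everything", c(-100, 100, 100, -100),
                            c(-100, -100, 100, 100))
  out2 <- assign_areas(ev, list(all_plane))
  expect_true(all(out2$.area == "everything"))
  # overlapping polygons are rejected with the offending pair
  sq2 <- area_polygon("B", c(0.4, 2, 2, 0.4), c(0.4, 0.4, 2, 2))
  expect_error(assign_areas(ev, list(sq, sq2)), "'A' and 'B'",
               class = "cytoforge_area_error")
  expect_error(area_polygon("x", 1:2, 1:2), "3")
})

test_that("the marker rule captures the planted subpopulation", {
  spec <- cohort_spec(cells_per_sample = 10000, seed = 19)
  s <- simulate_sample(spec, simulate_clinical(9)[5, ], seed = 20)
  ev <- s$events[s$events$.population %in%
                   c("neutrophil", "neutrophil_cd11b_low"), ]
  out <- assign_areas(ev, default_area_rules("neutrophil"))
  truth <- ev$.population == "neutrophil_cd11b_low"
  sens <- mean(out$.area[truth] == "Area 2")
  spec_ <- mean(out$.area[!truth] == "rest")
  expect_gt(sens, 0.9)
  expect_gt(spec_, 0.9)
  expect_error(assign_areas(ev, list(area_rule("x", NOPE = c(">=", 1)))),
               "unknown marker")
  expect_error(area_rule("x"), "at least one")
})

test_that("area percentages sum to 100 and recover planted levels", {
  tr <- small_tree()
  ann <- small_annotation()$annotation
  co <- small_cohort()
  neut <- isolate_population(tr, ann, "neutrophil")
  neut <- assign_areas(neut, default_area_rules("neutrophil"))
  st <- area_percentages(neut, mode = "exact")
  sums <- tapply(st$per_sample$percentage, st$per_sample$sample_id, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  # planted within-neutrophil fractions recovered within 3 points
  a2 <- st$per_sample[st$per_sample$area == "Area 2", ]
  truth <- co$truth[co$truth$subpopulation == "neutrophil_cd11b_low", ]
  cmp <- dplyr::inner_join(a2, truth, by = c(sample_id = "patient"))
  expect_true(all(abs(cmp$percentage / 100 - cmp$planted_fraction) < 0.03))
  # planted RA excess is detected
  expect_lt(st$tests$p_value[st$tests$area == "Area 2"], 0.05)
})

test_that("a single area yields 100 percent everywhere with p = 1", {
  ev <- tibble::tibble(tsne1 = rnorm(40), tsne2 = rnorm(40),
                       .sample_id = rep(c("r", "h"), 20),
                       .group = rep(c("RA", "healthy"), 20))
  ev <- assign_areas(ev, list(area_polygon("all", c(-9, 9, 9, -9),
                                           c(-9, -9, 9, 9))))
  st <- area_percentages(ev, mode = "exact")
  expect_true(all(st$per_sample$percentage == 100))
  expect_equal(st$tests$p_value, 1)
})

test_that("zero-cell samples are excluded with a warning", {
  ev <- tibble::tibble(CD11b = rnorm(10, 4), CD16 = rnorm(10, 4),
                       .sample_id = "present", .group = "RA")
  ev <- assign_areas(ev, default_area_rules("neutrophil"))
  expect_warning(area_percentages(ev, expected_samples = c("present",
                                                           "absent")),
                 "absent")
})

test_that("MSI separates areas and respects the sample unit", {
  co <- small_cohort()
  tr <- small_tree()
  ann <- small_annotation()$annotation
  neut <- isolate_population(tr, ann, "neutrophil")
  neut <- assign_areas(neut, default_area_rules("neutrophil"))
  res <- compare_msi(neut, "CD11b", mode = "auto", seed = 8)
  m2 <- res$msi$msi[res$msi$area == "Area 2"]
  m1 <- res$msi$msi[res$msi$area == "rest"]
  expect_lt(m2, m1)  # planted subset is CD11b-low
  expect_lt(res$tests$p_value, 0.05)
  res16 <- compare_msi(neut, "CD16", mode = "auto", seed = 8)
  expect_gt(res16$msi$msi[res16$msi$area == "Area 2"],
            res16$msi$msi[res16$msi$area == "rest"])
  expect_error(compare_msi(neut, "NOPE"), "unknown marker")
})

test_that("identical areas give equal MSI and p = 1", {
  base <- tibble::tibble(M = rnorm(30), .sample_id = rep(c("a", "b"), 15))
  dup <- dplyr::bind_rows(base, base)
  dup$.area <- rep(c("x", "y"), each = 30)
  res <- compare_msi(dup, "M", mode = "exact")
  expect_equal(res$msi$msi[1], res$msi$msi[2])
  expect_equal(res$tests$p_value, 1)
  const <- dup
  const$M <- 7
  res2 <- compare_msi(const, "M", mode = "exact")
  expect_true(all(res2$msi$msi == 7))
})
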