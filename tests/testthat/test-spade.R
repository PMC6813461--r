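# Density estimation, density-dependent downsampling, agglomerative
# clustering, MST construction, upsampling, and abundance tables.

test_that("coincident cells count each other in the density", {
  ev <- tibble::tibble(M1 = c(1, 1), M2 = c(2, 2))
  d <- estimate_density(ev, c("M1", "M2"))
  expect_equal(d$density, c(2, 2))
  expect_error(estimate_density(ev[1, ], c("M1", "M2")), "at least 2")
  expect_error(estimate_density(ev, character(0)), "nonempty")
})

test_that("dense regions score higher density than sparse ones", {
  set.seed(8)
  grid <- expand.grid(M1 = seq(0, 30, by = 3), M2 = seq(0, 30, by = 3))
  blob <- data.frame(M1 = rnorm(120, 50, 0.5), M2 = rnorm(120, 50, 0.5))
  ev <- tibble::as_tibble(rbind(grid, blob))
  d <- estimate_density(ev, c("M1", "M2"), seed = 2)
  is_blob <- seq_len(nrow(ev)) > nrow(grid)
  expect_gt(mean(d$density[is_blob]), mean(d$density[!is_blob]))
})

test_that("density is invariant under marker permutation", {
  ev <- blob_events(60, n_markers = 4)
  d1 <- estimate_density(ev, c("M1", "M2", "M3", "M4"), seed = 1)
  d2 <- estimate_density(ev, c("M4", "M2", "M1", "M3"), seed = 1)
  expect_equal(d1$density, d2$density)
})

test_that("downsampling hits the target fraction and equalizes density", {
  co <- small_cohort()
  ev <- dplyr::bind_rows(co$samples[c("PAT-1", "PAT-2")])  # bimodal pool
  ev <- head(ev, 2500)
  mk <- clustering_markers(co$panel, "all33")
  ev$.row <- seq_len(nrow(ev))
  d <- estimate_density(ev, mk, seed = 1)
  sub <- downsample_events(ev, d, 0.2, seed = 2)
  expect_lt(abs(nrow(sub) / nrow(ev) - 0.2), 0.05)
  expect_identical(downsample_events(ev, d, 1), ev)
  expect_error(downsample_events(ev, d, 0), "target_fraction")
  expect_error(downsample_events(ev, d, 1.5), "target_fraction")
})

test_that("downsampling equalizes density on a bimodal fixture", {
  set.seed(6)
  ev <- tibble::tibble(M1 = c(rnorm(4000, 0, 0.3), runif(1000, 5, 50)),
                       M2 = c(rnorm(4000, 0, 0.3), runif(1000, 5, 50)))
  ev$.row <- seq_len(nrow(ev))
  d <- estimate_density(ev, c("M1", "M2"), seed = 3)
  sub <- downsample_events(ev, d, 0.2, seed = 4)
  idx <- sub$.row
  expect_lt(stats::var(log(d$density[idx])), stats::var(log(d$density)))
  # local density of the retained cloud (same kernel radius) is more even
  d_after <- cytoforge:::cpp_l1_density(event_matrix(sub, c("M1", "M2")),
                                        d$radius)
  gini <- function(x) {
    x <- sort(x)
    n <- length(x)
    2 * sum(seq_len(n) * x) / (n * sum(x)) - (n + 1) / n
  }
  expect_lt(gini(d_after), gini(d$density))
})

test_that("the expected retained fraction solves to five percent", {
  set.seed(4)
  # strongly bimodal density profile at 20k cells
  ev <- tibble::tibble(M1 = c(rnorm(16000, 0, 0.3), runif(4000, 5, 50)),
                       M2 = c(rnorm(16000, 0, 0.3), runif(4000, 5, 50)))
  d <- estimate_density(ev, c("M1", "M2"), seed = 3)
  fractions <- vapply(1:5, function(s) {
    nrow(downsample_events(ev, d, 0.05, seed = s)) / nrow(ev)
  }, numeric(1))
  expect_true(all(fractions >= 0.045 & fractions <= 0.055))
})

test_that("clustering separable blobs recovers the ground truth", {
  ev <- blob_events(150, n_markers = 3, delta = 10)
  fit <- cluster_cells(ev, c("M1", "M2", "M3"), k = 2)
  tab <- table(fit$assignment, ev$.blob)
  purity <- sum(apply(tab, 1, max)) / nrow(ev)
  expect_equal(purity, 1)
})

test_that("k equal to cell count gives singleton clusters", {
  ev <- blob_events(5, n_markers = 2)
  fit <- cluster_cells(ev, c("M1", "M2"), k = nrow(ev))
  expect_equal(sort(unique(fit$assignment)), seq_len(nrow(ev)))
  for (i in seq_len(nrow(ev))) {
    expect_equal(unname(fit$medians[fit$assignment[i], ]),
                 c(ev$M1[i], ev$M2[i]))
  }
  expect_error(cluster_cells(ev, c("M1", "M2"), k = nrow(ev) + 1),
               "exceeds")
})

test_that("MST avoids long edges on collinear points", {
  med <- matrix(c(0, 1, 10), ncol = 1, dimnames = list(c("1", "2", "3")))
  mst <- build_mst(med)
  edges <- paste(pmin(mst$from, mst$to), pmax(mst$from, mst$to))
  # points at 0, 1, 10: edges (0-1) and (1-10), never the long (0-10)
  expect_setequal(edges, c("1 2", "2 3"))
  expect_equal(sum(mst$weight), 10)
})

test_that("MST weight equals the exhaustive minimum for small k", {
  # oracle: enumerate all spanning trees via Prufer sequences
  prufer_tree_edges <- function(seq_codes, k) {
    degree <- rep(1L, k)
    for (s in seq_codes) degree[s] <- degree[s] + 1L
    edges <- matrix(0L, nrow = k - 1, ncol = 2)
    ptr <- 1
    deg <- degree
    for (i in seq_along(seq_codes)) {
      leaf <- which(deg == 1L)[1]
      edges[i, ] <- c(leaf, seq_codes[i])
      deg[leaf] <- 0L
      deg[seq_codes[i]] <- deg[seq_codes[i]] - 1L
    }
    edges[k - 1, ] <- which(deg == 1L)
    edges
  }
  for (k in c(4, 5, 6)) {
    set.seed(k)
    med <- matrix(rnorm(k * 3), nrow = k,
                  dimnames = list(as.character(seq_len(k)), NULL))
    dmat <- as.matrix(dist(med, method = "manhattan"))
    codes <- as.matrix(expand.grid(rep(list(seq_len(k)), k - 2)))
    best <- Inf
    for (r in seq_len(nrow(codes))) {
      e <- prufer_tree_edges(codes[r, ], k)
      best <- min(best, sum(dmat[e]))
    }
    mst <- build_mst(med)
    expect_equal(sum(mst$weight), best, tolerance = 1e-10)
  }
})

test_that("MST is a spanning tree for random k", {
  for (k in c(10, 47, 100)) {
    set.seed(k)
    med <- matrix(rnorm(k * 4), nrow = k,
                  dimnames = list(as.character(seq_len(k)), NULL))
    mst <- build_mst(med)
    expect_equal(nrow(mst), k - 1)
    g <- igraph::graph_from_data_frame(mst, directed = FALSE)
    expect_true(igraph::is_connected(g))
    expect_equal(igraph::vcount(g), k)
  }
  expect_error(build_mst(matrix(0, 2, 1,
                                dimnames = list(c("a", "a"), NULL))),
               "duplicate")
})

test_that("upsampling assigns to the nearest median with the tie rule", {
  med <- matrix(c(0, 0, 4, 4, 2, 2), ncol = 2, byrow = TRUE,
                dimnames = list(NULL, c("M1", "M2")))
  ev <- tibble::tibble(M1 = c(0, 4, 2, 1), M2 = c(0, 4, 2, 1))
  # cell 4 at (1,1): L1 distances 2 (cluster 1), 6 (cluster 2), 2 (cluster 3)
  got <- upsample_cells(ev, med, c("M1", "M2"))
  expect_equal(got, c(1L, 2L, 3L, 1L))  # tie resolves to lower id
})

test_that("downsampled cells keep their cluster after upsampling", {
  ev <- blob_events(200, n_markers = 3, delta = 10)
  fit <- cluster_cells(ev, c("M1", "M2", "M3"), k = 2)
  up <- upsample_cells(ev, fit$medians, c("M1", "M2", "M3"))
  expect_equal(up, unname(fit$assignment))
})

test_that("abundance fractions count correctly and normalize", {
  ev <- tibble::tibble(.sample_id = rep("s", 10),
                       .cluster = rep(1L, 10))
  ab <- cluster_abundance(ev, k = 1)
  expect_true(all(ab$fraction == 1))
  ev2 <- tibble::tibble(.sample_id = rep("s", 100),
                        .cluster = rep(c(1L, 2L), c(30, 70)))
  ab2 <- cluster_abundance(ev2, k = 2)
  expect_equal(ab2$fraction[order(ab2$cluster)], c(0.3, 0.7))
  set.seed(1)
  ev3 <- tibble::tibble(.sample_id = sample(letters[1:4], 500, TRUE),
                        .cluster = sample.int(7, 500, TRUE))
  ab3 <- cluster_abundance(ev3, k = 9)
  sums <- tapply(ab3$fraction, ab3$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_equal(nrow(ab3), 4 * 9)  # empty clusters retained at zero
})

test_that("the full stage is deterministic under a fixed seed", {
  co <- small_cohort()
  sub <- co$samples[c("PAT-1", "HD-1")]
  mk <- clustering_markers(co$panel, "annotation9")
  t1 <- spade_tree(sub, mk, k = 12, seed = 5)
  t2 <- spade_tree(sub, mk, k = 12, seed = 5)
  expect_identical(t1$events$.cluster, t2$events$.cluster)
  expect_identical(t1$mst, t2$mst)
  expect_identical(t1$abundance, t2$abundance)
  expect_equal(glance(t1)$k, 12)
  expect_equal(nrow(tidy(t1)), 12 * 2)
})
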