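# Shared fixtures, built once per test run and memoized. The small cohort
# keeps the full 9 RA + 5 healthy layout but at reduced per-sample depth so
# unit tests stay fast; depth-sensitive checks build their own samples.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

small_cohort <- function() {
  memo("small_cohort", function() {
    simulate_cohort(cohort_spec(cells_per_sample = 1500, seed = 7L))
  })
}

small_tree <- function() {
  memo("small_tree", function() {
    co <- small_cohort()
    spade_tree(co$samples,
               markers = clustering_markers(co$panel, "all33"),
               k = 60, seed = 3L)
  })
}

small_annotation <- function() {
  memo("small_annotation", function() {
    tr <- small_tree()
    cats <- categorize_clusters(tr, marker_ranges(tr$events))
    list(categories = cats, annotation = annotate_clusters(cats))
  })
}

# two well-separated Gaussian blobs in marker space
blob_events <- function(n_per_blob = 100, n_markers = 3, delta = 10,
                        sd = 1, seed = 5L) {
  set.seed(seed)
  m <- rbind(
    matrix(rnorm(n_per_blob * n_markers, 0, sd), ncol = n_markers),
    matrix(rnorm(n_per_blob * n_markers, delta * sd, sd), ncol = n_markers)
  )
  colnames(m) <- paste0("M", seq_len(n_markers))
  ev <- tibble::as_tibble(m)
  ev$.sample_id <- rep(c("s1", "s2"), n_per_blob)
  ev$.blob <- rep(c(1L, 2L), each = n_per_blob)
  cytoforge:::set_events_transform(ev, "arcsinh", 5)
}

raw_events <- function(n = 50, markers = c("CD3", "CD16"), seed = 1L,
                       sample_id = "s1") {
  set.seed(seed)
  m <- matrix(runif(n * length(markers), 0, 500), ncol = length(markers),
              dimnames = list(NULL, markers))
  ev <- tibble::as_tibble(m)
  ev$.sample_id <- sample_id
  cytoforge:::set_events_transform(ev, "raw")
}

# all permutations of 1..n (test-side oracle for exact rank statistics)
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-i]
      out[row, ] <- c(i, rest[sub[j, ]])
      row <- row + 1
    }
  }
  out
}
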