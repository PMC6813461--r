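# Reading, writing, transforming and combining samples.

test_that("FCS write/read round-trips values and names", {
  ev <- raw_events(100, c("CD3", "HLADR", "GranzymeB"))
  path <- withr::local_tempfile(fileext = ".fcs")
  write_events(ev, path)
  back <- read_events(path, sample_id = "s1")
  expect_identical(marker_cols(back), marker_cols(ev))
  rel <- abs(event_matrix(back) - event_matrix(ev)) /
    (abs(event_matrix(ev)) + 1e-12)
  expect_lt(max(rel), 1e-6)
  # re-read data is float-exact on rewrite
  path2 <- withr::local_tempfile(fileext = ".fcs")
  write_events(back, path2)
  expect_identical(event_matrix(read_events(path2)), event_matrix(back))
})

test_that("CSV fallback parses verbatim and round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("CD3,CD16", "0,1", "2,3", "4,5"), path)
  ev <- read_events(path)
  expect_equal(unname(event_matrix(ev)),
               matrix(c(0, 2, 4, 1, 3, 5), ncol = 2))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, path2)
  expect_equal(event_matrix(read_events(path2)), event_matrix(ev))
})

test_that("marker names fall back from $PnS to $PnN", {
  # hand-built minimal FCS 3.0 with $P2S absent (reader oracle fixture)
  path <- withr::local_tempfile(fileext = ".fcs")
  d <- "/"
  kw <- c("$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
          "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
          "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
          "$NEXTDATA" = "0", "$PAR" = "2", "$TOT" = "2",
          "$P1N" = "ch1", "$P1S" = "CD3_stain", "$P1B" = "32",
          "$P1E" = "0,0", "$P1R" = "10",
          "$P2N" = "CD16", "$P2B" = "32", "$P2E" = "0,0", "$P2R" = "10")
  text <- paste0(d, paste0(names(kw), d, unname(kw), d, collapse = ""))
  text_beg <- 58
  text_end <- text_beg + nchar(text) - 1
  data_beg <- text_end + 1
  data_end <- data_beg + 4 * 4 - 1
  con <- file(path, "wb")
  writeChar(sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d", text_beg, text_end,
                    data_beg, data_end, 0, 0), con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(c(1, 2, 3, 4), con, size = 4, endian = "little")
  close(con)
  ev <- read_events(path)
  expect_identical(marker_cols(ev), c("CD3_stain", "CD16"))
  expect_equal(unname(event_matrix(ev)),
               matrix(c(1, 3, 2, 4), ncol = 2))
})

test_that("malformed or mismatched files raise informative errors", {
  path <- withr::local_tempfile(fileext = ".fcs")
  writeBin(charToRaw("FCS9.9 not a real file padding padding padding padding padd"),
           path)
  expect_error(read_events(path), "unsupported version",
               class = "cytoforge_format_error")
  ev <- raw_events(10, c("CD3", "CD16"))
  good <- withr::local_tempfile(fileext = ".fcs")
  write_events(ev, good)
  expect_error(read_events(good, panel = default_panel()),
               "missing panel marker", class = "cytoforge_panel_error")
  expect_error(write_events(ev[, ".sample_id", drop = FALSE], good),
               "no markers")
  expect_error(write_events(ev, "/nonexistent-dir/x.csv"))
})

test_that("arcsinh transform matches the closed form and is stateful", {
  ev <- raw_events(10)
  tr <- asinh_events(ev, cofactor = 5)
  expect_equal(event_matrix(tr), asinh(event_matrix(ev) / 5))
  ev0 <- ev
  ev0$CD3 <- 0
  expect_equal(asinh_events(ev0, 3)$CD3, rep(0, 10))
  x <- tibble::tibble(CD3 = 5)
  x <- cytoforge:::set_events_transform(x, "raw")
  expect_equal(asinh_events(x, 5)$CD3, 0.8813735870, tolerance = 1e-9)
  # strictly increasing
  v <- sort(runif(50, 0, 100))
  ev2 <- cytoforge:::set_events_transform(tibble::tibble(CD3 = v), "raw")
  expect_true(all(diff(asinh_events(ev2, 5)$CD3) > 0))
  expect_error(asinh_events(tr, 5), "already")
  expect_error(asinh_events(ev, -1), "positive")
})

test_that("concatenation stacks rows with provenance and checks state", {
  s1 <- raw_events(10, sample_id = "a", seed = 1)
  s2 <- raw_events(20, sample_id = "b", seed = 2)
  s3 <- raw_events(30, sample_id = "c", seed = 3)
  all3 <- bind_samples(list(s1, s2, s3))
  expect_equal(nrow(all3), 60)
  expect_equal(as.vector(table(all3$.sample_id)[c("a", "b", "c")]),
               c(10, 20, 30))
  # single sample passes through with provenance
  one <- bind_samples(s1)
  expect_equal(nrow(one), 10)
  expect_true(all(one$.sample_id == "a"))
  # per-sample medians unchanged by concatenation order
  med_before <- apply(event_matrix(s2), 2, median)
  shuffled <- bind_samples(list(s3, s1, s2))
  med_after <- apply(event_matrix(shuffled[shuffled$.sample_id == "b", ]),
                     2, median)
  expect_equal(med_after, med_before)
  # associativity on the (provenance, row) multiset
  ab_c <- bind_samples(list(bind_samples(list(s1, s2)), s3))
  a_bc <- bind_samples(list(s1, bind_samples(list(s2, s3))))
  key <- function(x) {
    k <- paste(x$.sample_id, x$CD3, x$CD16)
    sort(k)
  }
  expect_identical(key(ab_c), key(a_bc))
  mixed <- asinh_events(s2, 5)
  expect_error(bind_samples(list(s1, mixed)),
               class = "cytoforge_state_error")
})

test_that("equal subsampling clamps, reproduces, and is unbiased", {
  samples <- list(raw_events(100, seed = 1), raw_events(200, seed = 2),
                  raw_events(50, seed = 3))
  out <- subsample_equal(samples, 60, seed = 9)
  expect_equal(vapply(out, nrow, integer(1)), rep(50L, 3))
  out2 <- subsample_equal(samples, 60, seed = 9)
  expect_identical(out, out2)
  expect_error(subsample_equal(samples, 0), "positive")
  # without replacement: no duplicated rows within a sample
  big <- raw_events(2000, seed = 4)
  sub <- subsample_equal(list(big), 1000, seed = 1)[[1]]
  expect_equal(anyDuplicated(sub), 0L)
  # subsample mean within 3 SE of source mean
  for (m in marker_cols(big)) {
    se <- stats::sd(big[[m]]) / sqrt(1000)
    expect_lt(abs(mean(sub[[m]]) - mean(big[[m]])), 3 * se)
  }
})

test_that("panel validates structure and ships the documented sets", {
  p <- default_panel()
  expect_equal(nrow(p), 33)
  expect_setequal(clustering_markers(p, "stim20"),
                  c("CD3", "CD11a", "CD11b", "CD11c", "CD14", "CD16",
                    "CD19", "CD23", "CD28", "CD32", "CD64", "CD66", "CD86",
                    "CD123", "CCR5", "CXCR4", "GranzymeB", "Perforin",
                    "TLR2", "HLADR"))
  expect_length(clustering_markers(p, "annotation9"), 9)
  expect_true(all(clustering_markers(p, "stim20") %in% p$marker))
  expect_error(marker_panel(c("a", "a"), c("x", "y"),
                            rep("extracellular", 2)), "unique")
  expect_error(marker_panel("a", "x", "extracellular",
                            list(bad = "zz")), "unknown marker")
  expect_error(marker_panel(character(0), character(0), character(0)),
               "at least one")
})

test_that("the shipped panel and clinical fixtures load", {
  panel_path <- system.file("extdata", "panel_33.csv",
                            package = "cytoforge")
  p <- read_panel(panel_path)
  expect_equal(nrow(p), 33)
  expect_setequal(clustering_markers(p, "stim20"),
                  clustering_markers(default_panel(), "stim20"))
  clin_path <- system.file("extdata", "clinical_table1.csv",
                           package = "cytoforge")
  clin <- read_clinical(clin_path)
  expect_equal(clin$duration_months, simulate_clinical(9)$duration_months)
  expect_equal(clin$das28, simulate_clinical(9)$das28)
  expect_error(read_clinical(panel_path), "missing column")
})
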