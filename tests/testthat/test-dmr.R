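test_that("no seed windows means an empty DMR set", {
  w <- hand_windows()
  res <- hand_results(w, p = 0.5)
  dmrs <- call_dmrs(res, w)
  expect_s3_class(dmrs, "dmr_set")
  expect_equal(nrow(dmrs), 0)
})

test_that("edges extend into sub-threshold neighbors only", {
  w <- hand_windows()
  res <- hand_results(w, p = 0.5)
  res$p_value[11] <- 5e-7   # seed at [10000,11000)
  res$p_value[10] <- 0.05   # absorbable neighbor [9000,10000)
  res$log2fc[11] <- 1.5
  dmrs <- call_dmrs(res, w)
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$start, 9000L)
  expect_equal(dmrs$end, 11000L)
  expect_equal(dmrs$sig_windows, 1L)
  expect_equal(dmrs$n_windows, 2L)
  expect_equal(dmrs$direction, "increase")
})

test_that("adjacent seeds merge into one multi-window DMR", {
  w <- hand_windows()
  res <- hand_results(w, p = 0.5)
  res$p_value[11:12] <- c(5e-7, 8e-6)
  res$log2fc[11:12] <- c(-2, -1)
  dmrs <- call_dmrs(res, w)
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$start, 10000L)
  expect_equal(dmrs$end, 12000L)
  expect_equal(dmrs$sig_windows, 2L)
  expect_equal(dmrs$length_kb, 2)
  expect_equal(dmrs$direction, "decrease")
})

test_that("extension iterates to a fixed point", {
  w <- hand_windows()
  res <- hand_results(w, p = 0.5)
  res$p_value[11] <- 5e-7
  res$p_value[10] <- 0.09
  res$p_value[9] <- 0.09
  res$p_value[8] <- 0.5
  dmrs <- call_dmrs(res, w)
  expect_equal(dmrs$start, 8000L)
  expect_equal(dmrs$end, 11000L)
  # single-pass mode stops after the first absorption round
  one_pass <- call_dmrs(res, w, iterate = FALSE)
  expect_equal(one_pass$start, 8000L) # both neighbors are within 1 window
})

test_that("direction comes from the minimum-p seed window", {
  w <- hand_windows()
  res <- hand_results(w, p = 0.5)
  res$p_value[5:6] <- c(1e-7, 1e-6)
  res$log2fc[5:6] <- c(1, -1)
  dmrs <- call_dmrs(res, w)
  expect_equal(dmrs$direction, "increase")
  expect_equal(dmr_direction(dmrs, res)$direction, "increase")
})

test_that("DMR features aggregate member windows", {
  w <- hand_windows()
  w$cpg_count <- rep(12L, nrow(w))
  res <- hand_results(w, p = 0.5, log2fc = 1)
  res$p_value[3:4] <- 1e-7
  dmrs <- call_dmrs(res, w)
  expect_equal(dmrs$cpg_count, 24L)
  expect_equal(dmrs$cpg_per_100bp, 1.2)
  stats <- dmr_feature_stats(dmrs)
  expect_equal(stats$bin[stats$feature == "cpg_per_100bp"], 1)
  expect_equal(stats$bin[stats$feature == "length_kb"], 2)
})

test_that("threshold table brackets seed p-values and is monotone", {
  w <- hand_windows()
  res <- hand_results(w, p = 0.5)
  res$p_value[5] <- 5e-6
  tt <- threshold_table(res, w)
  expect_equal(tt$all_dmrs[tt$threshold == 1e-5], 1)
  expect_equal(tt$all_dmrs[tt$threshold == 1e-6], 0)
  expect_true(all(diff(tt$all_dmrs) <= 0))
  expect_error(threshold_table(res, w, thresholds = c(1e-6, 1e-3)),
               class = "medipdmr_input_error")
  null_tt <- threshold_table(hand_results(w, p = 1), w)
  expect_true(all(null_tt$all_dmrs == 0))
})

test_that("multiwindow histogram recounts the called set", {
  w <- hand_windows()
  res <- hand_results(w, p = 0.5, log2fc = 1)
  res$p_value[c(3, 8, 9, 15)] <- 1e-7
  dmrs <- call_dmrs(res, w)
  h <- multiwindow_histogram(dmrs)
  expect_equal(sum(h$n), nrow(dmrs))
  expect_equal(h$n[h$sig_windows == 1], 2)
  expect_equal(h$n[h$sig_windows == 2], 1)
})

test_that("lowering the edge threshold never enlarges a DMR", {
  set.seed(31)
  for (i in 1:20) {
    tab <- random_result_table(80)
    loose <- call_dmrs(tab, tab, edge_threshold = 0.1)
    tight <- call_dmrs(tab, tab, edge_threshold = 0.01)
    expect_equal(nrow(tight) >= nrow(loose), TRUE)
    for (j in seq_len(nrow(tight))) {
      cover <- loose$chrom == tight$chrom[j] &
        loose$start <= tight$start[j] & loose$end >= tight$end[j]
      expect_true(any(cover))
    }
  }
})

test_that("called DMRs never overlap and contain every seed window exactly once", {
  set.seed(17)
  for (i in 1:25) {
    tab <- random_result_table(150)
    dmrs <- call_dmrs(tab, tab)
    if (nrow(dmrs) > 1) {
      by_chrom <- split(tibble::as_tibble(dmrs), dmrs$chrom)
      for (d in by_chrom) {
        d <- d[order(d$start), ]
        if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
      }
    }
    seeds <- tab$window_index[tab$p_value < 1e-5]
    membership <- unlist(dmrs$window_indices)
    expect_true(all(seeds %in% membership))
    expect_false(anyDuplicated(membership) > 0)
  }
})

test_that("the caller matches the exhaustive fixed-point oracle on random tables", {
  set.seed(23)
  for (i in 1:40) {
    tab <- random_result_table(100)
    dmrs <- call_dmrs(tab, tab)
    oracle <- oracle_call_dmrs(tab, 1e-5, 0.1, 1000)
    expect_equal(length(oracle), nrow(dmrs))
    expect_equal(unname(dmrs$window_indices), unname(oracle))
  }
})

test_that("cluster chaining joins nearby DMRs and honors min_size", {
  dmrs <- tibble::tibble(
    dmr_id = sprintf("DMR_%04d", 1:5),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    start = c(1e6, 1.8e6, 3e6, 1e6, 12e6),
    end = c(1.002e6, 1.802e6, 3.002e6, 1.002e6, 12.002e6)
  )
  cl <- find_clusters(dmrs, max_gap = 2e6, min_size = 2)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_dmrs, 3) # the three chr1 DMRs chain together
  expect_equal(nrow(find_clusters(dmrs, max_gap = 2e6, min_size = 4)), 0)
  # 10 Mb apart never clusters at 2 Mb
  far <- dmrs[4:5, ]
  expect_equal(nrow(find_clusters(far, max_gap = 2e6, min_size = 2)), 0)
  expect_equal(nrow(find_clusters(dmrs[0, ], 2e6, 2)), 0)
})

test_that("overlap of DMR sets uses the 1-bp rule and partitions both sets", {
  a <- tibble::tibble(dmr_id = c("a1", "a2"), chrom = "chr1",
                      start = c(100L, 5000L), end = c(2000L, 6000L))
  b <- tibble::tibble(dmr_id = "b1", chrom = "chr1",
                      start = 1999L, end = 3000L)
  ov <- overlap_dmr_sets(a, b)
  expect_equal(ov$counts$shared_a, 1)
  expect_equal(ov$counts$a_only, 1)
  expect_equal(ov$counts$b_only, 0)
  # identical sets: everything shared
  self <- overlap_dmr_sets(a, a)
  expect_equal(self$counts$a_only, 0)
  expect_equal(self$counts$shared_a, 2)
  # disjoint chromosomes: nothing shared
  b2 <- dplyr::mutate(b, chrom = "chr2")
  expect_equal(overlap_dmr_sets(a, b2)$counts$shared_a, 0)
})

test_that("DMR writers emit BED6 and a flat TSV", {
  w <- hand_windows()
  res <- hand_results(w, p = 0.5, log2fc = 1)
  res$p_value[5] <- 1e-8
  dmrs <- call_dmrs(res, w)
  bed <- withr::local_tempfile(fileext = ".bed")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_dmrs_bed(dmrs, bed)
  write_dmrs_tsv(dmrs, tsv)
  fields <- strsplit(readLines(bed), "\t")[[1]]
  expect_length(fields, 6)
  expect_equal(fields[6], ".")
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(back$dmr_id, dmrs$dmr_id)
})
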