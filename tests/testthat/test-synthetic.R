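small_cfg <- function(...) {
  sim_config(n_chroms = 1, chrom_length = 1e5, depth_mean = 5e3,
             n_spikes = 2, seed = 5, ...)
}

test_that("simulated genomes realize the configured CpG rates", {
  cfg <- sim_config(n_chroms = 1, chrom_length = 1e6,
                    cpg_density_profile = 2, n_spikes = 0, seed = 3)
  g <- simulate_genome(cfg)
  w <- make_windows(g, cfg$window_size)
  # rate 2 per 100 bp over 1000 windows: mean window count near 20
  expect_gt(mean(w$cpg_count), 17)
  expect_lt(mean(w$cpg_count), 23)
})

test_that("a zero CpG rate yields a CpG-free genome", {
  cfg <- sim_config(n_chroms = 1, chrom_length = 5e4,
                    cpg_density_profile = 0, n_spikes = 0, seed = 2)
  w <- make_windows(simulate_genome(cfg), cfg$window_size)
  expect_true(all(w$cpg_count == 0))
})

test_that("all generators are bit-reproducible under a fixed seed", {
  cfg <- small_cfg()
  expect_identical(as.character(simulate_genome(cfg)),
                   as.character(simulate_genome(cfg)))
  expect_identical(simulate_windows(cfg), simulate_windows(cfg))
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$truth$start_window, s2$truth$start_window)
  r1 <- counts_to_reads(s1$counts, seed = 8)
  expect_identical(r1, counts_to_reads(s2$counts, seed = 8))
})

test_that("sequence-level and counts-level window routes agree in distribution", {
  cfg <- sim_config(n_chroms = 1, chrom_length = 5e5, n_spikes = 0,
                    seed = 9)
  w_seq <- make_windows(simulate_genome(cfg), cfg$window_size)
  w_fast <- simulate_windows(cfg)
  expect_equal(dim(w_seq), dim(w_fast))
  expect_lt(abs(mean(w_seq$cpg_count) - mean(w_fast$cpg_count)), 2)
})

test_that("Poisson-mode counts have unit variance-to-mean ratio", {
  cfg <- sim_config(n_chroms = 1, chrom_length = 2e6, depth_mean = 5e4,
                    depth_cv = 0, dispersion_phi = 0, n_spikes = 0,
                    n_per_group = c(10, 10), seed = 7)
  sim <- simulate_counts(cfg)
  y <- sim$counts$counts
  ratio <- apply(y, 1, var) / pmax(rowMeans(y), 1e-9)
  # mean VMR over 2000 windows: Poisson gives 1 with SE ~ sqrt(2/(n-1))/sqrt(W)
  se <- sqrt(2 / (ncol(y) - 1)) / sqrt(nrow(y))
  expect_lt(abs(mean(ratio) - 1), 3 * se + 0.02)
})

test_that("spiked windows shift the case-group mean by the fold change", {
  folds <- vapply(1:6, function(s) {
    cfg <- sim_config(n_chroms = 1, chrom_length = 2e5, depth_mean = 1e5,
                      n_spikes = 1, spike_fold = 8, spike_sizes = 1,
                      frac_increase = 1, dispersion_phi = 0.05, seed = s)
    sim <- simulate_counts(cfg)
    wi <- sim$truth$window_indices[[1]]
    row <- match(wi, sim$counts$windows$window_index)
    grp <- sim$counts$samples$group
    mean(sim$counts$counts[row, grp == "groupB"]) /
      mean(sim$counts$counts[row, grp == "groupA"])
  }, numeric(1))
  expect_lt(abs(mean(folds) - 8), 1.5)
})

test_that("decrease spikes divide the case-group mean", {
  cfg <- sim_config(n_chroms = 1, chrom_length = 2e5, depth_mean = 2e5,
                    n_spikes = 1, spike_fold = 8, spike_sizes = 1,
                    frac_increase = 0, dispersion_phi = 0.01, seed = 4)
  sim <- simulate_counts(cfg)
  expect_equal(sim$truth$direction, "decrease")
  wi <- sim$truth$window_indices[[1]]
  row <- match(wi, sim$counts$windows$window_index)
  grp <- sim$counts$samples$group
  ratio <- mean(sim$counts$counts[row, grp == "groupB"]) /
    mean(sim$counts$counts[row, grp == "groupA"])
  expect_lt(ratio, 0.25)
})

test_that("a unit fold change is rejected", {
  expect_error(small_cfg(spike_fold = 1), class = "medipdmr_input_error")
})

test_that("counts_to_reads round-trips through midpoint counting", {
  cfg <- small_cfg()
  sim <- simulate_counts(cfg)
  reads <- counts_to_reads(sim$counts, read_length = 50, seed = 3)
  back <- count_reads(reads, sim$counts$windows,
                      samples = sim$counts$samples)
  expect_identical(back$counts, sim$counts$counts)
  expect_equal(unname(back$library_size), unname(sim$counts$library_size))
  # empty matrix gives an empty read set
  empty <- make_wc(matrix(0L, 3, 1, dimnames = list(NULL, "S1")),
                   library_size = c(S1 = 0))
  expect_equal(nrow(counts_to_reads(empty, seed = 1)), 0)
})

test_that("held-out samples are flagged and share group parameters", {
  cfg <- sim_config(n_chroms = 1, chrom_length = 1e5, depth_mean = 1e4,
                    n_test_per_group = c(2, 1), n_spikes = 1, seed = 6)
  sim <- simulate_counts(cfg)
  meta <- sim$counts$samples
  expect_equal(sum(meta$test_set), 3)
  expect_equal(sum(!meta$test_set), 12)
  expect_setequal(meta$group[meta$test_set],
                  c("groupA", "groupA", "groupB"))
})

test_that("write_simulation emits the full text dataset", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg()
  sim <- write_simulation(cfg, dir)
  expect_true(file.exists(file.path(dir, "genome.fa")))
  expect_true(file.exists(file.path(dir, "windows.tsv")))
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  meta <- readr::read_tsv(file.path(dir, "metadata.tsv"),
                          show_col_types = FALSE)
  expect_equal(nrow(meta), 12)
  beds <- list.files(file.path(dir, "reads"), pattern = "\\.bed$")
  expect_length(beds, 12)
  # reads on disk re-count to the simulated matrix
  paths <- setNames(file.path(dir, "reads", beds),
                    sub("\\.bed$", "", beds))
  reads <- read_bed_reads(paths)
  windows <- readr::read_tsv(file.path(dir, "windows.tsv"),
                             show_col_types = FALSE)
  back <- count_reads(reads, windows, samples = sim$counts$samples)
  expect_identical(back$counts[, colnames(sim$counts$counts)],
                   sim$counts$counts)
})
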