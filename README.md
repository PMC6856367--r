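# medipdmr

Window-based differential DNA methylation analysis for MeDIP-seq, in
tidyverse-native R.

MeDIP-seq uses an anti-5-methylcytosine antibody to enrich methylated
DNA fragments, so sequencing coverage over a region tracks its
methylation level. Clinical studies of sperm DNA methylation use this
assay to search for epigenetic biomarkers — signatures that separate
fertile from infertile men, or therapy responders from non-responders —
in the low-CpG-density ~95% of the genome that CpG-island arrays miss.
medipdmr implements the downstream statistics of such a study as a
reusable, fully testable pipeline:

* **Windowing** — tile a reference genome into fixed 1000-bp windows
  annotated with forward-strand CpG counts (`make_windows`,
  `count_cpg`).
* **Coverage** — count mapped-read intervals (BED) into windows by
  midpoint, equalize depths by seeded hypergeometric subsampling,
  compute RPKM (`count_reads`, `subsample_counts`, `rpkm`).
* **Differential testing** — a two-sided negative-binomial exact test
  per window, conditional on the pooled total, with a pooled
  method-of-moments common dispersion and Benjamini–Hochberg FDR
  (`test_all_windows`, `nb_exact_test`, `estimate_common_dispersion`,
  `bh_adjust`). At φ = 0 the test reduces to a conditional binomial;
  with equal library sizes it agrees with edgeR's classic exact test
  to floating-point precision.
* **DMR calling** — windows with p < 1e-5 seed differentially
  methylated regions; nearby seeds merge; edges extend iteratively to
  absorb windows with p < 0.1 within 1000 bp until a fixed point; DMRs
  carry direction (hyper/hypomethylation), CpG density and length
  features (`call_dmrs`, `threshold_table`, `multiwindow_histogram`,
  `dmr_feature_stats`, `find_clusters`, `overlap_dmr_sets`).
* **Permutation null** — the full analysis re-run under random
  group-size-preserving relabelings gives a null distribution for the
  DMR count (`permutation_null`).
* **Biomarker projection** — PCA (centering-only, first three
  components) on RPKM over DMR windows; held-out samples are projected
  onto the frozen model and assigned to the nearest training-group
  centroid (`fit_pca`, `project_samples`, `assign_group`).
* **Annotation & cohort** — gene proximity within 10 kb and
  user-supplied gene categories (`associate_genes`,
  `category_summary`); semen-parameter utilities including total
  motile count (volume × concentration × motility) and 2-fold
  responder classification (`total_motile_count`,
  `classify_responders`).
* **Synthetic data** — a seeded generator of toy genomes with
  controlled CpG landscapes, NB window counts with CpG-dependent
  enrichment and library-size variation, spiked hyper/hypomethylated
  regions of 1–4 windows with a recorded truth table, and count→read
  round-tripping (`sim_config`, `simulate_genome`, `simulate_counts`,
  `counts_to_reads`).

Results are tibbles (or small S3 objects with `tidy()`, `glance()` and
`autoplot()` methods), so everything chains with the pipe.

## Worked example

Simulate a small two-group cohort (one 2-Mb chromosome, 6 + 6 samples,
four spiked regions), test every window, call DMRs, and compare with
the generative truth:

```r
library(medipdmr)
library(dplyr)

cfg <- sim_config(n_chroms = 1, chrom_length = 2e6, depth_mean = 2e4,
                  n_spikes = 4, seed = 3)
sim <- simulate_counts(cfg)
sim$counts
#> <window_counts> 2000 windows x 12 samples
#>   library sizes: 17,603 - 24,203 reads (min-max)

res  <- test_all_windows(sim$counts)
dmrs <- call_dmrs(res, sim$counts$windows)
dmrs |> as_tibble() |>
  select(dmr_id, chrom, start, end, sig_windows, min_p, direction, length_kb)
#> # A tibble: 4 × 8
#>   dmr_id   chrom   start     end sig_windows    min_p direction length_kb
#>   <chr>    <chr>   <int>   <int>       <int>    <dbl> <chr>         <dbl>
#> 1 DMR_0001 chr1  1132000 1136000           2 5.10e-11 increase          4
#> 2 DMR_0002 chr1  1379000 1382000           3 3.81e-18 increase          3
#> 3 DMR_0003 chr1  1468000 1469000           1 1.32e- 9 increase          1
#> 4 DMR_0004 chr1  1536000 1539000           3 5.01e-17 increase          3

sim$truth |> as_tibble() |> select(spike_id, start, end, n_windows, direction)
#> # A tibble: 4 × 5
#>   spike_id   start     end n_windows direction
#> 1 SPK_04   1132000 1134000         2 increase
#> 2 SPK_03   1379000 1382000         3 increase
#> 3 SPK_01   1468000 1469000         1 increase
#> 4 SPK_02   1536000 1539000         3 increase
```

All four spiked regions are recovered at their true coordinates with
the correct direction; `DMR_0001` is two seed windows plus two edge
extension windows (p < 0.1 neighbors), which is why its span exceeds
the spike. A 20-permutation null shows the observed count is not
label-free noise:

```r
permutation_null(sim$counts, n_perm = 20, seed = 11)
#> <dmr_permutation> observed 4 DMRs vs null over 20 permutations (max 1);
#>   empirical p = 0.0476
```

`autoplot()` on the permutation object draws the Fig-4d-style null
histogram with the observed count as a vertical line;
`autoplot(fit_pca(...))` plots the component scores with projected
held-out samples overlaid.

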