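#' Configuration for the synthetic MeDIP-seq data generator
#'
#' Captures the generative model the analysis assumes: a toy genome tiled
#' into fixed windows whose CpG counts follow a low-density profile;
#' per-sample read depths with lognormal library-size variation; expected
#' window coverage proportional to a CpG-dependent enrichment weight
#' `(1 + cpg_count)^coupling_exponent` (MeDIP pulls down methylated
#' CpGs); negative-binomial counting noise; and spiked hyper- or
#' hypomethylated regions of 1-4 consecutive windows in the case group.
#'
#' Defaults describe the study conditions the package is tested under:
#' 6 + 6 samples, 20,000 windows of 1000 bp, mean depth 2e5 reads per
#' sample, dispersion 0.1, CpG density cycling over 1-4 CpG per 100 bp,
#' and 10 spiked regions of fold change 6 spanning 1-4 windows, 90% of
#' them methylation increases.
#'
#' @param n_chroms Number of chromosomes (default 2).
#' @param chrom_length Chromosome length in bp (default 1e7).
#' @param window_size Window width in bp (default 1000).
#' @param n_per_group Training samples per group, length-2 (default
#'   `c(6, 6)`).
#' @param n_test_per_group Held-out samples per group, length-2 (default
#'   `c(0, 0)`); drawn from the same group generative parameters and
#'   flagged `test_set`.
#' @param depth_mean Expected reads per sample (default 2e5).
#' @param depth_cv Coefficient of variation of the lognormal per-sample
#'   depth (default 0.1).
#' @param dispersion_phi NB dispersion phi, `var = mu + phi mu^2`
#'   (default 0.1; 0 gives Poisson counts).
#' @param cpg_density_profile Piecewise window rates in CpG per 100 bp,
#'   recycled across windows (default `c(1, 2, 3, 4)`).
#' @param n_spikes Number of spiked regions (default 10).
#' @param spike_fold Fold change applied to spiked windows in the case
#'   group (> 1; default 6).
#' @param spike_sizes Possible spike widths in windows (default `1:4`).
#' @param frac_increase Fraction of spikes that are methylation
#'   increases (default 0.9).
#' @param coupling_exponent Exponent of the CpG enrichment weight
#'   (default 1).
#' @param seed Integer seed driving every stochastic stage (default 1).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 2, chrom_length = 1e7,
                       window_size = 1000,
                       n_per_group = c(6, 6),
                       n_test_per_group = c(0, 0),
                       depth_mean = 2e5, depth_cv = 0.1,
                       dispersion_phi = 0.1,
                       cpg_density_profile = c(1, 2, 3, 4),
                       n_spikes = 10, spike_fold = 6, spike_sizes = 1:4,
                       frac_increase = 0.9, coupling_exponent = 1,
                       seed = 1) {
  check_number(n_chroms, "n_chroms", min = 1)
  check_number(chrom_length, "chrom_length", min = 1)
  check_number(window_size, "window_size", min = 1)
  check_number(depth_mean, "depth_mean", min = 1)
  check_number(depth_cv, "depth_cv", min = 0)
  check_number(dispersion_phi, "dispersion_phi", min = 0)
  check_number(n_spikes, "n_spikes", min = 0)
  check_number(spike_fold, "spike_fold")
  if (spike_fold <= 1) {
    stop_input("`spike_fold` must be greater than 1.")
  }
  check_number(frac_increase, "frac_increase", min = 0)
  if (frac_increase > 1) {
    stop_input("`frac_increase` must lie in [0, 1].")
  }
  if (length(n_per_group) != 2 || any(n_per_group < 1)) {
    stop_input("`n_per_group` must be two positive integers.")
  }
  if (length(n_test_per_group) != 2 || any(n_test_per_group < 0)) {
    stop_input("`n_test_per_group` must be two non-negative integers.")
  }
  if (any(cpg_density_profile < 0)) {
    stop_input("`cpg_density_profile` rates must be non-negative.")
  }
  structure(
    list(
      n_chroms = as.integer(n_chroms),
      chrom_length = as.integer(chrom_length),
      window_size = as.integer(window_size),
      n_per_group = as.integer(n_per_group),
      n_test_per_group = as.integer(n_test_per_group),
      depth_mean = depth_mean, depth_cv = depth_cv,
      dispersion_phi = dispersion_phi,
      cpg_density_profile = cpg_density_profile,
      n_spikes = as.integer(n_spikes), spike_fold = spike_fold,
      spike_sizes = as.integer(spike_sizes),
      frac_increase = frac_increase,
      coupling_exponent = coupling_exponent,
      seed = seed
    ),
    class = "sim_config"
  )
}

# per-window Poisson CpG rates: profile recycled across windows
window_cpg_rates <- function(cfg, n_win_per_chrom) {
  purrr::map(n_win_per_chrom, function(n) {
    rep(cfg$cpg_density_profile, length.out = n)
  })
}

#' Simulate a toy genome with a controlled CpG landscape
#'
#' Builds random chromosomes whose per-window CpG counts are exactly
#' Poisson with the configured piecewise rates: the background sequence
#' is generated CG-free (any chance `CG` has its `G` resampled to A/T),
#' then each window receives a Poisson number of `CG` dinucleotides at
#' uniformly chosen non-overlapping positions. A rate of 0 therefore
#' yields a genome with no CpGs at all. Bit-reproducible under the
#' config seed.
#'
#' @param cfg A [sim_config()].
#' @return A [Biostrings::DNAStringSet] with chromosomes `chr1`,
#'   `chr2`, ...
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ws <- cfg$window_size
  with_seed_local(derive_seed(cfg$seed, 101), {
    seqs <- purrr::map(seq_len(cfg$n_chroms), function(ci) {
      len <- cfg$chrom_length
      s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      bad <- which(s[-len] == "C" & s[-1] == "G")
      if (length(bad)) {
        s[bad + 1L] <- sample(c("A", "T"), length(bad), replace = TRUE)
      }
      n_win <- ceiling(len / ws)
      rates <- rep(cfg$cpg_density_profile, length.out = n_win)
      for (w in seq_len(n_win)) {
        w_start <- (w - 1L) * ws
        width <- min(ws, len - w_start)
        max_cg <- width %/% 2L
        if (max_cg < 1L) next
        n_cg <- min(rpois(1L, rates[w] * width / 100), max_cg)
        if (n_cg == 0L) next
        # even offsets guarantee injected CGs cannot overlap
        cand <- w_start + 2L * (seq_len(max_cg) - 1L)
        pos <- cand[sample.int(length(cand), n_cg)]
        s[pos + 1L] <- "C"
        s[pos + 2L] <- "G"
      }
      paste(s, collapse = "")
    })
    out <- Biostrings::DNAStringSet(unlist(seqs))
    names(out) <- paste0("chr", seq_len(cfg$n_chroms))
    out
  })
}

#' Simulate a window table directly (counts-level shortcut)
#'
#' Draws per-window CpG counts from the same Poisson model that
#' [simulate_genome()] realizes in sequence, without building the
#' sequence itself. Distributionally equivalent to
#' `make_windows(simulate_genome(cfg))` and much faster when only the
#' count pipeline is being exercised.
#'
#' @param cfg A [sim_config()].
#' @return A window tibble as from [make_windows()].
#' @export
simulate_windows <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ws <- cfg$window_size
  with_seed_local(derive_seed(cfg$seed, 102), {
    per_chrom <- purrr::map(seq_len(cfg$n_chroms), function(ci) {
      len <- cfg$chrom_length
      starts <- seq.int(0L, len - 1L, by = ws)
      ends <- pmin(starts + ws, len)
      width <- ends - starts
      rates <- rep(cfg$cpg_density_profile, length.out = length(starts))
      tibble::tibble(
        chrom = paste0("chr", ci),
        start = as.integer(starts), end = as.integer(ends),
        cpg_count = pmin(rpois(length(starts), rates * width / 100),
                         width %/% 2L)
      )
    })
    out <- dplyr::bind_rows(per_chrom)
    dplyr::mutate(out, window_index = dplyr::row_number() - 1L,
                  .after = "end")
  })
}

#' Place spiked differential regions on a window set
#'
#' Chooses `n_spikes` non-overlapping runs of consecutive windows (sizes
#' drawn from `spike_sizes`, each run within one chromosome, separated by
#' at least 5 windows so distinct spikes cannot fuse into one region),
#' assigns each a direction (increase with probability `frac_increase`)
#' and the configured fold change. This is the ground truth used for
#' recovery testing.
#'
#' @param windows A window tibble.
#' @param cfg A [sim_config()].
#' @param seed Optional seed override (defaults to a child of
#'   `cfg$seed`).
#' @return A tibble of class `spike_truth`: `spike_id`, `chrom`,
#'   `start`, `end` (bp), `start_window` (global `window_index`),
#'   `n_windows`, `fold_change`, `direction`, `window_indices`
#'   (list-column).
#' @export
simulate_spikes <- function(windows, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_spikes == 0L) {
    return(empty_spikes())
  }
  seed <- seed %||% derive_seed(cfg$seed, 103)
  with_seed_local(seed, {
    sizes <- sample(cfg$spike_sizes, cfg$n_spikes, replace = TRUE)
    dirs <- ifelse(runif(cfg$n_spikes) < cfg$frac_increase,
                   "increase", "decrease")
    taken <- integer(0) # window rows blocked by earlier spikes + buffer
    rows <- vector("list", cfg$n_spikes)
    chrom_of <- windows$chrom
    for (i in seq_len(cfg$n_spikes)) {
      placed <- FALSE
      for (attempt in seq_len(1000)) {
        s <- sample.int(nrow(windows) - sizes[i] + 1L, 1L)
        idx <- s:(s + sizes[i] - 1L)
        if (length(unique(chrom_of[idx])) > 1L) next
        if (any(idx %in% taken)) next
        rows[[i]] <- list(idx = idx)
        # block a 5-window buffer so spikes cannot fuse during calling
        taken <- c(taken,
                   max(1L, s - 5L):min(nrow(windows), s + sizes[i] + 4L))
        placed <- TRUE
        break
      }
      if (!placed) {
        stop_input("could not place non-overlapping spikes; reduce n_spikes.")
      }
    }
    out <- purrr::imap(rows, function(r, i) {
      idx <- r$idx
      tibble::tibble(
        spike_id = sprintf("SPK_%02d", i),
        chrom = windows$chrom[idx[1]],
        start = windows$start[idx[1]],
        end = windows$end[idx[length(idx)]],
        start_window = windows$window_index[idx[1]],
        n_windows = length(idx),
        fold_change = cfg$spike_fold,
        direction = dirs[i],
        window_indices = list(windows$window_index[idx])
      )
    }) |>
      dplyr::bind_rows() |>
      dplyr::arrange(.data$chrom, .data$start)
    validate_spikes(out, windows)
    structure(out, class = c("spike_truth", class(out)))
  })
}

empty_spikes <- function() {
  structure(
    tibble::tibble(
      spike_id = character(), chrom = character(), start = integer(),
      end = integer(), start_window = integer(), n_windows = integer(),
      fold_change = numeric(), direction = character(),
      window_indices = list()
    ),
    class = c("spike_truth", "tbl_df", "tbl", "data.frame")
  )
}

validate_spikes <- function(spikes, windows) {
  if (!nrow(spikes)) {
    return(invisible(spikes))
  }
  if (any(spikes$fold_change <= 1)) {
    stop_input("spike fold_change must be greater than 1.")
  }
  wi <- unlist(spikes$window_indices)
  if (anyDuplicated(wi)) {
    stop_input("spikes must not overlap.")
  }
  if (!all(wi %in% windows$window_index)) {
    stop_input("spikes lie outside the window set.")
  }
  invisible(spikes)
}

#' Simulate a window count matrix with spiked differential regions
#'
#' Baseline enrichment weight for window `j` is
#' `(1 + cpg_count_j)^coupling_exponent`, normalized over windows; the
#' expected count is `depth_i * weight_j`, multiplied (direction
#' `increase`) or divided (`decrease`, symmetric on the log scale) by
#' the spike fold change for case-group samples in spiked windows.
#' Counts are negative binomial with the configured dispersion (Poisson
#' at `phi = 0`). Library sizes are the realized per-sample totals.
#' Held-out samples are generated from their group's parameters and
#' flagged `test_set` in the metadata.
#'
#' @param cfg A [sim_config()].
#' @param windows Window tibble; defaults to [simulate_windows()] on
#'   `cfg`.
#' @param spikes Spike truth tibble; defaults to [simulate_spikes()] on
#'   `cfg`. Supply `empty_spikes()`-style tibbles for a pure null.
#' @return A list with elements `counts` (a [window_counts] with group
#'   and test-set metadata) and `truth` (the spike tibble).
#' @export
simulate_counts <- function(cfg, windows = NULL, spikes = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  windows <- windows %||% simulate_windows(cfg)
  check_df_cols(windows, c("chrom", "start", "end", "window_index",
                           "cpg_count"), "windows")
  spikes <- spikes %||% simulate_spikes(windows, cfg)
  validate_spikes(spikes, windows)

  q <- (1 + windows$cpg_count)^cfg$coupling_exponent
  q <- q / sum(q)
  samples <- tibble::tibble(
    sample_id = c(
      sprintf("A%02d", seq_len(cfg$n_per_group[1])),
      sprintf("B%02d", seq_len(cfg$n_per_group[2])),
      sprintf("TA%02d", seq_len(cfg$n_test_per_group[1])),
      sprintf("TB%02d", seq_len(cfg$n_test_per_group[2]))
    ),
    group = rep(
      c("groupA", "groupB", "groupA", "groupB"),
      times = c(cfg$n_per_group, cfg$n_test_per_group)
    ),
    test_set = rep(
      c(FALSE, TRUE),
      times = c(sum(cfg$n_per_group), sum(cfg$n_test_per_group))
    )
  )

  spike_mult <- rep(1, nrow(windows))
  if (nrow(spikes)) {
    for (i in seq_len(nrow(spikes))) {
      rows <- match(spikes$window_indices[[i]], windows$window_index)
      spike_mult[rows] <- if (spikes$direction[i] == "increase") {
        spikes$fold_change[i]
      } else {
        1 / spikes$fold_change[i]
      }
    }
  }

  with_seed_local(derive_seed(cfg$seed, 104), {
    sigma <- sqrt(log(1 + cfg$depth_cv^2))
    depth <- cfg$depth_mean *
      exp(stats::rnorm(nrow(samples), -sigma^2 / 2, sigma))
    counts <- matrix(0L, nrow = nrow(windows), ncol = nrow(samples),
                     dimnames = list(NULL, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      mu <- depth[j] * q
      if (samples$group[j] == "groupB") {
        mu <- mu * spike_mult
      }
      counts[, j] <- if (cfg$dispersion_phi > 0) {
        rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion_phi)
      } else {
        rpois(length(mu), mu)
      }
    }
    wc <- window_counts(windows, counts, colSums(counts), samples)
    list(counts = wc, truth = spikes)
  })
}

#' Expand window counts into synthetic read intervals
#'
#' For every counted read, emits one interval of `read_length` bp whose
#' midpoint is uniform within the window, so re-counting the output with
#' the midpoint policy reproduces the count matrix exactly (a round-trip
#' check of the coverage stage). Reads near a chromosome start are
#' shifted so they never extend below coordinate 0, preserving the
#' midpoint.
#'
#' @param wc A [window_counts] object.
#' @param read_length Read length in bp (positive, smaller than the
#'   window size).
#' @param seed Optional integer seed.
#' @return A tibble `sample_id`, `chrom`, `start`, `end` (0-based
#'   half-open), one row per read.
#' @export
counts_to_reads <- function(wc, read_length = 50, seed = NULL) {
  stopifnot(inherits(wc, "window_counts"))
  check_number(read_length, "read_length", min = 1)
  min_width <- min(wc$windows$end - wc$windows$start)
  if (read_length >= min_width) {
    stop_input("`read_length` must be smaller than the window size.")
  }
  half <- read_length %/% 2
  with_seed_local(seed, {
    per_sample <- purrr::map(colnames(wc$counts), function(sid) {
      n <- wc$counts[, sid]
      keep <- n > 0L
      if (!any(keep)) {
        return(tibble::tibble(sample_id = character(), chrom = character(),
                              start = integer(), end = integer()))
      }
      lo <- pmax(wc$windows$start[keep], half)
      hi <- wc$windows$end[keep] - 1L
      lo_r <- rep(lo, n[keep])
      hi_r <- rep(hi, n[keep])
      mid <- lo_r + floor(runif(length(lo_r)) * (hi_r - lo_r + 1))
      tibble::tibble(
        sample_id = sid,
        chrom = rep(wc$windows$chrom[keep], n[keep]),
        start = as.integer(mid - half),
        end = as.integer(mid - half + read_length)
      )
    })
    dplyr::bind_rows(per_sample)
  })
}

#' Write a complete simulated dataset to disk
#'
#' Emits `genome.fa`, one BED file of read intervals per sample under
#' `reads/`, `windows.tsv`, `counts.tsv`, `metadata.tsv` and
#' `truth.tsv` into `dir`. With `genome = FALSE` the sequence stage is
#' skipped and windows come from the counts-level shortcut.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param genome Also simulate and write the FASTA genome (default
#'   TRUE).
#' @param read_length Read length for [counts_to_reads()] (default 50).
#' @return Invisibly, the list from [simulate_counts()].
#' @export
write_simulation <- function(cfg, dir, genome = TRUE, read_length = 50) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(file.path(dir, "reads"), recursive = TRUE,
             showWarnings = FALSE)
  if (genome) {
    fa <- simulate_genome(cfg)
    Biostrings::writeXStringSet(fa, file.path(dir, "genome.fa"))
    windows <- make_windows(fa, cfg$window_size)
  } else {
    windows <- simulate_windows(cfg)
  }
  sim <- simulate_counts(cfg, windows)
  write_windows_tsv(windows, file.path(dir, "windows.tsv"))
  write_counts_tsv(sim$counts, file.path(dir, "counts.tsv"))
  readr::write_tsv(
    dplyr::mutate(sim$counts$samples,
                  test_set = as.integer(.data$test_set)),
    file.path(dir, "metadata.tsv")
  )
  truth <- tibble::as_tibble(sim$truth)
  if (nrow(truth)) {
    truth$window_indices <- purrr::map_chr(
      truth$window_indices, ~ paste(.x, collapse = ",")
    )
  } else {
    truth$window_indices <- character(0)
  }
  readr::write_tsv(truth, file.path(dir, "truth.tsv"))
  reads <- counts_to_reads(sim$counts, read_length = read_length,
                           seed = derive_seed(cfg$seed, 105))
  for (sid in unique(sim$counts$samples$sample_id)) {
    sub <- reads[reads$sample_id == sid,
                 c("chrom", "start", "end")]
    readr::write_tsv(sub, file.path(dir, "reads", paste0(sid, ".bed")),
                     col_names = FALSE)
  }
  invisible(sim)
}
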