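#' Construct a window count container
#'
#' Bundles the window table, the integer read-count matrix (windows in
#' rows, samples in columns), per-sample library sizes (total input reads,
#' including reads that fell in no window) and the sample metadata. Most
#' users create one via [count_reads()] or [simulate_counts()] rather than
#' directly.
#'
#' @param windows Window tibble from [make_windows()].
#' @param counts Integer matrix, `nrow(windows)` x number of samples, with
#'   sample ids as column names.
#' @param library_size Named numeric vector of total mapped reads per
#'   sample (names matching `colnames(counts)`).
#' @param samples Optional sample metadata tibble (`sample_id`, `group`,
#'   `test_set`); defaults to a bare table of sample ids.
#' @return An object of class `window_counts`.
#' @export
window_counts <- function(windows, counts, library_size, samples = NULL) {
  check_df_cols(windows, c("chrom", "start", "end", "window_index"),
                "windows")
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(windows)) {
    stop_input("`counts` must have one row per window.")
  }
  if (is.null(colnames(counts))) {
    stop_input("`counts` must have sample ids as column names.")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_input("`counts` must be non-negative integers.")
  }
  storage.mode(counts) <- "integer"
  if (!setequal(names(library_size), colnames(counts))) {
    stop_input("`library_size` names must match the count matrix columns.")
  }
  # under midpoint counting library sizes bound the in-window totals;
  # overlap_any counts boundary reads more than once, so no check here
  library_size <- library_size[colnames(counts)]
  if (any(library_size < 0)) {
    stop_input("library sizes must be non-negative.")
  }
  if (is.null(samples)) {
    samples <- tibble::tibble(
      sample_id = colnames(counts),
      group = NA_character_,
      test_set = FALSE
    )
  }
  check_df_cols(samples, "sample_id", "samples")
  if (!setequal(samples$sample_id, colnames(counts))) {
    stop_input("`samples$sample_id` must match the count matrix columns.")
  }
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  structure(
    list(
      windows = tibble::as_tibble(windows),
      counts = counts,
      library_size = library_size,
      samples = tibble::as_tibble(samples)
    ),
    class = "window_counts"
  )
}

#' @export
print.window_counts <- function(x, ...) {
  cat(sprintf(
    "<window_counts> %d windows x %d samples\n",
    nrow(x$counts), ncol(x$counts)
  ))
  cat(sprintf(
    "  library sizes: %s reads (min-max)\n",
    paste(format(range(x$library_size), big.mark = ","), collapse = " - ")
  ))
  if (!all(is.na(x$samples$group))) {
    tab <- table(x$samples$group, x$samples$test_set)
    cat("  samples per group (columns: test_set):\n")
    print(tab)
  }
  invisible(x)
}

#' @export
dim.window_counts <- function(x) dim(x$counts)

#' Tidy a window count container into a long tibble
#'
#' @param x A `window_counts` object.
#' @param ... Unused.
#' @return A tibble with one row per window x sample: window coordinates,
#'   `sample_id`, `group`, `test_set`, `count`, `library_size`.
#' @export
tidy.window_counts <- function(x, ...) {
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(x$windows, tibble::as_tibble(x$counts)),
    cols = dplyr::all_of(colnames(x$counts)),
    names_to = "sample_id", values_to = "count"
  )
  long |>
    dplyr::left_join(x$samples, by = "sample_id") |>
    dplyr::mutate(library_size = x$library_size[.data$sample_id])
}

#' Read per-sample mapped-read intervals from BED files
#'
#' Each interval is one mapped read. Files may be gzipped.
#'
#' @param paths Character vector of BED file paths, named by sample id.
#' @return A tibble with columns `sample_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @export
read_bed_reads <- function(paths) {
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    stop_input("`paths` must be named by sample id.")
  }
  purrr::imap(paths, function(p, sid) {
    gr <- rtracklayer::import(p, format = "BED")
    tibble::tibble(
      sample_id = sid,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr)
    )
  }) |>
    dplyr::bind_rows()
}

#' Count mapped reads into genome windows
#'
#' Under the default `midpoint` policy each read is assigned to exactly
#' one window: the one containing `floor((start + end) / 2)`. Under
#' `overlap_any` every window the read overlaps by at least 1 bp is
#' incremented, so a read spanning a boundary is counted twice. Library
#' size is the total number of input reads per sample (not the in-window
#' total), matching the "per million mapped reads" denominator of RPKM.
#'
#' @param reads Tibble of read intervals with columns `sample_id`,
#'   `chrom`, `start`, `end` (0-based half-open), e.g. from
#'   [read_bed_reads()].
#' @param windows Window tibble from [make_windows()].
#' @param policy `"midpoint"` (default) or `"overlap_any"`.
#' @param unknown_chrom What to do with reads on chromosomes absent from
#'   `windows`: `"skip"` (drop with a warning; they still count toward
#'   library size) or `"error"`.
#' @param samples Optional sample metadata tibble to attach.
#' @return A [window_counts] object.
#' @export
count_reads <- function(reads, windows,
                        policy = c("midpoint", "overlap_any"),
                        unknown_chrom = c("skip", "error"),
                        samples = NULL) {
  policy <- match.arg(policy)
  unknown_chrom <- match.arg(unknown_chrom)
  check_df_cols(reads, c("sample_id", "chrom", "start", "end"), "reads")
  check_df_cols(windows, c("chrom", "start", "end", "window_index"),
                "windows")
  if (any(reads$start >= reads$end)) {
    stop_input("read intervals must satisfy start < end.")
  }
  lib <- table(factor(reads$sample_id))
  sample_ids <- names(lib)
  if (!is.null(samples)) {
    sample_ids <- samples$sample_id
    if (!all(names(lib) %in% sample_ids)) {
      stop_input("reads contain sample ids absent from `samples`.")
    }
  }
  library_size <- setNames(rep(0, length(sample_ids)), sample_ids)
  library_size[names(lib)] <- as.numeric(lib)

  off_contig <- !reads$chrom %in% unique(windows$chrom)
  if (any(off_contig)) {
    if (unknown_chrom == "error") {
      stop_input(sprintf(
        "%d read(s) on chromosome(s) absent from the window set.",
        sum(off_contig)
      ))
    }
    rlang::warn(sprintf(
      "skipping %d read(s) on unknown chromosome(s); they still count toward library size.",
      sum(off_contig)
    ))
    reads <- reads[!off_contig, ]
  }

  win_gr <- windows_granges(windows)
  if (policy == "midpoint") {
    mid <- (reads$start + reads$end) %/% 2
    q <- GenomicRanges::GRanges(
      reads$chrom, IRanges::IRanges(start = mid + 1L, width = 1L)
    )
  } else {
    q <- GenomicRanges::GRanges(
      reads$chrom,
      IRanges::IRanges(start = reads$start + 1L, end = reads$end)
    )
  }
  hits <- GenomicRanges::findOverlaps(q, win_gr)
  counts <- matrix(
    0L, nrow = nrow(windows), ncol = length(sample_ids),
    dimnames = list(NULL, sample_ids)
  )
  if (length(hits)) {
    sj <- match(reads$sample_id[S4Vectors::queryHits(hits)], sample_ids)
    wi <- S4Vectors::subjectHits(hits)
    tab <- table(factor(wi, levels = seq_len(nrow(windows))), factor(sj))
    counts[, as.integer(colnames(tab))] <- as.integer(tab)
  }
  window_counts(windows, counts, library_size, samples)
}

# one multivariate-hypergeometric draw: k reads without replacement from
# urns with `counts` reads each (sequential conditional hypergeometric)
rmvhyper <- function(counts, k) {
  n <- length(counts)
  out <- integer(n)
  remaining <- sum(counts)
  for (j in seq_len(n)) {
    if (k == 0L) break
    cj <- counts[j]
    remaining <- remaining - cj
    out[j] <- rhyper(1L, m = cj, n = remaining, k = k)
    k <- k - out[j]
  }
  out
}

#' Randomly subsample samples to a common read depth
#'
#' Equalizes depths across samples before differential testing, mirroring
#' read-level random subsampling. Each column with in-window total above
#' `target_depth` is replaced by a multivariate-hypergeometric draw of
#' `target_depth` reads without replacement from its window counts
#' (distributionally identical to subsampling the read file and
#' re-counting); columns at or below the target are left unchanged.
#' Library sizes of subsampled columns are set to `target_depth`.
#'
#' @param wc A [window_counts] object.
#' @param target_depth Number of reads to keep per sample (>= 0).
#' @param seed Integer seed for reproducibility (optional).
#' @return A new [window_counts] object.
#' @export
subsample_counts <- function(wc, target_depth, seed = NULL) {
  stopifnot(inherits(wc, "window_counts"))
  check_number(target_depth, "target_depth", min = 0)
  with_seed_local(seed, {
    counts <- wc$counts
    lib <- wc$library_size
    for (j in seq_len(ncol(counts))) {
      tot <- sum(counts[, j])
      if (tot > target_depth) {
        counts[, j] <- rmvhyper(counts[, j], as.integer(target_depth))
        lib[j] <- target_depth
      }
    }
    window_counts(wc$windows, counts, lib, wc$samples)
  })
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm[i, j] = count[i, j] / ((length_i / 1000) * (library_size_j / 1e6))`.
#' Length-normalization uses each window's true width, so trailing partial
#' windows are comparable with full ones.
#'
#' @param wc A [window_counts] object.
#' @param rows Optional integer vector of `window_index` values to
#'   restrict to (e.g. DMR member windows); default all windows.
#' @return A numeric matrix (selected windows x samples) with
#'   `window_index` values as row names.
#' @export
rpkm <- function(wc, rows = NULL) {
  stopifnot(inherits(wc, "window_counts"))
  if (any(wc$library_size <= 0)) {
    stop_input("all library sizes must be positive for RPKM.")
  }
  idx <- seq_len(nrow(wc$counts))
  if (!is.null(rows)) {
    idx <- match(rows, wc$windows$window_index)
    if (anyNA(idx)) {
      stop_input("`rows` contains window_index values not in `wc`.")
    }
  }
  len_kb <- (wc$windows$end[idx] - wc$windows$start[idx]) / 1000
  lib_m <- wc$library_size / 1e6
  out <- wc$counts[idx, , drop = FALSE] /
    outer(len_kb, lib_m)
  rownames(out) <- wc$windows$window_index[idx]
  out
}

#' Write a window count matrix as TSV
#'
#' Window coordinates lead, then one column per sample; library sizes go
#' in a comment-style header line.
#'
#' @param wc A [window_counts] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(wc, path) {
  stopifnot(inherits(wc, "window_counts"))
  header <- paste0(
    "# library_size: ",
    paste(sprintf("%s=%s", names(wc$library_size), wc$library_size),
          collapse = " ")
  )
  writeLines(header, path)
  readr::write_tsv(
    dplyr::bind_cols(wc$windows, tibble::as_tibble(wc$counts)),
    path, append = TRUE, col_names = TRUE
  )
  invisible(path)
}
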