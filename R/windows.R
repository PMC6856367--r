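#' Tile a genome into fixed-width windows with CpG counts
#'
#' Partitions every sequence of a reference genome into consecutive
#' non-overlapping windows of `window_size` bp (the last window of a
#' chromosome may be shorter) and annotates each window with the number of
#' CpG dinucleotides in its sequence. Coordinates are 0-based half-open
#' throughout the package, as in BED.
#'
#' CpGs are counted on the forward strand: positions `i` with `C` at `i`
#' and `G` at `i + 1`, both inside the window. A CG pair straddling a
#' window boundary belongs to neither window. Soft-masked (lowercase)
#' bases count as their uppercase base; `N` never matches.
#'
#' @param genome A path to a FASTA file (optionally gzipped) or a
#'   [Biostrings::DNAStringSet].
#' @param window_size Window width in bp (>= 1; default 1000).
#' @return A tibble with columns `chrom`, `start`, `end`, `window_index`
#'   (0-based, in genome order) and `cpg_count`, one row per window,
#'   ordered by sequence order in the FASTA then position.
#' @examples
#' genome <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 625)))
#' make_windows(genome, window_size = 1000)
#' @export
make_windows <- function(genome, window_size = 1000) {
  check_number(window_size, "window_size", min = 1)
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (!methods::is(genome, "DNAStringSet")) {
    stop_input("`genome` must be a FASTA path or a DNAStringSet.")
  }
  if (length(genome) == 0L) {
    stop_input("the genome contains no sequences.")
  }
  nms <- sub("\\s.*$", "", names(genome) %||% character(0))
  if (is.null(names(genome)) || any(!nzchar(nms))) {
    stop_input("every genome sequence must be named.")
  }
  if (anyDuplicated(nms)) {
    stop_input("duplicate sequence names in the genome.")
  }
  names(genome) <- nms

  per_chrom <- purrr::map2(nms, as.list(Biostrings::width(genome)),
    function(chrom, len) {
      starts <- seq.int(0L, len - 1L, by = window_size)
      tibble::tibble(
        chrom = chrom,
        start = as.integer(starts),
        end = as.integer(pmin(starts + window_size, len))
      )
    }
  )
  windows <- dplyr::bind_rows(per_chrom)
  windows$window_index <- seq_len(nrow(windows)) - 1L

  # locate every CG once per chromosome, then bin by window; a match whose
  # second base falls in the next window is dropped (not inside either)
  cpg <- integer(nrow(windows))
  offset <- 0L
  for (i in seq_along(genome)) {
    seq_i <- Biostrings::DNAString(toupper(as.character(genome[[i]])))
    validate_dna(as.character(seq_i))
    hits <- Biostrings::start(Biostrings::matchPattern("CG", seq_i)) - 1L
    len <- Biostrings::width(genome)[i]
    n_win <- ceiling(len / window_size)
    if (length(hits)) {
      win_of <- hits %/% as.integer(window_size)
      inside <- (hits + 1L) %/% as.integer(window_size) == win_of
      tab <- tabulate(win_of[inside] + 1L, nbins = n_win)
      cpg[offset + seq_len(n_win)] <- tab
    }
    offset <- offset + n_win
  }
  windows$cpg_count <- cpg
  windows
}

validate_dna <- function(x) {
  if (any(grepl("[^ACGTNacgtn]", x))) {
    stop_input("sequence contains characters outside {A, C, G, T, N}.")
  }
  invisible(x)
}

#' Count CpG dinucleotides in DNA sequences
#'
#' Counts forward-strand `CG` dinucleotides: positions `i` with `C` at `i`
#' and `G` at `i + 1`. Case-insensitive; `N` never matches. CG pairs
#' cannot overlap each other, so this equals the number of non-overlapping
#' `CG` matches.
#'
#' @param sequence A character vector of DNA sequences over
#'   `{A, C, G, T, N}` (case-insensitive).
#' @return An integer vector of CpG counts, one per input sequence.
#' @examples
#' count_cpg(c("CGCGCG", "GCGCGC", "AAAA"))
#' @export
count_cpg <- function(sequence) {
  if (!is.character(sequence)) {
    stop_input("`sequence` must be a character vector.")
  }
  validate_dna(sequence)
  if (length(sequence) == 0L) {
    return(integer(0))
  }
  as.integer(Biostrings::vcountPattern(
    "CG", Biostrings::DNAStringSet(toupper(sequence))
  ))
}

#' CpG density per 100 bp
#'
#' @param cpg_count Integer CpG counts.
#' @param length_bp Region lengths in bp.
#' @return Numeric density, CpG per 100 bp.
#' @export
cpg_density <- function(cpg_count, length_bp) {
  check_number(length_bp, "length_bp", min = 1, allow_zero_len = TRUE)
  100 * cpg_count / length_bp
}

#' Write windows as BED4 and TSV
#'
#' `write_windows_bed()` emits `chrom start end cpg_count` (0-based
#' half-open, no header); `write_windows_tsv()` writes the full window
#' table with `window_index` and a header.
#'
#' @param windows A window tibble from [make_windows()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(windows, path) {
  check_df_cols(windows, c("chrom", "start", "end", "cpg_count"), "windows")
  readr::write_tsv(
    windows[, c("chrom", "start", "end", "cpg_count")],
    path, col_names = FALSE
  )
  invisible(path)
}

#' @rdname write_windows_bed
#' @export
write_windows_tsv <- function(windows, path) {
  check_df_cols(
    windows, c("chrom", "start", "end", "window_index", "cpg_count"),
    "windows"
  )
  readr::write_tsv(windows, path)
  invisible(path)
}

windows_granges <- function(windows) {
  GenomicRanges::GRanges(
    seqnames = windows$chrom,
    ranges = IRanges::IRanges(start = windows$start + 1L, end = windows$end)
  )
}
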