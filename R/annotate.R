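#' Read gene intervals from BED or minimal GFF3
#'
#' BED6 input uses the `name` column as the gene id. For GFF3, only
#' `gene`-type features are kept and the id is taken from the `ID` (or
#' `gene_id`) attribute. Coordinates are returned 0-based half-open.
#'
#' @param path Path to a BED or GFF3 file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return A tibble `gene_id`, `chrom`, `start`, `end`, `name`.
#' @export
read_genes <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) {
      "gff3"
    } else {
      "bed"
    }
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED"
                            else "GFF3")
  if (format == "gff3") {
    if ("type" %in% names(S4Vectors::mcols(gr))) {
      gr <- gr[as.character(gr$type) == "gene"]
    }
    ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) gr$ID else gr$gene_id
    nms <- if ("Name" %in% names(S4Vectors::mcols(gr))) gr$Name else ids
  } else {
    ids <- gr$name
    nms <- gr$name
  }
  out <- tibble::tibble(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = as.character(nms)
  )
  if (any(out$end <= out$start)) {
    stop_input("gene intervals must satisfy start < end.")
  }
  out
}

#' Associate DMRs with nearby genes
#'
#' A DMR associates with every gene whose interval lies within
#' `proximity` bp of the DMR span, measured between closest interval
#' edges; overlapping features have distance 0. Strand is ignored. A DMR
#' may associate with zero, one or many genes.
#'
#' @param dmrs A `dmr_set` from [call_dmrs()].
#' @param genes A gene tibble (`gene_id`, `chrom`, `start`, `end`), e.g.
#'   from [read_genes()].
#' @param proximity Maximum gap in bp (default 10000).
#' @return A tibble `dmr_id`, `gene_id`, `distance` (bp, 0 for
#'   overlap), one row per association.
#' @export
associate_genes <- function(dmrs, genes, proximity = 10000) {
  check_df_cols(dmrs, c("dmr_id", "chrom", "start", "end"), "dmrs")
  check_df_cols(genes, c("gene_id", "chrom", "start", "end"), "genes")
  check_number(proximity, "proximity", min = 0)
  empty <- tibble::tibble(dmr_id = character(), gene_id = character(),
                          distance = integer())
  if (!nrow(dmrs) || !nrow(genes)) {
    return(empty)
  }
  gr_d <- GenomicRanges::GRanges(
    dmrs$chrom, IRanges::IRanges(start = dmrs$start + 1L, end = dmrs$end)
  )
  gr_g <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = genes$start + 1L,
                                  end = genes$end)
  )
  hits <- GenomicRanges::findOverlaps(gr_d, gr_g, maxgap = proximity)
  if (!length(hits)) {
    return(empty)
  }
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  dist <- GenomicRanges::distance(gr_d[qh], gr_g[sh])
  tibble::tibble(
    dmr_id = dmrs$dmr_id[qh],
    gene_id = genes$gene_id[sh],
    distance = as.integer(dist)
  ) |>
    dplyr::filter(.data$distance <= proximity) |>
    dplyr::arrange(.data$dmr_id, .data$distance)
}

#' Read a gene-to-category map
#'
#' @param path Two-column TSV: `gene_id`, `category` (header required).
#' @return A tibble `gene_id`, `category`.
#' @export
read_category_map <- function(path) {
  map <- readr::read_tsv(path, show_col_types = FALSE)
  check_df_cols(map, c("gene_id", "category"), "category map")
  tibble::as_tibble(map[, c("gene_id", "category")])
}

#' Count DMRs per gene functional category
#'
#' Each DMR is counted once per distinct category among its associated
#' genes: two same-category genes near one DMR contribute a single count,
#' while genes of two categories increment both. Genes missing from the
#' map fall in category `"unknown"`.
#'
#' @param associations Tibble from [associate_genes()].
#' @param category_map Tibble `gene_id`, `category`, e.g. from
#'   [read_category_map()].
#' @return A tibble `category`, `n_dmrs`, sorted by descending count.
#' @export
category_summary <- function(associations, category_map) {
  check_df_cols(associations, c("dmr_id", "gene_id"), "associations")
  check_df_cols(category_map, c("gene_id", "category"), "category_map")
  if (!nrow(associations)) {
    return(tibble::tibble(category = character(), n_dmrs = integer()))
  }
  associations |>
    dplyr::left_join(category_map, by = "gene_id",
                     relationship = "many-to-many") |>
    dplyr::mutate(category = dplyr::coalesce(.data$category, "unknown")) |>
    dplyr::distinct(.data$dmr_id, .data$category) |>
    dplyr::count(.data$category, name = "n_dmrs") |>
    dplyr::arrange(dplyr::desc(.data$n_dmrs), .data$category)
}
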