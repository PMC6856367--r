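#' Call differentially methylated regions from window test results
#'
#' A DMR nucleates at seed windows with `p_value < sig_threshold`
#' (default 1e-5). Seed windows on the same chromosome whose spans are
#' adjacent or separated by at most `edge_distance` bp are merged. The
#' edges are then extended: any window with `p_value < edge_threshold`
#' (default 0.1) lying within `edge_distance` bp of the current DMR span
#' is absorbed, and absorption is iterated to a fixed point, so a newly
#' absorbed window can pull in further windows (set `iterate = FALSE` for
#' a single pass). Finally, DMRs whose extended spans touch or overlap
#' are merged. `sig_windows` counts seed windows only, so tables of
#' multi-window DMRs refer to significant windows.
#'
#' @param results Per-window test results from [test_all_windows()].
#' @param windows Window tibble from [make_windows()] (provides CpG
#'   counts); must cover the same `window_index` values as `results`.
#' @param sig_threshold Seed p-value threshold (default 1e-5); must be
#'   <= `edge_threshold`.
#' @param edge_threshold Extension p-value threshold (default 0.1).
#' @param edge_distance Maximum gap in bp between a window and the DMR
#'   span for absorption/merging; defaults to the modal window width.
#' @param iterate Iterate extension to a fixed point (default TRUE).
#' @param comparison_label Free-text label stored on the result.
#' @return A tibble of class `dmr_set`, one row per DMR, sorted and
#'   non-overlapping, with columns `dmr_id`, `chrom`, `start`, `end`
#'   (0-based half-open union of member windows), `n_windows`,
#'   `sig_windows`, `min_p`, `direction` (`"increase"`/`"decrease"`, case
#'   group over reference), `log2fc` (at the minimum-p seed window),
#'   `max_abs_log2fc`, `cpg_count`, `cpg_per_100bp`, `length_kb`, and the
#'   list-column `window_indices` (all member windows, seeds and
#'   extensions). Thresholds are stored as attributes, as is
#'   `n_seed_groups`, the number of merged seed groups before
#'   extension-driven span merging (equal to the row count unless
#'   extension fused neighboring groups).
#' @export
call_dmrs <- function(results, windows, sig_threshold = 1e-5,
                      edge_threshold = 0.1, edge_distance = NULL,
                      iterate = TRUE, comparison_label = "") {
  check_df_cols(results, c("window_index", "p_value", "log2fc"), "results")
  check_df_cols(windows, c("window_index", "chrom", "start", "end"),
                "windows")
  check_number(sig_threshold, "sig_threshold", min = 0)
  check_number(edge_threshold, "edge_threshold", min = 0)
  if (sig_threshold > edge_threshold) {
    stop_input("`sig_threshold` must not exceed `edge_threshold`.")
  }
  if (!all(results$window_index %in% windows$window_index)) {
    stop_input("`results` and `windows` are misaligned: unknown window_index.")
  }
  if (is.null(edge_distance)) {
    w <- windows$end - windows$start
    edge_distance <- as.numeric(names(sort(table(w), decreasing = TRUE))[1])
  }
  check_number(edge_distance, "edge_distance", min = 0)

  cpg <- if ("cpg_count" %in% names(windows)) windows$cpg_count else
    rep(NA_integer_, nrow(windows))
  tab <- dplyr::inner_join(
    results[, c("window_index", "p_value", "log2fc")],
    dplyr::mutate(windows[, c("window_index", "chrom", "start", "end")],
                  cpg_count = cpg),
    by = "window_index"
  )
  tab <- dplyr::arrange(tab, .data$chrom, .data$start)

  members <- list()
  for (chrom in unique(tab$chrom)) {
    ct <- tab[tab$chrom == chrom, ]
    members <- c(members, dmr_members_one_chrom(
      ct, sig_threshold, edge_threshold, edge_distance, iterate
    ))
  }

  if (!length(members)) {
    out <- tibble::tibble(
      dmr_id = character(), chrom = character(),
      start = integer(), end = integer(),
      n_windows = integer(), sig_windows = integer(),
      min_p = numeric(), direction = character(), log2fc = numeric(),
      max_abs_log2fc = numeric(), cpg_count = integer(),
      cpg_per_100bp = numeric(), length_kb = numeric(),
      window_indices = list()
    )
  } else {
    rows <- purrr::map(members, function(m) {
      seeds <- m[m$p_value < sig_threshold, ]
      lead <- seeds[order(seeds$p_value, -abs(seeds$log2fc)), ][1, ]
      span_start <- min(m$start)
      span_end <- max(m$end)
      tibble::tibble(
        chrom = m$chrom[1],
        start = span_start, end = span_end,
        n_windows = nrow(m), sig_windows = nrow(seeds),
        min_p = min(m$p_value),
        direction = if (lead$log2fc > 0) "increase" else "decrease",
        log2fc = lead$log2fc,
        max_abs_log2fc = max(abs(m$log2fc)),
        cpg_count = sum(m$cpg_count),
        cpg_per_100bp = 100 * sum(m$cpg_count) / (span_end - span_start),
        length_kb = (span_end - span_start) / 1000,
        window_indices = list(sort(m$window_index))
      )
    })
    out <- dplyr::arrange(dplyr::bind_rows(rows), .data$chrom, .data$start)
    out <- dplyr::mutate(
      out, dmr_id = sprintf("DMR_%04d", dplyr::row_number()),
      .before = 1
    )
  }
  # how many merged seed groups existed before extension-driven span
  # merging, for comparison with the merged count nrow(out)
  n_seed_groups <- sum(purrr::map_int(unique(tab$chrom), function(ch) {
    s <- tab[tab$chrom == ch & tab$p_value < sig_threshold, ]
    if (!nrow(s)) return(0L)
    s <- s[order(s$start), ]
    1L + sum(s$start[-1] - cummax(s$end)[-nrow(s)] > edge_distance)
  }))
  structure(
    out,
    class = c("dmr_set", class(out)),
    n_seed_groups = n_seed_groups,
    sig_threshold = sig_threshold,
    edge_threshold = edge_threshold,
    edge_distance = edge_distance,
    comparison_label = comparison_label
  )
}

# gap in bp between two half-open intervals; 0 for touching or overlapping
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s1 - e2, s2 - e1))
}

# core region-growing on one chromosome's sorted window table; returns a
# list of member sub-tables
dmr_members_one_chrom <- function(ct, sig_threshold, edge_threshold,
                                  edge_distance, iterate) {
  seed_idx <- which(ct$p_value < sig_threshold)
  if (!length(seed_idx)) {
    return(list())
  }
  cand_idx <- which(ct$p_value < edge_threshold)

  # (1)+(2) merge seed windows whose spans lie within edge_distance
  groups <- list(seed_idx[1])
  if (length(seed_idx) > 1) {
    for (i in seed_idx[-1]) {
      last <- groups[[length(groups)]]
      if (ct$start[i] - max(ct$end[last]) <= edge_distance) {
        groups[[length(groups)]] <- c(last, i)
      } else {
        groups <- c(groups, list(i))
      }
    }
  }

  # (3) absorb sub-threshold windows near each span, iterating to a fixed
  # point; (4) merge spans that touch or overlap; repeat until stable
  repeat {
    changed <- FALSE
    groups <- purrr::map(groups, function(g) {
      repeat {
        s <- min(ct$start[g]); e <- max(ct$end[g])
        near <- cand_idx[!cand_idx %in% g &
          interval_gap(ct$start[cand_idx], ct$end[cand_idx], s, e) <=
            edge_distance]
        if (!length(near)) break
        g <- c(g, near)
        changed <<- TRUE
        if (!iterate) break
      }
      g
    })
    # merge groups whose spans touch or overlap (sorted by span start)
    spans <- purrr::map(groups, ~ c(min(ct$start[.x]), max(ct$end[.x])))
    ord <- order(purrr::map_dbl(spans, 1))
    groups <- groups[ord]
    spans <- spans[ord]
    merged <- list(groups[[1]])
    merged_span <- spans[[1]]
    if (length(groups) > 1) {
      for (i in 2:length(groups)) {
        if (spans[[i]][1] <= merged_span[2]) {
          merged[[length(merged)]] <- union(merged[[length(merged)]],
                                            groups[[i]])
          merged_span[2] <- max(merged_span[2], spans[[i]][2])
          changed <- TRUE
        } else {
          merged <- c(merged, list(groups[[i]]))
          merged_span <- spans[[i]]
        }
      }
    }
    groups <- purrr::map(merged, ~ sort(unique(.x)))
    if (!changed || !iterate) break
  }
  purrr::map(groups, ~ ct[.x, ])
}

#' Direction of methylation change per DMR
#'
#' A DMR's direction is the sign of the log2 fold change at its
#' minimum-p seed window (case group over reference): positive means an
#' increase in methylation (more MeDIP coverage in the case group). Ties
#' on p-value break toward the larger absolute fold change.
#'
#' @param dmrs A `dmr_set` from [call_dmrs()].
#' @param results The per-window results the set was called from.
#' @return A tibble `dmr_id`, `direction`.
#' @export
dmr_direction <- function(dmrs, results) {
  sig <- attr(dmrs, "sig_threshold") %||% 1e-5
  dirs <- purrr::map_chr(dmrs$window_indices, function(wi) {
    sub <- results[results$window_index %in% wi &
                     results$p_value < sig, ]
    lead <- sub[order(sub$p_value, -abs(sub$log2fc)), ][1, ]
    if (lead$log2fc > 0) "increase" else "decrease"
  })
  tibble::tibble(dmr_id = dmrs$dmr_id, direction = dirs)
}

#' DMR counts across a ladder of p-value thresholds
#'
#' Re-runs the DMR caller at each threshold and reports, per threshold,
#' the number of DMRs overall and the number containing at least two
#' significant (seed) windows. Counts are monotone non-increasing as the
#' threshold tightens.
#'
#' @param results,windows As for [call_dmrs()].
#' @param thresholds Seed p-value thresholds, sorted descending (default
#'   `10^-(3:7)`).
#' @param ... Further arguments passed to [call_dmrs()].
#' @return A tibble `threshold`, `all_dmrs`, `multiple_window_dmrs`.
#' @export
threshold_table <- function(results, windows,
                            thresholds = c(1e-3, 1e-4, 1e-5, 1e-6, 1e-7),
                            ...) {
  if (is.unsorted(rev(thresholds))) {
    stop_input("`thresholds` must be sorted descending.")
  }
  purrr::map(thresholds, function(th) {
    s <- call_dmrs(results, windows, sig_threshold = th, ...)
    tibble::tibble(
      threshold = th,
      all_dmrs = nrow(s),
      multiple_window_dmrs = sum(s$sig_windows >= 2)
    )
  }) |>
    dplyr::bind_rows()
}

#' Histogram of significant windows per DMR
#'
#' @param dmrs A `dmr_set`.
#' @return A tibble `sig_windows`, `n`; `sum(n)` equals the number of
#'   DMRs.
#' @export
multiwindow_histogram <- function(dmrs) {
  check_df_cols(dmrs, "sig_windows", "dmrs")
  dmrs |>
    tibble::as_tibble() |>
    dplyr::count(.data$sig_windows, name = "n") |>
    dplyr::arrange(.data$sig_windows)
}

#' DMR CpG-density and length histograms
#'
#' CpG density (CpG per 100 bp, summed over member windows and divided by
#' the span length) is binned at integer edges `[k, k + 1)`; length is
#' binned in 1-kb bins.
#'
#' @param dmrs A `dmr_set`.
#' @return A tibble `feature` (`"cpg_per_100bp"` or `"length_kb"`),
#'   `bin` (left edge), `n`.
#' @export
dmr_feature_stats <- function(dmrs) {
  check_df_cols(dmrs, c("cpg_per_100bp", "length_kb"), "dmrs")
  dplyr::bind_rows(
    tibble::as_tibble(dmrs) |>
      dplyr::count(bin = floor(.data$cpg_per_100bp)) |>
      dplyr::mutate(feature = "cpg_per_100bp"),
    tibble::as_tibble(dmrs) |>
      dplyr::count(bin = floor(.data$length_kb)) |>
      dplyr::mutate(feature = "length_kb")
  ) |>
    dplyr::select("feature", "bin", "n") |>
    dplyr::arrange(.data$feature, .data$bin)
}

#' Chromosomal clusters of DMRs
#'
#' Single-linkage chaining: consecutive DMRs on a chromosome whose gap is
#' at most `max_gap` bp join a cluster; clusters with at least `min_size`
#' members are reported.
#'
#' @param dmrs A `dmr_set`.
#' @param max_gap Maximum inter-DMR gap in bp (default 2 Mb).
#' @param min_size Minimum cluster size (default 3).
#' @return A tibble `cluster_id`, `chrom`, `start`, `end`, `n_dmrs`,
#'   `dmr_ids` (list-column).
#' @export
find_clusters <- function(dmrs, max_gap = 2e6, min_size = 3) {
  check_number(max_gap, "max_gap", min = 1)
  check_number(min_size, "min_size", min = 2)
  empty <- tibble::tibble(
    cluster_id = character(), chrom = character(), start = integer(),
    end = integer(), n_dmrs = integer(), dmr_ids = list()
  )
  if (!nrow(dmrs)) {
    return(empty)
  }
  d <- dplyr::arrange(tibble::as_tibble(dmrs), .data$chrom, .data$start)
  d <- d |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      gap = .data$start - dplyr::lag(cummax(.data$end)),
      new_cluster = is.na(.data$gap) | .data$gap > max_gap,
      cluster = cumsum(.data$new_cluster)
    ) |>
    dplyr::ungroup()
  out <- d |>
    dplyr::group_by(.data$chrom, .data$cluster) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      n_dmrs = dplyr::n(), dmr_ids = list(.data$dmr_id),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_dmrs >= min_size) |>
    dplyr::arrange(.data$chrom, .data$start)
  if (!nrow(out)) {
    return(empty)
  }
  out |>
    dplyr::mutate(cluster_id = sprintf("CL_%03d", dplyr::row_number())) |>
    dplyr::select("cluster_id", "chrom", "start", "end", "n_dmrs",
                  "dmr_ids")
}

#' Overlap two DMR sets
#'
#' Two DMRs are shared when their genomic spans overlap by at least 1 bp.
#' The counts partition each set: `a_only + shared_a` is the size of
#' `a`, `b_only + shared_b` the size of `b` (a DMR in one set can
#' overlap several in the other, so `shared_a` and `shared_b` may
#' differ).
#'
#' @param a,b `dmr_set` tibbles on the same genome.
#' @return A list of class `dmr_overlap` with elements `counts` (one-row
#'   tibble `a_only`, `shared_a`, `shared_b`, `b_only`), `pairs` (tibble
#'   of overlapping `dmr_id_a`, `dmr_id_b`), `a_only` and `b_only`
#'   (tibbles of the unshared DMRs).
#' @export
overlap_dmr_sets <- function(a, b) {
  check_df_cols(a, c("chrom", "start", "end", "dmr_id"), "a")
  check_df_cols(b, c("chrom", "start", "end", "dmr_id"), "b")
  lev <- union(unique(a$chrom), unique(b$chrom))
  gr <- function(x) GenomicRanges::GRanges(
    factor(x$chrom, levels = lev),
    IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
  hits <- if (nrow(a) && nrow(b)) {
    GenomicRanges::findOverlaps(gr(a), gr(b))
  } else {
    S4Vectors::Hits(nLnode = nrow(a), nRnode = nrow(b))
  }
  ia <- unique(S4Vectors::queryHits(hits))
  ib <- unique(S4Vectors::subjectHits(hits))
  structure(
    list(
      counts = tibble::tibble(
        a_only = nrow(a) - length(ia),
        shared_a = length(ia),
        shared_b = length(ib),
        b_only = nrow(b) - length(ib)
      ),
      pairs = tibble::tibble(
        dmr_id_a = a$dmr_id[S4Vectors::queryHits(hits)],
        dmr_id_b = b$dmr_id[S4Vectors::subjectHits(hits)]
      ),
      a_only = tibble::as_tibble(a)[setdiff(seq_len(nrow(a)), ia), ],
      b_only = tibble::as_tibble(b)[setdiff(seq_len(nrow(b)), ib), ]
    ),
    class = "dmr_overlap"
  )
}

#' @export
print.dmr_overlap <- function(x, ...) {
  cat("<dmr_overlap>\n")
  print(x$counts)
  invisible(x)
}

#' Write DMRs as BED6(+) and TSV
#'
#' BED columns: chrom, start, end, name, score (-log10 min p, capped at
#' 1000), strand "."; the TSV carries the full feature table (the
#' list-column of member windows is serialized as a comma-joined string).
#'
#' @param dmrs A `dmr_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmrs_bed <- function(dmrs, path) {
  check_df_cols(dmrs, c("chrom", "start", "end", "dmr_id", "min_p"), "dmrs")
  bed <- tibble::tibble(
    chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
    name = dmrs$dmr_id,
    score = round(pmin(-log10(dmrs$min_p), 1000), 3),
    strand = "."
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_dmrs_bed
#' @export
write_dmrs_tsv <- function(dmrs, path) {
  out <- tibble::as_tibble(dmrs)
  out$window_indices <- purrr::map_chr(
    out$window_indices, ~ paste(.x, collapse = ",")
  )
  readr::write_tsv(out, path)
  invisible(path)
}
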