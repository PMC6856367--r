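#' Randomly permute group labels, preserving group sizes
#'
#' Uniformly random reassignment of the two group labels to the samples,
#' holding the number of samples per group constant.
#'
#' @param groups Character vector of group labels (exactly two distinct
#'   values, both present).
#' @param seed Optional integer seed.
#' @return A character vector of the same length, a random relabeling
#'   with the same group sizes.
#' @export
permute_labels <- function(groups, seed = NULL) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2 || any(table(groups) == 0)) {
    stop_input("`groups` must contain two non-empty groups.")
  }
  with_seed_local(seed, sample(groups))
}

#' Permutation null distribution for the DMR count
#'
#' Repeats the full window-test-and-DMR-call analysis under random
#' reassignments of the group labels (group sizes held constant) to ask
#' whether the observed number of DMRs exceeds what label-free noise
#' produces. The dispersion is re-estimated within every permutation so
#' the null mimics the complete analysis. The empirical p-value uses the
#' add-one rule `(1 + #{null >= observed}) / (1 + n_perm)`, so its floor
#' is `1 / (1 + n_perm)` (about 0.048 for the default 20 permutations).
#'
#' @param wc A [window_counts] object.
#' @param groups Optional per-column labels; defaults to non-test-set
#'   metadata groups.
#' @param n_perm Number of permutations (default 20).
#' @param seed Optional integer seed.
#' @param sig_threshold,edge_threshold,edge_distance DMR-calling
#'   configuration, as in [call_dmrs()].
#' @param min_group_size Smallest per-group sample count for which the
#'   permutation analysis is allowed (default 3): with fewer samples the
#'   label-assignment space is too small for a meaningful null.
#' @param ... Further arguments passed to [test_all_windows()].
#' @return An object of class `dmr_permutation`: a list with
#'   `observed_dmr_count`, `null_counts`, `n_permutations`,
#'   `empirical_p`, `seed`.
#' @export
permutation_null <- function(wc, groups = NULL, n_perm = 20, seed = NULL,
                             sig_threshold = 1e-5, edge_threshold = 0.1,
                             edge_distance = NULL, min_group_size = 3,
                             ...) {
  stopifnot(inherits(wc, "window_counts"))
  check_number(n_perm, "n_perm", min = 1)
  sel <- select_training(wc, groups)
  if (any(table(sel$groups) < min_group_size)) {
    stop_input(sprintf(
      "permutation analysis needs at least %d samples per group.",
      min_group_size
    ))
  }
  full_groups <- rep(NA_character_, ncol(wc$counts))
  full_groups[sel$cols] <- sel$groups

  count_dmrs <- function(g) {
    res <- test_all_windows(wc, groups = g, ...)
    nrow(call_dmrs(res, wc$windows, sig_threshold = sig_threshold,
                   edge_threshold = edge_threshold,
                   edge_distance = edge_distance))
  }
  observed <- count_dmrs(full_groups)
  null_counts <- integer(n_perm)
  for (i in seq_len(n_perm)) {
    g <- full_groups
    g[sel$cols] <- permute_labels(sel$groups, seed = derive_seed(seed, i))
    null_counts[i] <- count_dmrs(g)
  }
  structure(
    list(
      observed_dmr_count = observed,
      null_counts = null_counts,
      n_permutations = as.integer(n_perm),
      empirical_p = (1 + sum(null_counts >= observed)) / (1 + n_perm),
      seed = seed
    ),
    class = "dmr_permutation"
  )
}

#' @export
print.dmr_permutation <- function(x, ...) {
  cat(sprintf(
    "<dmr_permutation> observed %d DMRs vs null over %d permutations (max %d); empirical p = %.4f\n",
    x$observed_dmr_count, x$n_permutations,
    if (length(x$null_counts)) max(x$null_counts) else NA_integer_,
    x$empirical_p
  ))
  invisible(x)
}

#' @describeIn permutation_null Tidy the null distribution: one row per
#'   permutation (`permutation`, `dmr_count`).
#' @param x A `dmr_permutation` object.
#' @export
tidy.dmr_permutation <- function(x, ...) {
  tibble::tibble(
    permutation = seq_along(x$null_counts),
    dmr_count = x$null_counts
  )
}

#' @describeIn permutation_null One-row summary (`observed_dmr_count`,
#'   `null_mean`, `null_max`, `n_permutations`, `empirical_p`).
#' @export
glance.dmr_permutation <- function(x, ...) {
  tibble::tibble(
    observed_dmr_count = x$observed_dmr_count,
    null_mean = mean(x$null_counts),
    null_max = max(x$null_counts),
    n_permutations = x$n_permutations,
    empirical_p = x$empirical_p
  )
}

#' Write a permutation result as TSV
#'
#' One row per permutation plus a trailing summary row (`permutation =
#' "observed"`).
#'
#' @param x A `dmr_permutation` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_permutation_tsv <- function(x, path) {
  stopifnot(inherits(x, "dmr_permutation"))
  out <- dplyr::bind_rows(
    dplyr::mutate(tidy(x), permutation = as.character(.data$permutation)),
    tibble::tibble(permutation = "observed",
                   dmr_count = x$observed_dmr_count)
  )
  readr::write_tsv(out, path)
  invisible(path)
}
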