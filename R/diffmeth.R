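#' Estimate a common negative-binomial dispersion
#'
#' Method-of-moments estimate of the dispersion phi in the NB
#' mean-variance relation `var = mu + phi * mu^2`, pooled over windows and
#' groups. Counts are first scaled to a common library size (the mean of
#' the per-sample totals); within each group and window the sample mean
#' `m` and variance `s2` satisfy `E[s2 - m] = phi * m^2` under the NB
#' model, so the ratio estimator `phi = sum(s2 - m) / sum(m^2)` (floored
#' at 0) pools all windows with squared-mean weights. Deterministic.
#'
#' @param wc A [window_counts] object.
#' @param groups Optional character vector of group labels for the
#'   columns; defaults to the non-test samples' `group` metadata.
#' @return A one-row tibble with columns `phi` and `method` (`"moment"`).
#' @export
estimate_common_dispersion <- function(wc, groups = NULL) {
  stopifnot(inherits(wc, "window_counts"))
  sel <- select_training(wc, groups)
  counts <- wc$counts[, sel$cols, drop = FALSE]
  groups <- sel$groups
  if (any(table(groups) < 2)) {
    stop_input("each group needs at least 2 samples to estimate dispersion.")
  }
  if (sum(counts) == 0) {
    return(tibble::tibble(phi = 0, method = "moment"))
  }
  lib <- wc$library_size[sel$cols]
  lib[lib <= 0] <- 1
  scaled <- sweep(counts, 2, mean(lib) / lib, `*`)
  num <- 0
  den <- 0
  for (g in unique(groups)) {
    y <- scaled[, groups == g, drop = FALSE]
    m <- rowMeans(y)
    s2 <- apply(y, 1, var)
    num <- num + sum(s2 - m)
    den <- den + sum(m^2)
  }
  phi <- if (den > 0) max(0, num / den) else 0
  tibble::tibble(phi = phi, method = "moment")
}

# resolve which columns of wc enter a two-group analysis and their labels;
# by default the non-test-set samples with their metadata groups
select_training <- function(wc, groups = NULL) {
  if (is.null(groups)) {
    if (all(is.na(wc$samples$group))) {
      stop_input("no group labels: supply `groups` or sample metadata.")
    }
    keep <- !wc$samples$test_set & !is.na(wc$samples$group)
    cols <- which(keep)
    groups <- wc$samples$group[keep]
  } else {
    if (length(groups) != ncol(wc$counts)) {
      stop_input("`groups` must have one label per sample column (use NA to drop).")
    }
    cols <- which(!is.na(groups))
    groups <- groups[cols]
  }
  if (length(unique(groups)) != 2) {
    stop_input("exactly two groups are required.")
  }
  list(cols = cols, groups = as.character(groups))
}

# conditional two-group exact test for one window.
# a = observed group-A pooled count, t = pooled total, w_a = group A's
# share of the total effective library size, size_a/size_b = NB shape of
# the pooled group totals (n_group / phi); phi = 0 gives the binomial.
exact_p_single <- function(a, t, w_a, size_a, size_b, phi,
                           rule = c("minlik", "doubletail")) {
  rule <- match.arg(rule)
  if (t == 0) {
    return(1)
  }
  k <- 0:t
  if (phi <= 0) {
    lp <- dbinom(k, t, w_a, log = TRUE)
  } else {
    lp <- dnbinom(k, size = size_a, mu = t * w_a, log = TRUE) +
      dnbinom(t - k, size = size_b, mu = t * (1 - w_a), log = TRUE)
    lp <- lp - matrixStats_logsumexp(lp)
  }
  if (rule == "minlik") {
    # sum of outcomes no more likely than observed; small slack absorbs
    # floating-point ties
    keep <- lp <= lp[a + 1] + 1e-10
    if (all(keep)) {
      return(1)
    }
    p <- sum(exp(lp[keep]))
  } else {
    lower <- sum(exp(lp[k <= a]))
    upper <- sum(exp(lp[k >= a]))
    p <- 2 * min(lower, upper)
  }
  min(p, 1)
}

matrixStats_logsumexp <- function(lp) {
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

#' Negative-binomial exact test for one window
#'
#' Two-sided exact test of equal relative coverage between two sample
#' groups, conditional on the pooled total. Counts are pooled within each
#' group; under the null the group-A total given the grand total follows
#' the convolution of two negative binomials with shapes `n_A / phi` and
#' `n_B / phi` and means proportional to the groups' summed library
#' sizes (a binomial when `phi = 0`). The two-sided p-value sums the
#' probabilities of all outcomes no more likely than the observed one
#' (minimum-likelihood rule; `"doubletail"` doubles the smaller tail
#' instead).
#'
#' The pooled-NB form is exact when library sizes are equal within each
#' group — the situation [subsample_counts()] creates — and is the
#' standard approximation otherwise.
#'
#' @param counts_a,counts_b Non-negative integer read counts for the
#'   window, one per sample in each group.
#' @param lib_a,lib_b Positive library sizes per sample.
#' @param phi Common NB dispersion (>= 0).
#' @param rule Two-sidedness rule, `"minlik"` (default) or
#'   `"doubletail"`.
#' @return A single p-value in (0, 1].
#' @examples
#' nb_exact_test(c(0, 0), c(10, 10), c(1e6, 1e6), c(1e6, 1e6), phi = 0)
#' @export
nb_exact_test <- function(counts_a, counts_b, lib_a, lib_b, phi = 0,
                          rule = c("minlik", "doubletail")) {
  rule <- match.arg(rule)
  if (length(counts_a) == 0 || length(counts_b) == 0) {
    stop_input("both groups must be non-empty.")
  }
  if (any(counts_a < 0) || any(counts_b < 0)) {
    stop_input("counts must be non-negative.")
  }
  if (any(lib_a <= 0) || any(lib_b <= 0)) {
    stop_input("library sizes must be positive.")
  }
  check_number(phi, "phi", min = 0)
  a <- sum(counts_a)
  t <- a + sum(counts_b)
  w_a <- sum(lib_a) / (sum(lib_a) + sum(lib_b))
  exact_p_single(
    a, t, w_a,
    size_a = length(counts_a) / max(phi, .Machine$double.eps),
    size_b = length(counts_b) / max(phi, .Machine$double.eps),
    phi = phi, rule = rule
  )
}

#' Test every window for differential coverage
#'
#' Runs the negative-binomial exact test on each genome window,
#' Benjamini-Hochberg-adjusts the p-values, and reports per-group
#' normalized means and a log2 fold change. Held-out (test-set) samples
#' are excluded unless explicit `groups` are given. Windows with zero
#' counts in every sample carry no information: they receive `p = 1` and
#' are excluded from the BH family (toggle with `drop_empty_from_fdr`).
#'
#' @param wc A [window_counts] object.
#' @param groups Optional per-column group labels (NA drops a column);
#'   defaults to non-test-set metadata groups. The first label in sorted
#'   order is group A (reference); log2 fold change is B over A.
#' @param phi NB dispersion; estimated with
#'   [estimate_common_dispersion()] when `NULL`.
#' @param pseudocount Reads-per-million pseudocount for the fold change
#'   (default 0.5).
#' @param rule Two-sidedness rule passed to the exact test.
#' @param drop_empty_from_fdr Exclude all-zero windows from the BH family
#'   (default TRUE).
#' @return A tibble with one row per window: `window_index`, `chrom`,
#'   `start`, `end`, `p_value`, `fdr_q`, `log2fc`, `mean_norm_A`,
#'   `mean_norm_B` (reads per million), `tested`.
#' @export
test_all_windows <- function(wc, groups = NULL, phi = NULL,
                             pseudocount = 0.5,
                             rule = c("minlik", "doubletail"),
                             drop_empty_from_fdr = TRUE) {
  stopifnot(inherits(wc, "window_counts"))
  rule <- match.arg(rule)
  check_number(pseudocount, "pseudocount", min = 0)
  sel <- select_training(wc, groups)
  glev <- sort(unique(sel$groups))
  ca <- wc$counts[, sel$cols[sel$groups == glev[1]], drop = FALSE]
  cb <- wc$counts[, sel$cols[sel$groups == glev[2]], drop = FALSE]
  la <- wc$library_size[sel$cols[sel$groups == glev[1]]]
  lb <- wc$library_size[sel$cols[sel$groups == glev[2]]]
  if (is.null(phi)) {
    phi <- estimate_common_dispersion(wc, groups)$phi
  }
  check_number(phi, "phi", min = 0)

  a <- rowSums(ca)
  t <- a + rowSums(cb)
  w_a <- sum(la) / (sum(la) + sum(lb))
  size_a <- ncol(ca) / max(phi, .Machine$double.eps)
  size_b <- ncol(cb) / max(phi, .Machine$double.eps)
  p <- rep(1, length(t))
  nz <- which(t > 0)
  for (i in nz) {
    p[i] <- exact_p_single(a[i], t[i], w_a, size_a, size_b, phi, rule)
  }

  mean_norm_a <- rowMeans(sweep(ca, 2, la / 1e6, `/`))
  mean_norm_b <- rowMeans(sweep(cb, 2, lb / 1e6, `/`))
  log2fc <- log2((mean_norm_b + pseudocount) / (mean_norm_a + pseudocount))

  tested <- if (drop_empty_from_fdr) t > 0 else rep(TRUE, length(t))
  fdr <- rep(1, length(t))
  if (any(tested)) {
    fdr[tested] <- bh_adjust(p[tested])
  }
  dplyr::bind_cols(
    wc$windows[, c("window_index", "chrom", "start", "end")],
    tibble::tibble(
      p_value = p, fdr_q = fdr, log2fc = log2fc,
      mean_norm_A = mean_norm_a, mean_norm_B = mean_norm_b,
      tested = tested
    )
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (via [stats::p.adjust()]): monotone
#' non-decreasing in p-rank and capped at 1. Input p-values must lie in
#' (0, 1].
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Numeric vector of adjusted values, same length.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) {
    return(numeric(0))
  }
  if (anyNA(p_values) || any(p_values <= 0) || any(p_values > 1)) {
    stop_input("p-values must lie in (0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Write a per-window test-result table as TSV
#'
#' @param results Tibble from [test_all_windows()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  check_df_cols(
    results,
    c("chrom", "start", "end", "p_value", "fdr_q", "log2fc"),
    "results"
  )
  readr::write_tsv(results, path)
  invisible(path)
}
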