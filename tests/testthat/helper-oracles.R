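# Independent brute-force reference implementations used to verify the
# package's fast paths. Each is written as the most literal possible
# reading of the corresponding definition.

# step-up FDR: q_(i) = min_{j >= i} p_(j) * m / j, in the original order
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(p[ord][i:m] * m / (i:m), 1)
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# two-sided conditional binomial exact test (minimum-likelihood rule),
# by full enumeration; the phi = 0 oracle for nb_exact_test
oracle_exact_binom <- function(a, t, w) {
  if (t == 0) return(1)
  pk <- dbinom(0:t, t, w)
  min(1, sum(pk[pk <= pk[a + 1] * (1 + 1e-12)]))
}

# literal single-step fixed-point DMR caller. tab: window_index, chrom,
# start, end, p_value. Returns a list of sorted member window_index
# vectors, ordered by span.
oracle_call_dmrs <- function(tab, sig, edge, dist) {
  gap <- function(s1, e1, s2, e2) max(0, s1 - e2, s2 - e1)
  span <- function(idx) c(min(tab$start[idx]), max(tab$end[idx]))
  seeds <- which(tab$p_value < sig)
  if (!length(seeds)) return(list())
  comps <- as.list(seeds)

  # stage 1: merge seed components within `dist`, one pair at a time
  repeat {
    done <- TRUE
    for (i in seq_along(comps)) {
      for (j in seq_along(comps)) {
        if (i >= j) next
        if (tab$chrom[comps[[i]][1]] != tab$chrom[comps[[j]][1]]) next
        si <- span(comps[[i]]); sj <- span(comps[[j]])
        if (gap(si[1], si[2], sj[1], sj[2]) <= dist) {
          comps[[i]] <- c(comps[[i]], comps[[j]])
          comps[[j]] <- NULL
          done <- FALSE
          break
        }
      }
      if (!done) break
    }
    if (done) break
  }

  # stage 2: absorb one candidate at a time; merge touching components
  cands <- which(tab$p_value < edge)
  repeat {
    done <- TRUE
    for (i in seq_along(comps)) {
      s <- span(comps[[i]])
      for (w in cands) {
        if (w %in% comps[[i]]) next
        if (tab$chrom[w] != tab$chrom[comps[[i]][1]]) next
        if (gap(tab$start[w], tab$end[w], s[1], s[2]) <= dist) {
          comps[[i]] <- c(comps[[i]], w)
          done <- FALSE
          break
        }
      }
      if (!done) break
    }
    if (!done) next
    for (i in seq_along(comps)) {
      for (j in seq_along(comps)) {
        if (i >= j) next
        if (tab$chrom[comps[[i]][1]] != tab$chrom[comps[[j]][1]]) next
        si <- span(comps[[i]]); sj <- span(comps[[j]])
        if (gap(si[1], si[2], sj[1], sj[2]) <= 0) {
          comps[[i]] <- c(comps[[i]], comps[[j]])
          comps[[j]] <- NULL
          done <- FALSE
          break
        }
      }
      if (!done) break
    }
    if (done) break
  }
  comps <- lapply(comps, function(x) sort(tab$window_index[unique(x)]))
  comps[order(vapply(comps, min, numeric(1)))]
}

# random per-window p-value tables over a toy tiled genome, with enough
# sub-threshold mass to exercise seeding, extension and merging
random_result_table <- function(n_windows, window_size = 1000,
                                n_chroms = 2) {
  chrom <- sort(rep_len(paste0("chr", seq_len(n_chroms)), n_windows))
  pos <- unlist(lapply(table(chrom), function(n) seq_len(n) - 1L))
  p <- runif(n_windows)
  hot <- runif(n_windows) < 0.15
  p[hot] <- 10^(-runif(sum(hot), 0, 8))
  tibble::tibble(
    window_index = seq_len(n_windows) - 1L,
    chrom = chrom,
    start = as.integer(pos * window_size),
    end = as.integer((pos + 1) * window_size),
    p_value = p,
    log2fc = stats::rnorm(n_windows),
    cpg_count = stats::rpois(n_windows, 20)
  )
}

# small deterministic window/result pair for hand-traced DMR examples:
# 20 contiguous 1000 bp windows on one chromosome, all p = 0.5
hand_windows <- function(n = 20, window_size = 1000) {
  tibble::tibble(
    chrom = "chr1",
    start = as.integer((seq_len(n) - 1) * window_size),
    end = as.integer(seq_len(n) * window_size),
    window_index = seq_len(n) - 1L,
    cpg_count = 10L
  )
}

hand_results <- function(windows, p = 0.5, log2fc = 0) {
  tibble::tibble(
    window_index = windows$window_index,
    p_value = rep_len(p, nrow(windows)),
    log2fc = rep_len(log2fc, nrow(windows))
  )
}

# window_counts built directly from a matrix, for unit tests
make_wc <- function(counts, window_size = 1000, groups = NULL,
                    library_size = NULL, test_set = NULL) {
  n <- nrow(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("S%02d", seq_len(ncol(counts)))
  }
  windows <- tibble::tibble(
    chrom = "chr1",
    start = as.integer((seq_len(n) - 1) * window_size),
    end = as.integer(seq_len(n) * window_size),
    window_index = seq_len(n) - 1L,
    cpg_count = 5L
  )
  samples <- tibble::tibble(
    sample_id = colnames(counts),
    group = if (is.null(groups)) NA_character_ else groups,
    test_set = if (is.null(test_set)) FALSE else test_set
  )
  window_counts(
    windows, counts,
    library_size %||% stats::setNames(colSums(counts), colnames(counts)),
    samples
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
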