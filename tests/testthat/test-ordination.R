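sim_features <- function(seed = 1, n_feat = 30, shift = 6) {
  set.seed(seed)
  base <- matrix(rnorm(n_feat * 12, 10, 1), nrow = n_feat)
  base[1:10, 7:12] <- base[1:10, 7:12] + shift
  colnames(base) <- sprintf("S%02d", 1:12)
  rownames(base) <- as.character(seq_len(n_feat) - 1)
  base
}

test_that("PC1 separates two well-separated synthetic groups", {
  x <- sim_features()
  groups <- rep(c("groupA", "groupB"), each = 6)
  fit <- fit_pca(x, groups)
  s <- tidy(fit)
  rA <- range(s$PC1[s$group == "groupA"])
  rB <- range(s$PC1[s$group == "groupB"])
  expect_true(rA[2] < rB[1] || rB[2] < rA[1])
  expect_equal(ncol(fit$loadings), 3)
  # loadings are orthonormal, variance non-increasing
  expect_equal(crossprod(fit$loadings), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(fit$explained_variance) <= 1e-10))
})

test_that("duplicate sample columns get identical scores", {
  x <- sim_features(2)
  x <- cbind(x, dup = x[, 1])
  fit <- fit_pca(x, c(rep(c("groupA", "groupB"), each = 6), "groupA"))
  s <- fit$training_scores
  expect_equal(unname(s[1, ]), unname(s[13, ]))
})

test_that("constant feature sets are rejected", {
  x <- matrix(5, nrow = 4, ncol = 6,
              dimnames = list(1:4, sprintf("S%d", 1:6)))
  expect_error(fit_pca(x, rep(c("groupA", "groupB"), each = 3)),
               class = "medipdmr_input_error")
})

test_that("projection maps training samples onto their own scores", {
  x <- sim_features(3)
  groups <- rep(c("groupA", "groupB"), each = 6)
  fit <- fit_pca(x, groups)
  proj <- project_samples(fit, x)
  expect_equal(as.matrix(proj[, c("PC1", "PC2", "PC3")]),
               unname(fit$training_scores), tolerance = 1e-10,
               ignore_attr = TRUE)
  # the feature-mean vector projects to the origin
  origin <- project_samples(fit, matrix(fit$feature_means,
                                        dimnames = list(rownames(x), "m")))
  expect_equal(unlist(origin[, c("PC1", "PC2", "PC3")]),
               c(PC1 = 0, PC2 = 0, PC3 = 0), tolerance = 1e-10)
})

test_that("projection is affine in its input", {
  x <- sim_features(5)
  fit <- fit_pca(x, rep(c("groupA", "groupB"), each = 6))
  u <- x[, 1, drop = FALSE]; v <- x[, 8, drop = FALSE]
  alpha <- 0.3
  mix <- alpha * u + (1 - alpha) * v
  colnames(mix) <- "mix"
  pm <- as.matrix(project_samples(fit, mix)[, c("PC1", "PC2", "PC3")])
  pu <- as.matrix(project_samples(fit, u)[, c("PC1", "PC2", "PC3")])
  pv <- as.matrix(project_samples(fit, v)[, c("PC1", "PC2", "PC3")])
  expect_equal(pm, alpha * pu + (1 - alpha) * pv, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("scores are invariant to a consistent feature reordering", {
  x <- sim_features(6)
  fit <- fit_pca(x, rep(c("groupA", "groupB"), each = 6))
  perm <- sample(nrow(x))
  fit2 <- fit_pca(x[perm, ], rep(c("groupA", "groupB"), each = 6))
  expect_equal(abs(fit$training_scores), abs(fit2$training_scores),
               tolerance = 1e-8)
})

test_that("rank-3 reconstruction attains the Eckart-Young optimum", {
  x <- sim_features(7)
  fit <- fit_pca(x, rep(c("groupA", "groupB"), each = 6))
  centered <- t(x) - rep(fit$feature_means, each = ncol(x))
  recon <- fit$training_scores %*% t(fit$loadings)
  best <- sum((centered - recon)^2)
  set.seed(99)
  for (i in 1:20) {
    # random rank-3 factorization via perturbed random projections
    q <- qr.Q(qr(matrix(rnorm(nrow(x) * 3), ncol = 3)))
    alt <- (centered %*% q) %*% t(q)
    expect_lte(best, sum((centered - alt)^2) + 1e-8)
  }
})

test_that("held-out samples are assigned to the nearest group centroid", {
  x <- sim_features(8)
  groups <- rep(c("groupA", "groupB"), each = 6)
  fit <- fit_pca(x, groups)
  # new samples from group B's generative recipe
  set.seed(10)
  newx <- matrix(rnorm(30 * 2, 10, 1), nrow = 30)
  newx[1:10, ] <- newx[1:10, ] + 6
  colnames(newx) <- c("T1", "T2")
  rownames(newx) <- rownames(x)
  assigned <- assign_group(fit, project_samples(fit, newx))
  expect_true(all(assigned$assigned_group == "groupB"))
  expect_true(all(assigned$margin > 0))
  # a point exactly at a centroid belongs to that group, margin =
  # inter-centroid distance
  centA <- colMeans(fit$training_scores[groups == "groupA", ])
  centB <- colMeans(fit$training_scores[groups == "groupB", ])
  at_cent <- tibble::tibble(sample_id = "c", PC1 = centA[1],
                            PC2 = centA[2], PC3 = centA[3])
  out <- assign_group(fit, at_cent)
  expect_equal(out$assigned_group, "groupA")
  expect_equal(out$margin, sqrt(sum((centA - centB)^2)))
  # equidistant points break to the first group and are flagged
  mid <- (centA + centB) / 2
  tie <- assign_group(fit, tibble::tibble(sample_id = "t", PC1 = mid[1],
                                          PC2 = mid[2], PC3 = mid[3]))
  expect_equal(tie$assigned_group, "groupA")
  expect_true(tie$ambiguous)
})

test_that("the dmr feature matrix supports window and per-DMR modes", {
  w <- hand_windows()
  set.seed(12)
  y <- matrix(rpois(20 * 4, 50), ncol = 4,
              dimnames = list(NULL, sprintf("S%d", 1:4)))
  wc <- window_counts(w, y, setNames(colSums(y), colnames(y)))
  res <- hand_results(w, p = 0.5, log2fc = 1)
  res$p_value[3:4] <- 1e-7
  res$p_value[10] <- 1e-8
  dmrs <- call_dmrs(res, w)
  fm <- dmr_feature_matrix(wc, dmrs)
  expect_equal(nrow(fm), 3) # three member windows across two DMRs
  fd <- dmr_feature_matrix(wc, dmrs, mode = "dmr_mean")
  expect_equal(nrow(fd), 2)
  expect_equal(fd["DMR_0001", ], colMeans(fm[c("2", "3"), ]))
})

test_that("model serialization writes means and loadings tables", {
  x <- sim_features(9)
  fit <- fit_pca(x, rep(c("groupA", "groupB"), each = 6))
  stem <- file.path(withr::local_tempdir(), "model")
  write_pca_tsv(fit, stem)
  means <- readr::read_tsv(paste0(stem, "_means.tsv"),
                           show_col_types = FALSE)
  expect_equal(means$mean, unname(fit$feature_means))
  loads <- readr::read_tsv(paste0(stem, "_loadings.tsv"),
                           show_col_types = FALSE)
  expect_equal(loads$PC1, unname(fit$loadings[, 1]))
})
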