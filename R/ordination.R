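#' Build the RPKM feature matrix over DMR windows
#'
#' The biomarker features are the RPKM read depths of the DMR member
#' windows. In the default `"window"` mode each member window is one
#' feature (preserving multi-window DMR structure); `"dmr_mean"`
#' averages the member-window RPKM within each DMR to give one feature
#' per DMR.
#'
#' @param wc A [window_counts] object (all samples, including test-set).
#' @param dmrs A `dmr_set` from [call_dmrs()].
#' @param mode `"window"` (default) or `"dmr_mean"`.
#' @return A numeric feature x sample matrix with feature ids as row
#'   names (window indices or DMR ids).
#' @export
dmr_feature_matrix <- function(wc, dmrs, mode = c("window", "dmr_mean")) {
  mode <- match.arg(mode)
  if (!nrow(dmrs)) {
    stop_input("the DMR set is empty: no features to extract.")
  }
  wi <- sort(unique(unlist(dmrs$window_indices)))
  mat <- rpkm(wc, rows = wi)
  if (mode == "window") {
    return(mat)
  }
  out <- t(vapply(seq_len(nrow(dmrs)), function(i) {
    colMeans(mat[as.character(dmrs$window_indices[[i]]), , drop = FALSE])
  }, numeric(ncol(mat))))
  rownames(out) <- dmrs$dmr_id
  out
}

#' Fit a principal-component biomarker model on training samples
#'
#' Mean-centers the features across the training samples (no variance
#' scaling: RPKM is already on a common scale), takes the singular value
#' decomposition, and retains the first three components (fewer when
#' rank-limited). Component signs are fixed by making the
#' largest-magnitude loading of each component positive, so output files
#' are reproducible. Held-out samples must be projected with
#' [project_samples()]; they never influence the means or loadings.
#'
#' @param features Numeric feature x sample matrix (e.g. from
#'   [dmr_feature_matrix()]), training samples only.
#' @param groups Character vector of group labels, one per training
#'   sample (column).
#' @param n_components Number of components to retain (default 3).
#' @return An object of class `dmr_pca`: feature means, loadings
#'   (feature x component), per-component explained variance, training
#'   scores and group labels.
#' @export
fit_pca <- function(features, groups, n_components = 3) {
  features <- as.matrix(features)
  if (ncol(features) < 3) {
    stop_input("at least 3 training samples are required.")
  }
  if (nrow(features) < 1) {
    stop_input("at least one feature is required.")
  }
  if (length(groups) != ncol(features)) {
    stop_input("`groups` must have one label per sample column.")
  }
  x <- t(features) # samples x features
  if (all(apply(x, 2, var) == 0)) {
    stop_input("all features are constant across samples: nothing to fit.")
  }
  n_components <- min(n_components, ncol(x), nrow(x) - 1L)
  fit <- prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  k <- ncol(fit$rotation)
  # sign convention: largest-|loading| entry of each component positive
  flip <- vapply(seq_len(k), function(j) {
    v <- fit$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  loadings <- sweep(fit$rotation, 2, flip, `*`)
  scores <- sweep(fit$x, 2, flip, `*`)
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(k))
  structure(
    list(
      feature_ids = rownames(features) %||%
        as.character(seq_len(nrow(features))),
      feature_means = fit$center,
      loadings = loadings,
      explained_variance = fit$sdev[seq_len(k)]^2,
      training_scores = scores,
      training_groups = as.character(groups),
      sample_ids = colnames(features) %||%
        as.character(seq_len(ncol(features)))
    ),
    class = "dmr_pca"
  )
}

#' @export
print.dmr_pca <- function(x, ...) {
  ev <- x$explained_variance / sum(x$explained_variance)
  cat(sprintf(
    "<dmr_pca> %d features, %d training samples, %d components (%s of retained variance)\n",
    length(x$feature_means), nrow(x$training_scores), ncol(x$loadings),
    paste(sprintf("%.0f%%", 100 * ev), collapse = "/")
  ))
  invisible(x)
}

#' Project held-out samples onto a fitted component space
#'
#' Coordinates are `(x - feature_means) %*% loadings`: a held-out copy
#' of a training sample maps exactly onto that sample's training score,
#' and projecting the feature-mean vector gives the origin.
#'
#' @param model A `dmr_pca` from [fit_pca()].
#' @param new_features Numeric feature x sample matrix over the same
#'   features (same order) as the training matrix.
#' @return A tibble with `sample_id` and one column per component.
#' @export
project_samples <- function(model, new_features) {
  stopifnot(inherits(model, "dmr_pca"))
  new_features <- as.matrix(new_features)
  if (nrow(new_features) != length(model$feature_means)) {
    stop_input("`new_features` must cover the model's features.")
  }
  if (!is.null(rownames(new_features)) &&
      !identical(rownames(new_features), model$feature_ids)) {
    stop_input("`new_features` rows must match the model's features in order.")
  }
  coords <- t(new_features - model$feature_means) %*% model$loadings
  tibble::as_tibble(coords) |>
    dplyr::mutate(
      sample_id = colnames(new_features) %||%
        as.character(dplyr::row_number()),
      .before = 1
    )
}

#' Assign projected samples to the nearest training-group centroid
#'
#' Each sample is assigned to the group whose training-score centroid is
#' nearest in Euclidean distance over the retained components. The
#' margin is the distance difference between the two centroids; an exact
#' tie is broken toward the first group in sorted order and flagged
#' ambiguous.
#'
#' @param model A `dmr_pca` with training group labels.
#' @param coords A tibble of projected coordinates from
#'   [project_samples()] (or the training scores).
#' @return `coords` with added columns `assigned_group`, `margin`,
#'   `ambiguous`.
#' @export
assign_group <- function(model, coords) {
  stopifnot(inherits(model, "dmr_pca"))
  pcs <- colnames(model$loadings)
  check_df_cols(coords, pcs, "coords")
  lev <- sort(unique(model$training_groups))
  if (length(lev) != 2) {
    stop_input("the model must carry exactly two training groups.")
  }
  centroids <- vapply(lev, function(g) {
    colMeans(model$training_scores[model$training_groups == g, ,
                                   drop = FALSE])
  }, numeric(length(pcs)))
  xy <- as.matrix(coords[, pcs])
  d1 <- sqrt(rowSums(sweep(xy, 2, centroids[, 1])^2))
  d2 <- sqrt(rowSums(sweep(xy, 2, centroids[, 2])^2))
  dplyr::mutate(
    coords,
    assigned_group = ifelse(d1 <= d2, lev[1], lev[2]),
    margin = abs(d1 - d2),
    ambiguous = d1 == d2
  )
}

#' @describeIn fit_pca Tidy the training scores: one row per sample with
#'   `sample_id`, `group` and the component coordinates.
#' @param x A `dmr_pca` object.
#' @param ... Unused.
#' @export
tidy.dmr_pca <- function(x, ...) {
  tibble::as_tibble(x$training_scores) |>
    dplyr::mutate(
      sample_id = x$sample_ids,
      group = x$training_groups,
      .before = 1
    )
}

#' @describeIn fit_pca One-row summary: feature and component counts and
#'   the fraction of retained variance per component.
#' @export
glance.dmr_pca <- function(x, ...) {
  ev <- x$explained_variance
  tibble::tibble(
    n_features = length(x$feature_means),
    n_training_samples = nrow(x$training_scores),
    n_components = ncol(x$loadings),
    prop_variance_pc1 = ev[1] / sum(ev)
  )
}

#' Serialize / restore a fitted component model as TSV
#'
#' Writes two files: `<stem>_means.tsv` (feature id, mean) and
#' `<stem>_loadings.tsv` (feature id, one column per component).
#'
#' @param model A `dmr_pca`.
#' @param stem Output path stem.
#' @return The two paths, invisibly.
#' @export
write_pca_tsv <- function(model, stem) {
  stopifnot(inherits(model, "dmr_pca"))
  p1 <- paste0(stem, "_means.tsv")
  p2 <- paste0(stem, "_loadings.tsv")
  readr::write_tsv(
    tibble::tibble(feature_id = model$feature_ids,
                   mean = model$feature_means),
    p1
  )
  readr::write_tsv(
    dplyr::bind_cols(
      tibble::tibble(feature_id = model$feature_ids),
      tibble::as_tibble(model$loadings)
    ),
    p2
  )
  invisible(c(p1, p2))
}
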