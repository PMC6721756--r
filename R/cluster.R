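# Epsilon-centering of knockdown fold-change profiles, calibration of
# epsilon against the predefined categories, and heatmap-ready ordering.

#' Knockdown fold-change profiles of classified genes
#'
#' Joins the two knockdown log2 fold changes onto the category assignments,
#' producing the 2-D profile clustered downstream.
#'
#' @param assignments A `category_assignment` (see [classify_genes()]).
#' @param stat2,irf9 The knockdown `GeneTestResult` tables.
#' @return A data.frame with `gene_id`, `fc_stat2`, `fc_irf9`, `category`.
#' @export
fc_profiles <- function(assignments, stat2, irf9) {
  stopifnot(inherits(assignments, "category_assignment"))
  a <- assignments$assignments
  prof <- data.frame(
    gene_id = a$gene_id,
    fc_stat2 = stat2$log2fc[match(a$gene_id, stat2$gene_id)],
    fc_irf9 = irf9$log2fc[match(a$gene_id, irf9$gene_id)],
    category = a$category,
    stringsAsFactors = FALSE
  )
  # genes missing from a knockdown table carry no measured effect there
  prof$fc_stat2[is.na(prof$fc_stat2)] <- 0
  prof$fc_irf9[is.na(prof$fc_irf9)] <- 0
  prof
}

#' @keywords internal
validate_profiles <- function(profiles) {
  stopifnot(is.data.frame(profiles),
            all(c("gene_id", "fc_stat2", "fc_irf9", "category") %in%
                  names(profiles)))
  if (nrow(profiles) == 0L) stop("profile set is empty")
  if (anyNA(profiles$fc_stat2) || anyNA(profiles$fc_irf9) ||
      any(!is.finite(profiles$fc_stat2)) ||
      any(!is.finite(profiles$fc_irf9))) {
    stop("fold-change profiles must be finite")
  }
  invisible(profiles)
}

#' Category centroids and their pairwise distances
#'
#' @param profiles Profile data.frame (see [fc_profiles()]).
#' @return A list with `centroids` (data.frame: `category`, `fc_stat2`,
#'   `fc_irf9`) and `distances` (symmetric Euclidean distance matrix between
#'   centroids).
#' @export
category_centroids <- function(profiles) {
  validate_profiles(profiles)
  cats <- sort(unique(profiles$category))
  cent <- t(vapply(cats, function(cc) {
    sel <- profiles$category == cc
    c(mean(profiles$fc_stat2[sel]), mean(profiles$fc_irf9[sel]))
  }, numeric(2)))
  centroids <- data.frame(category = cats,
                          fc_stat2 = cent[, 1L], fc_irf9 = cent[, 2L],
                          row.names = NULL, stringsAsFactors = FALSE)
  d <- as.matrix(stats::dist(cent))
  dimnames(d) <- list(cats, cats)
  list(centroids = centroids, distances = d)
}

#' Epsilon-centering transformation
#'
#' Shifts each gene's knockdown fold-change profile by `epsilon` times its
#' own category's mean profile, coordinate-wise:
#' `FC_new = FC_old - epsilon * FC_category`. `epsilon = 0` is the identity;
#' `epsilon = 1` centres every category at the origin; since the
#' transformed centroid is `(1 - epsilon)` times the original, negative
#' values push centroids apart.
#'
#' @param profiles Profile data.frame (see [fc_profiles()]).
#' @param epsilon Scalar transformation strength.
#' @return The profiles with `fc_stat2` and `fc_irf9` transformed.
#' @export
epsilon_transform <- function(profiles, epsilon) {
  validate_profiles(profiles)
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, is.finite(epsilon))
  cent <- category_centroids(profiles)$centroids
  i <- match(profiles$category, cent$category)
  profiles$fc_stat2 <- profiles$fc_stat2 - epsilon * cent$fc_stat2[i]
  profiles$fc_irf9 <- profiles$fc_irf9 - epsilon * cent$fc_irf9[i]
  profiles
}

#' @keywords internal
profile_tree <- function(profiles, linkage = "average") {
  m <- as.matrix(profiles[, c("fc_stat2", "fc_irf9")])
  rownames(m) <- profiles$gene_id
  stats::hclust(stats::dist(m, method = "euclidean"), method = linkage)
}

#' Calibrate the epsilon-centering against the predefined categories
#'
#' For each epsilon on the grid: transform the profiles, build a Euclidean
#' hierarchical tree, cut it into as many clusters as there are nonempty
#' categories, and score the agreement between the cut and the predefined
#' category labels with the adjusted Rand index (ARI). Returns the epsilon
#' maximising the ARI (ties broken towards the smallest `|epsilon|`, then
#' the smallest epsilon), together with the transformed profiles, the tree
#' and its leaf order.
#'
#' With a single nonempty category the agreement is undefined; `epsilon = 0`
#' is returned with `agreement = NA`.
#'
#' @param profiles Profile data.frame (see [fc_profiles()]).
#' @param grid Numeric `c(lo, hi, step)` describing the epsilon grid.
#' @param linkage Linkage method for [stats::hclust()].
#' @return A list of class `epsilon_fit`: `epsilon`, `agreement` (ARI),
#'   `grid` (data.frame epsilon vs ARI), `profiles` (transformed at the
#'   best epsilon), `tree`, `leaf_order` (gene ids in dendrogram order),
#'   `k` (number of clusters cut).
#' @export
calibrate_epsilon <- function(profiles, grid = c(-5, 5, 0.05),
                              linkage = "average") {
  validate_profiles(profiles)
  stopifnot(is.numeric(grid), length(grid) == 3L, grid[3L] > 0,
            grid[1L] <= grid[2L])
  eps_grid <- seq(grid[1L], grid[2L], by = grid[3L])
  if (length(eps_grid) == 0L) stop("epsilon grid is empty")
  labels <- profiles$category
  k <- length(unique(labels))
  if (k < 2L || nrow(profiles) < 3L) {
    fit <- list(epsilon = 0, agreement = NA_real_,
                grid = data.frame(epsilon = eps_grid, ari = NA_real_),
                profiles = profiles,
                tree = if (nrow(profiles) >= 2L) profile_tree(profiles,
                                                              linkage),
                leaf_order = profiles$gene_id, k = k)
    return(structure(fit, class = "epsilon_fit"))
  }
  ari <- vapply(eps_grid, function(eps) {
    tp <- epsilon_transform(profiles, eps)
    cut <- stats::cutree(profile_tree(tp, linkage), k = k)
    mclust::adjustedRandIndex(cut, labels)
  }, numeric(1))
  # max ARI; ties -> smallest |epsilon|, then smallest epsilon
  best <- which(ari > max(ari) - 1e-12)
  best <- best[order(abs(eps_grid[best]), eps_grid[best])][1L]
  eps <- eps_grid[best]
  tp <- epsilon_transform(profiles, eps)
  tree <- profile_tree(tp, linkage)
  structure(list(epsilon = eps, agreement = ari[best],
                 grid = data.frame(epsilon = eps_grid, ari = ari),
                 profiles = tp, tree = tree,
                 leaf_order = tree$labels[tree$order], k = k),
            class = "epsilon_fit")
}

#' @export
print.epsilon_fit <- function(x, ...) {
  cat(sprintf(
    "epsilon_fit: epsilon = %g, ARI = %s over %d genes in %d categories\n",
    x$epsilon, format(x$agreement, digits = 4), nrow(x$profiles), x$k))
  invisible(x)
}

#' Export the calibrated profiles in heatmap order
#'
#' Rows are the transformed profiles ordered by the dendrogram leaf order
#' of the calibrated tree, with the category as a row annotation; ready to
#' be rendered as a heatmap or written as TSV.
#'
#' @param fit An `epsilon_fit` from [calibrate_epsilon()].
#' @param path Optional TSV output path.
#' @return A data.frame (`gene_id`, `fc_stat2`, `fc_irf9`, `category`) in
#'   leaf order, invisibly if `path` is given.
#' @export
heatmap_export <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "epsilon_fit"))
  ord <- match(fit$leaf_order, fit$profiles$gene_id)
  out <- fit$profiles[ord, c("gene_id", "fc_stat2", "fc_irf9", "category")]
  rownames(out) <- NULL
  if (!is.null(path)) {
    write_tsv_file(out, path)
    return(invisible(out))
  }
  out
}

#' Render the calibrated profile heatmap
#'
#' Thin wrapper around \pkg{pheatmap} drawing the leaf-ordered transformed
#' profiles with a category annotation; requires the suggested package.
#'
#' @param fit An `epsilon_fit`.
#' @param filename Optional file to render into (passed to
#'   [pheatmap::pheatmap()]).
#' @return The pheatmap object, invisibly.
#' @export
plot_heatmap <- function(fit, filename = NA) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("plot_heatmap requires the 'pheatmap' package")
  }
  ordered <- heatmap_export(fit)
  m <- as.matrix(ordered[, c("fc_stat2", "fc_irf9")])
  rownames(m) <- ordered$gene_id
  ann <- data.frame(category = ordered$category, row.names = ordered$gene_id)
  ph <- pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                           annotation_row = ann, show_rownames = FALSE,
                           filename = filename)
  invisible(ph)
}
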