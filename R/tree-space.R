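# Tree-space concordance analysis: principal-coordinate projection of the
# Kendall-Colijn distance matrix, hierarchical cluster discovery at a
# dendrogram height cut-off, and nomination of the loci whose gene trees
# share a cluster with a designated reference tree (e.g. the consensus of
# the species trees).

#' Principal-coordinate (classical MDS) projection of a distance matrix
#'
#' Double-centers `-D^2 / 2` and eigendecomposes it; axes are ordered by
#' decreasing eigenvalue and the first `n_axes` positive-eigenvalue axes are
#' retained. Negative eigenvalues are dropped with a warning; if fewer than
#' `n_axes` positive eigenvalues exist, fewer axes are returned with a
#' warning.
#'
#' @param d Square symmetric distance matrix (zero diagonal).
#' @param n_axes Number of axes to retain (default 5).
#' @return A list with `coordinates` (matrix, rownames from `d`) and
#'   `eigenvalues` (all eigenvalues, decreasing).
#' @export
project_pcoa <- function(d, n_axes = 5L) {
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d), n_axes >= 1L)
  n <- nrow(d)
  mds <- suppressWarnings(cmdscale(stats::as.dist(d), k = max(1L, min(n_axes, n - 1L)),
                                   eig = TRUE))
  ev <- mds$eig
  tol <- max(abs(ev)) * 1e-9 + 1e-12
  npos <- sum(ev > tol)
  if (any(ev < -tol)) {
    warn(sprintf("Distance matrix is not exactly Euclidean: %d negative eigenvalue(s) dropped.",
                 sum(ev < -tol)))
  }
  keep <- min(n_axes, max(npos, 1L))
  if (npos < n_axes) {
    warn(sprintf("Only %d positive eigenvalue(s); returning %d axis/axes instead of %d.",
                 npos, keep, n_axes))
  }
  if (npos == 0L || ncol(mds$points) == 0L) {
    coords <- matrix(0, nrow = n, ncol = 1L,
                     dimnames = list(rownames(d), "PC1"))
  } else {
    coords <- mds$points[, seq_len(min(keep, ncol(mds$points))), drop = FALSE]
    colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
    rownames(coords) <- rownames(d)
  }
  list(coordinates = coords, eigenvalues = ev)
}

#' Cluster trees in projected tree space
#'
#' Agglomerative clustering (Ward by default) on Euclidean distances in the
#' projected coordinates, cut at `cutoff_height`. When `cutoff_height` is
#' `NULL` the dendrogram is cut in the middle of the largest gap between
#' successive merge heights (automatic cut-off).
#'
#' @param coordinates Numeric matrix of projected coordinates (rows = trees).
#' @param cutoff_height Dendrogram cut height (default 100), or `NULL` for
#'   the automatic largest-gap cut.
#' @param linkage One of `"ward"`, `"complete"`, `"average"`.
#' @return Integer cluster labels named by tree id, numbered by first
#'   appearance in row order. Attribute `hclust` holds the dendrogram,
#'   attribute `cutoff_height` the height used.
#' @export
cluster_trees <- function(coordinates, cutoff_height = 100, linkage = "ward") {
  stopifnot(is.matrix(coordinates), all(is.finite(coordinates)))
  method <- switch(match.arg(linkage, c("ward", "complete", "average")),
                   ward = "ward.D2", complete = "complete", average = "average")
  n <- nrow(coordinates)
  if (n == 1L) {
    labels <- setNames(1L, rownames(coordinates))
    attr(labels, "cutoff_height") <- cutoff_height %||% 0
    return(labels)
  }
  hc <- hclust(dist(coordinates), method = method)
  if (is.null(cutoff_height)) {
    h <- sort(hc$height)
    if (length(h) == 1L) {
      cutoff_height <- h / 2
    } else {
      gaps <- diff(c(0, h))
      gi <- which.max(gaps)
      cutoff_height <- (c(0, h)[gi] + h[gi]) / 2
    }
  }
  raw <- cutree(hc, h = cutoff_height)
  # renumber by first appearance in input order
  labels <- match(raw, unique(raw))
  names(labels) <- rownames(coordinates)
  attr(labels, "hclust") <- hc
  attr(labels, "cutoff_height") <- cutoff_height
  labels
}

#' Trees sharing a cluster with a reference tree
#'
#' The marker-nomination rule: loci whose gene trees fall in the same cluster
#' as the reference (consensus) tree are nominated; the reference itself is
#' excluded from the listing.
#'
#' @param labels Named cluster labels (from [cluster_trees()]).
#' @param reference_id Name of the reference tree.
#' @return Character vector of the other member ids (possibly empty).
#' @export
reference_cluster <- function(labels, reference_id) {
  if (!reference_id %in% names(labels)) {
    abort(sprintf("Input error: unknown reference id '%s'.", reference_id))
  }
  members <- names(labels)[labels == labels[[reference_id]]]
  setdiff(members, reference_id)
}

#' Full tree-space concordance analysis
#'
#' Computes the Kendall-Colijn distance matrix, projects it onto principal
#' coordinates, discovers clusters at the cut-off height, and (when a
#' reference tree id is given) nominates the trees sharing the reference's
#' cluster.
#'
#' @param trees Named list of `phylo` trees (or `multiPhylo`).
#' @param lambda KC blending parameter (default 0: topology only).
#' @param n_axes Number of principal coordinates (default 5).
#' @param cutoff_height Dendrogram cut height (default 100; `NULL` for
#'   automatic).
#' @param linkage Linkage method (default `"ward"`).
#' @param outgroup Optional outgroup used to root unrooted inputs.
#' @param reference Optional id of the reference tree for marker nomination.
#' @return An object of class `tree_space` with elements `tree_ids`,
#'   `kc_distances`, `coordinates`, `eigenvalues`, `cluster_labels`,
#'   `reference`, `reference_cluster`, and `config`.
#' @export
tree_space <- function(trees, lambda = 0, n_axes = 5L, cutoff_height = 100,
                       linkage = "ward", outgroup = NULL, reference = NULL) {
  trees <- as_tree_list(trees)
  d <- kc_distance_matrix(trees, lambda = lambda, outgroup = outgroup)
  proj <- project_pcoa(d, n_axes = n_axes)
  labels <- cluster_trees(proj$coordinates, cutoff_height = cutoff_height,
                          linkage = linkage)
  ref_members <- if (!is.null(reference)) reference_cluster(labels, reference)
  structure(list(
    tree_ids = names(trees),
    kc_distances = d,
    coordinates = proj$coordinates,
    eigenvalues = proj$eigenvalues,
    cluster_labels = labels,
    reference = reference,
    reference_cluster = ref_members,
    config = list(lambda = lambda, n_axes = n_axes,
                  cutoff_height = attr(labels, "cutoff_height"),
                  linkage = linkage, outgroup = outgroup)
  ), class = "tree_space")
}

#' @export
print.tree_space <- function(x, ...) {
  cat(sprintf("<tree_space> %d trees, %d clusters (lambda = %g, cut height = %g)\n",
              length(x$tree_ids), max(x$cluster_labels),
              x$config$lambda, x$config$cutoff_height))
  if (!is.null(x$reference)) {
    cat(sprintf("  reference '%s' shares its cluster with %d tree(s)\n",
                x$reference, length(x$reference_cluster)))
  }
  invisible(x)
}

#' @describeIn tree_space Tidy per-tree table: id, coordinates, cluster,
#'   reference-cluster membership.
#' @param x A `tree_space` object.
#' @param ... Unused.
#' @export
tidy.tree_space <- function(x, ...) {
  out <- as_tibble(x$coordinates)
  out <- dplyr::mutate(out,
    tree_id = x$tree_ids,
    cluster = as.integer(x$cluster_labels),
    in_reference_cluster = if (is.null(x$reference)) NA else
      x$tree_ids %in% c(x$reference, x$reference_cluster),
    .before = 1)
  out
}

#' @describeIn tree_space One-row summary: tree count, cluster count,
#'   variance captured by the retained axes.
#' @export
glance.tree_space <- function(x, ...) {
  pos <- x$eigenvalues[x$eigenvalues > 0]
  captured <- sum(pos[seq_len(min(ncol(x$coordinates), length(pos)))]) / sum(pos)
  tibble(n_trees = length(x$tree_ids),
         n_clusters = max(x$cluster_labels),
         n_axes = ncol(x$coordinates),
         prop_variance = captured,
         lambda = x$config$lambda,
         cutoff_height = x$config$cutoff_height)
}

#' @describeIn tree_space Scatter of the first two principal coordinates,
#'   coloured by cluster; the reference tree (if any) is marked.
#' @param object A `tree_space` object.
#' @export
autoplot.tree_space <- function(object, ...) {
  df <- tidy(object)
  pl <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1,
                                         y = if ("PC2" %in% names(df)) .data$PC2 else 0,
                                         colour = factor(.data$cluster))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "PCo 1", y = "PCo 2", colour = "Cluster") +
    ggplot2::theme_minimal()
  if (!is.null(object$reference)) {
    ref <- df[df$tree_id == object$reference, , drop = FALSE]
    pl <- pl + ggplot2::geom_point(data = ref, shape = 8, size = 4,
                                   colour = "black")
  }
  pl
}

#' Table-shaped cluster report
#'
#' @param x A `tree_space` object.
#' @param min_size Report only clusters with at least this many members
#'   (default 3, matching the convention of reporting clusters of three or
#'   more similar trees; use 1 for all clusters).
#' @return A tibble `cluster`, `members` (comma-separated ids), `n_trees`.
#' @export
cluster_table <- function(x, min_size = 3L) {
  stopifnot(inherits(x, "tree_space"))
  lab <- x$cluster_labels
  out <- lapply(sort(unique(lab)), function(cl) {
    ids <- names(lab)[lab == cl]
    tibble(cluster = cl, members = paste(ids, collapse = "; "),
           n_trees = length(ids))
  })
  out <- dplyr::bind_rows(out)
  out[out$n_trees >= min_size, , drop = FALSE]
}
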