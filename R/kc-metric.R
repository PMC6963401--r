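# Kendall-Colijn tree vectors and distances.
#
# A rooted tree with tips 1..n is mapped to the vector
#   ( m_ij )_{i<j}  followed by  ( p_i )_i
# where, for the unordered tip pair (i, j),
#   m_ij = lambda * (root-to-MRCA path length) + (1 - lambda) * (edge count)
# and for each tip
#   p_i  = lambda * (pendant branch length)   + (1 - lambda) * 1.
# Tip pairs are taken in fixed lexicographic order of the tip labels, so
# vectors from different trees on the same taxon set are comparable; the KC
# distance is the Euclidean distance between vectors. lambda = 0 compares
# topology only; lambda = 1 compares branch-length depths only.

#' Kendall-Colijn vector of a rooted tree
#'
#' @param tree A rooted `phylo` with unique tip labels. Branch lengths are
#'   required when `lambda > 0`.
#' @param lambda Blending parameter in `[0, 1]`; 0 = topology only.
#' @return A named numeric vector: `n(n-1)/2` tip-pair entries (named
#'   `"a|b"`, lexicographic) followed by `n` pendant entries (named by tip).
#' @export
kc_vector <- function(tree, lambda = 0) {
  stopifnot(inherits(tree, "phylo"), lambda >= 0, lambda <= 1)
  if (!ape::is.rooted(tree)) {
    abort("Rooting error: the Kendall-Colijn vector requires a rooted tree; root on the configured outgroup first (see root_on_outgroup()).")
  }
  if (anyDuplicated(tree$tip.label)) {
    abort("Tip labels must be unique.")
  }
  has_bl <- !is.null(tree$edge.length)
  if (lambda > 0 && !has_bl) {
    abort("Input error: lambda > 0 requires branch lengths.")
  }
  n <- length(tree$tip.label)
  nnode <- n + tree$Nnode
  root <- n + 1L
  # depths from root: edge counts and path lengths
  d_edges <- rep(NA_real_, nnode); d_edges[root] <- 0
  d_len <- rep(NA_real_, nnode); d_len[root] <- 0
  eo <- rev(ape::postorder(tree))
  for (k in eo) {
    par <- tree$edge[k, 1]; chi <- tree$edge[k, 2]
    d_edges[chi] <- d_edges[par] + 1
    d_len[chi] <- d_len[par] + if (has_bl) tree$edge.length[k] else 0
  }
  ord <- order(tree$tip.label)
  labs <- tree$tip.label[ord]
  mr <- ape::mrca(tree)[labs, labs, drop = FALSE]
  pairs <- combn(length(labs), 2L)  # lexicographic: ab, ac, ad, bc, ...
  pair_nodes <- mr[cbind(pairs[1, ], pairs[2, ])]
  m <- (1 - lambda) * d_edges[pair_nodes] +
    (if (lambda > 0) lambda * d_len[pair_nodes] else 0)
  pair_names <- paste(labs[pairs[1, ]], labs[pairs[2, ]], sep = "|")
  # pendant entries
  pend_len <- numeric(n)
  if (has_bl) {
    tipidx <- match(seq_len(n), tree$edge[, 2])
    pend_len <- tree$edge.length[tipidx]
  }
  p <- (1 - lambda) * 1 + lambda * pend_len[ord]
  setNames(c(m, p), c(pair_names, labs))
}

#' Kendall-Colijn distance between two rooted trees
#'
#' @param t1,t2 Rooted `phylo` trees on identical tip sets.
#' @param lambda Blending parameter (see [kc_vector()]).
#' @return The Euclidean distance between the two KC vectors.
#' @export
kc_distance <- function(t1, t2, lambda = 0) {
  s1 <- sort(t1$tip.label); s2 <- sort(t2$tip.label)
  if (!identical(s1, s2)) {
    diff <- c(setdiff(s1, s2), setdiff(s2, s1))
    abort(paste0("Tip-set mismatch between trees: ", paste(diff, collapse = ", ")))
  }
  v1 <- kc_vector(t1, lambda)
  v2 <- kc_vector(t2, lambda)
  sqrt(sum((v1 - v2)^2))
}

#' Root an unrooted tree on an outgroup, placing the root mid-edge
#'
#' Roots on the edge subtending the outgroup (a tip or a clade) and places
#' the root node at the midpoint of that edge.
#'
#' @param tree A `phylo` tree.
#' @param outgroup Character vector of outgroup tip labels.
#' @return A rooted `phylo`.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing)) {
    abort(paste0("Outgroup tips not in tree: ", paste(missing, collapse = ", ")))
  }
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  tr <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  if (!is.null(tr$edge.length)) {
    n <- length(tr$tip.label)
    root <- n + 1L
    re <- which(tr$edge[, 1] == root)
    if (length(re) == 2L) {
      tot <- sum(tr$edge.length[re])
      tr$edge.length[re] <- tot / 2
    }
  }
  tr
}

#' Kendall-Colijn distance matrix for a set of trees
#'
#' Unrooted trees are rooted on `outgroup` first. Trees with unequal tip sets
#' are restricted to the common taxon set (with a message) when
#' `prune_to_common = TRUE`, otherwise a mismatch is an error.
#'
#' @param trees A (named) list of `phylo` trees or `multiPhylo`.
#' @param lambda Blending parameter.
#' @param outgroup Optional outgroup tip labels used to root unrooted inputs.
#' @param prune_to_common Restrict all trees to the shared taxon set.
#' @return A symmetric distance matrix with tree ids as dimnames.
#' @export
kc_distance_matrix <- function(trees, lambda = 0, outgroup = NULL,
                               prune_to_common = TRUE) {
  trees <- as_tree_list(trees)
  common <- Reduce(intersect, lapply(trees, function(t) t$tip.label))
  full <- unique(unlist(lapply(trees, function(t) t$tip.label)))
  if (length(common) < length(full)) {
    if (!prune_to_common) {
      abort("Tip sets differ across trees and prune_to_common = FALSE.")
    }
    inform(sprintf("Pruning %d tree(s) to the %d shared taxa (%d dropped).",
                   length(trees), length(common), length(full) - length(common)))
    trees <- lapply(trees, function(t) ape::keep.tip(t, common))
  }
  trees <- lapply(trees, function(t) {
    if (!ape::is.rooted(t)) {
      if (is.null(outgroup)) {
        abort("Rooting error: unrooted tree(s) present; supply `outgroup`.")
      }
      t <- root_on_outgroup(t, intersect(outgroup, t$tip.label))
    }
    t
  })
  vecs <- vapply(trees, kc_vector, numeric(length(kc_vector(trees[[1]], lambda))),
                 lambda = lambda)
  d <- as.matrix(stats::dist(t(vecs)))
  dimnames(d) <- list(names(trees), names(trees))
  d
}

as_tree_list <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (inherits(trees, "multiPhylo")) trees <- unclass(trees)
  if (is.null(names(trees)) || anyNA(names(trees)) || any(names(trees) == "")) {
    names(trees) <- paste0("tree", seq_along(trees))
  }
  trees
}
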