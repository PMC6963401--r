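# Majority-rule consensus and genus-monophyly screening.

#' Majority-rule consensus tree
#'
#' Contains exactly the splits occurring in strictly more than `threshold`
#' of the input trees (ties at exactly the threshold are excluded, the
#' standard strict-majority convention). Retained splits are annotated with
#' their frequency as node labels.
#'
#' @param trees List of `phylo` trees (or `multiPhylo`) on identical tip
#'   sets.
#' @param threshold Split-frequency threshold (default 0.5).
#' @return A (possibly multifurcating) `phylo`; node labels give split
#'   frequencies.
#' @export
majority_rule_consensus <- function(trees, threshold = 0.5) {
  trees <- as_tree_list(trees)
  stopifnot(length(trees) >= 1L)
  tipsets <- lapply(trees, function(t) sort(t$tip.label))
  ref <- tipsets[[1]]
  bad <- names(trees)[!vapply(tipsets, identical, logical(1), y = ref)]
  if (length(bad)) {
    abort(paste0("Tip-set mismatch in consensus input: ", paste(bad, collapse = ", ")))
  }
  if (length(trees) == 1L) return(trees[[1]])
  mp <- do.call(c, lapply(trees, list))
  class(mp) <- "multiPhylo"
  rooted <- all(vapply(trees, ape::is.rooted, logical(1)))
  cons <- ape::consensus(mp, p = threshold, check.labels = TRUE,
                         rooted = rooted)
  # annotate split frequencies on internal nodes
  freq <- ape::prop.clades(cons, mp, rooted = rooted) / length(trees)
  cons$node.label <- formatC(freq, digits = 3, format = "g")
  cons
}

#' Is a set of tips monophyletic?
#'
#' Rooted trees: true iff some clade equals `tips` exactly. Unrooted trees:
#' true iff `tips` form one side of some split. Singleton and full tip sets
#' are monophyletic by convention.
#'
#' @param tree A `phylo`.
#' @param tips Character vector of tip labels.
#' @return Logical.
#' @export
is_monophyletic <- function(tree, tips) {
  stopifnot(inherits(tree, "phylo"), length(tips) >= 1L)
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown)) {
    abort(paste0("Input error: unknown tip(s): ", paste(unknown, collapse = ", ")))
  }
  if (length(tips) %in% c(1L, length(tree$tip.label))) return(TRUE)
  ape::is.monophyletic(tree, tips)
}

#' Genus-monophyly screen over a set of gene trees
#'
#' A tree passes when every genus with at least two sampled tips in that tree
#' is monophyletic.
#'
#' @param trees Named list of `phylo` trees (or `multiPhylo`).
#' @param genus_map Data frame with columns `taxon` and `genus` covering
#'   every tip of every tree.
#' @return An object of class `monophyly_report`: list with `per_genus`
#'   (tibble `tree_id`, `genus`, `n_tips`, `monophyletic`), `per_tree`
#'   (tibble `tree_id`, `passes`) and `n_passing`.
#' @export
genus_monophyly_report <- function(trees, genus_map) {
  trees <- as_tree_list(trees)
  genus_map <- as_tibble(genus_map)
  stopifnot(all(c("taxon", "genus") %in% names(genus_map)))
  all_tips <- unique(unlist(lapply(trees, function(t) t$tip.label)))
  unmapped <- setdiff(all_tips, genus_map$taxon)
  if (length(unmapped)) {
    abort(paste0("Input error: taxa without a genus assignment: ",
                 paste(unmapped, collapse = ", ")))
  }
  per_genus <- dplyr::bind_rows(lapply(names(trees), function(id) {
    tr <- trees[[id]]
    gm <- genus_map[genus_map$taxon %in% tr$tip.label, , drop = FALSE]
    dplyr::bind_rows(lapply(split(gm$taxon, gm$genus), function(tx) {
      tibble(genus = genus_map$genus[match(tx[1], genus_map$taxon)],
             n_tips = length(tx),
             monophyletic = is_monophyletic(tr, tx))
    })) |>
      dplyr::mutate(tree_id = id, .before = 1)
  }))
  per_tree <- per_genus |>
    dplyr::filter(.data$n_tips >= 2L) |>
    dplyr::group_by(.data$tree_id) |>
    dplyr::summarise(passes = all(.data$monophyletic), .groups = "drop")
  # trees in which no genus has >= 2 tips pass vacuously
  missing_ids <- setdiff(names(trees), per_tree$tree_id)
  if (length(missing_ids)) {
    per_tree <- dplyr::bind_rows(per_tree,
                                 tibble(tree_id = missing_ids, passes = TRUE))
  }
  per_tree <- per_tree[match(names(trees), per_tree$tree_id), , drop = FALSE]
  structure(list(per_genus = per_genus, per_tree = per_tree,
                 n_passing = sum(per_tree$passes)),
            class = "monophyly_report")
}

#' @export
print.monophyly_report <- function(x, ...) {
  cat(sprintf("<monophyly_report> %d of %d trees have every sampled genus monophyletic\n",
              x$n_passing, nrow(x$per_tree)))
  invisible(x)
}

#' @export
tidy.monophyly_report <- function(x, ...) x$per_genus

#' @export
glance.monophyly_report <- function(x, ...) {
  tibble(n_trees = nrow(x$per_tree), n_passing = x$n_passing,
         prop_passing = x$n_passing / nrow(x$per_tree))
}
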