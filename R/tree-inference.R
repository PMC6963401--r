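# Desk-scale gene-tree estimation: Jukes-Cantor distances and
# neighbor-joining. This is a deliberately simple, deterministic estimator so
# the downstream tree-space analysis can run end-to-end; externally produced
# Newick gene trees (e.g. from ML software) can be supplied instead at every
# entry point that takes trees.

#' Jukes-Cantor (JC69) distance matrix from an alignment
#'
#' Pairwise mismatch proportions are computed on pairwise-complete sites
#' (pairwise deletion of anything other than A/C/G/T; set
#' `pairwise_deletion = FALSE` for complete deletion across all rows) and
#' transformed as `d = -(3/4) log(1 - (4/3) p)`. Saturated pairs
#' (`p >= 3/4`, infinite distance) are reported with a warning and set to
#' `saturation_cap`.
#'
#' @param aln An alignment matrix.
#' @param pairwise_deletion Use pairwise-complete sites (default) rather than
#'   complete deletion across all rows.
#' @param saturation_cap Replacement distance for saturated pairs.
#' @return A symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
jc69_distance_matrix <- function(aln, pairwise_deletion = TRUE,
                                 saturation_cap = 5) {
  stopifnot(is.matrix(aln), nrow(aln) >= 2L)
  if (!pairwise_deletion) aln <- complete_deletion(aln)
  dna <- ape::as.DNAbin(tolower(unclass(aln)))
  d <- as.matrix(ape::dist.dna(dna, model = "JC69", pairwise.deletion = TRUE))
  bad <- !is.finite(d)
  diag(bad) <- FALSE
  if (any(bad)) {
    pairs <- which(bad & upper.tri(bad), arr.ind = TRUE)
    labs <- apply(pairs, 1L, function(ij) {
      paste(rownames(d)[ij[1]], colnames(d)[ij[2]], sep = " / ")
    })
    warn(paste0("Saturation: p >= 3/4 for pair(s) ",
                paste(labs, collapse = "; "),
                "; distance set to the cap (", saturation_cap, ")."))
    d[bad] <- saturation_cap
  }
  # pairwise retained length must be >= 1
  nn <- nrow(aln)
  if (any(is.na(d))) {
    abort("Some pairs share no pairwise-complete sites; cannot compute distances.")
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' @param d A symmetric distance matrix with taxa as dimnames (>= 3 taxa).
#' @return An unrooted binary `phylo` tree. Negative estimated branch lengths
#'   are clamped to zero; the total clamped deficit is reported via a
#'   message.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) {
    abort("Input error: neighbor-joining needs at least 3 taxa.")
  }
  stopifnot(isTRUE(all.equal(d, t(d), tolerance = 1e-8)),
            all(diag(d) == 0), all(is.finite(d)))
  tr <- ape::nj(stats::as.dist(d))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    inform(sprintf(
      "Neighbor-joining: %d negative branch length(s) clamped to 0 (total deficit %.3g).",
      sum(neg), -sum(tr$edge.length[neg])))
    tr$edge.length[neg] <- 0
  }
  tr
}

#' Estimate one gene tree per locus alignment
#'
#' Convenience wrapper: JC69 distances then neighbor-joining, per locus.
#' Loci with fewer than 3 sequences are skipped with a message.
#'
#' @param loci A named list of alignment matrices (or of named character
#'   vectors of equal-length sequences).
#' @param ... Passed to [jc69_distance_matrix()].
#' @return A named list of `phylo` trees.
#' @export
estimate_gene_trees <- function(loci, ...) {
  out <- list()
  for (nm in names(loci)) {
    aln <- loci[[nm]]
    if (!is.matrix(aln)) {
      if (length(unique(nchar(aln))) != 1L) {
        inform(sprintf("Locus '%s' skipped: unequal sequence lengths (unaligned).", nm))
        next
      }
      aln <- as_alignment(aln)
    }
    if (nrow(aln) < 3L) {
      inform(sprintf("Locus '%s' skipped: fewer than 3 sequences.", nm))
      next
    }
    out[[nm]] <- neighbor_joining(jc69_distance_matrix(aln, ...))
  }
  out
}
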