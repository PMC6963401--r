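# Locus extraction: coding sequences, intergenic spacers (IGS) and introns
# from canonicalized annotated plastomes. One inverted-repeat copy only:
# loci falling entirely inside IRa are duplicates of IRb loci and are dropped.

#' Locus-extraction configuration
#'
#' @param min_igs_length Minimum IGS length in bp; spacers are kept only when
#'   strictly longer than this in the plastome that defines them.
#' @param intron_genes Gene symbols whose exon gaps are extracted as intron
#'   loci (two introns are supported for `clpP` and `ycf3`, one for `trnK`).
#' @return A list of class `locus_config`.
#' @export
locus_config <- function(min_igs_length = 100L,
                         intron_genes = c("clpP", "ycf3", "trnK")) {
  stopifnot(min_igs_length >= 0L)
  structure(list(min_igs_length = as.integer(min_igs_length),
                 intron_genes = intron_genes),
            class = "locus_config")
}

#' Extract CDS, IGS and intron loci from a set of canonical plastomes
#'
#' CDS loci are the concatenated coding intervals of each protein-coding gene
#' (reverse-complemented for minus-strand genes); tRNA and rRNA genes
#' contribute their (spliced) sequences the same way. IGS loci are the gaps
#' between consecutive feature boundaries on the canonical strand, named
#' `geneA_geneB`, and kept when strictly longer than `cfg$min_igs_length` in
#' the plastome that defines them. Intron loci are the gaps between
#' consecutive exons of `cfg$intron_genes`, numbered per gene. Loci lying
#' entirely inside IRa are dropped (one IR copy only). Pseudogenes bound IGS
#' loci but contribute no CDS locus.
#'
#' @param plastomes A list of canonicalized `plastome` objects.
#' @param cfg A [locus_config()].
#' @return A `locus_collection`: list with `sequences` (named list locus ->
#'   named character vector of per-taxon unaligned sequences) and `manifest`
#'   (tibble `locus`, `category`, `n_taxa`, `min_length`, `max_length`).
#' @export
extract_loci <- function(plastomes, cfg = locus_config()) {
  if (inherits(plastomes, "plastome")) plastomes <- list(plastomes)
  per_taxon <- lapply(plastomes, extract_loci_one, cfg = cfg)
  names(per_taxon) <- vapply(plastomes, function(p) p$taxon_id, character(1))

  all_loci <- unique(unlist(lapply(per_taxon, function(x) x$locus)))
  sequences <- list()
  categories <- character()
  for (loc in all_loci) {
    seqs <- character()
    cat_seen <- character()
    for (tx in names(per_taxon)) {
      tab <- per_taxon[[tx]]
      hit <- tab[tab$locus == loc, ]
      if (nrow(hit) == 1L) {
        seqs[[tx]] <- hit$sequence
        cat_seen <- c(cat_seen, hit$category)
      }
    }
    sequences[[loc]] <- seqs
    categories[[loc]] <- cat_seen[1]
  }
  manifest <- tibble(
    locus = all_loci,
    category = unname(categories[all_loci]),
    n_taxa = unname(vapply(sequences[all_loci], length, integer(1))),
    min_length = unname(vapply(sequences[all_loci], function(s) min(nchar(s)),
                               integer(1))),
    max_length = unname(vapply(sequences[all_loci], function(s) max(nchar(s)),
                               integer(1)))
  )
  structure(list(sequences = sequences, manifest = manifest),
            class = "locus_collection")
}

#' @export
print.locus_collection <- function(x, ...) {
  counts <- table(x$manifest$category)
  cat(sprintf("<locus_collection> %d loci (%s) across %d taxa\n",
              nrow(x$manifest),
              paste(sprintf("%s: %d", names(counts), counts), collapse = ", "),
              max(x$manifest$n_taxa)))
  invisible(x)
}

# per-taxon locus table: locus, category, sequence
extract_loci_one <- function(p, cfg) {
  stopifnot(inherits(p, "plastome"))
  if (is.null(p$regions)) {
    abort(sprintf("Plastome '%s' must be canonicalized before locus extraction.",
                  p$taxon_id))
  }
  n <- nchar(p$sequence)
  ira <- p$regions[p$regions$region == "IRa", ]
  in_ira <- function(s, e) s >= ira$start && e <= ira$end

  f <- p$features
  # per-instance footprint: the span of each annotated feature instance,
  # on the canonical strand (both IR copies are separate instances)
  gene_rows <- f[f$kind %in% c("gene", "CDS", "tRNA", "rRNA", "pseudogene"), , drop = FALSE]
  out <- list()

  # ---- CDS loci (protein-coding only; tRNA/rRNA act as IGS boundaries) ----
  cds <- f[f$kind == "CDS", , drop = FALSE]
  seen_cds <- character()
  for (id in unique(cds$fid)) {
    g <- cds[cds$fid == id, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    nm <- g$name[1]
    if (in_ira(min(g$start), max(g$end))) next   # one IR copy only
    if (nm %in% seen_cds) next
    seen_cds <- c(seen_cds, nm)
    seqs <- substring(p$sequence, g$start + 1L, g$end)
    s <- paste(seqs, collapse = "")
    if (g$strand[1] == "-") s <- revcomp(s)
    out[[length(out) + 1L]] <- tibble(locus = nm, category = "CDS",
                                      sequence = s)
  }

  # ---- IGS loci: gaps between consecutive feature footprints ----
  foot <- dplyr::summarise(dplyr::group_by(gene_rows, .data$fid),
                           name = .data$name[1],
                           start = min(.data$start), end = max(.data$end),
                           .groups = "drop")
  foot <- foot[order(foot$start, foot$end), , drop = FALSE]
  # collapse gene/CDS instance pairs sharing a name and span
  foot <- foot[!duplicated(foot[, c("name", "start", "end")]), , drop = FALSE]
  if (nrow(foot) >= 2L) {
    for (i in seq_len(nrow(foot))) {
      j <- if (i < nrow(foot)) i + 1L else 1L
      gap_start <- foot$end[i]
      gap_end <- if (i < nrow(foot)) foot$start[j] else foot$start[j] + n
      gap_len <- gap_end - gap_start
      if (gap_len < 0L) {
        warn(sprintf(
          "Overlapping features %s/%s in '%s' produce a negative IGS length; spacer skipped.",
          foot$name[i], foot$name[j], p$taxon_id))
        next
      }
      if (gap_len <= cfg$min_igs_length) next
      if (in_ira(gap_start, min(gap_end, n))) next
      nm <- paste0(foot$name[i], "_", foot$name[j])
      out[[length(out) + 1L]] <- tibble(
        locus = nm, category = "IGS",
        sequence = circ_substr(p$sequence, gap_start, gap_len))
    }
  }

  # ---- intron loci: gaps between consecutive exons of intron genes ----
  spliceable <- f[f$kind %in% c("CDS", "tRNA", "rRNA"), , drop = FALSE]
  intron_fids <- unique(spliceable$fid[spliceable$name %in% cfg$intron_genes])
  seen_intron <- character()
  for (id in intron_fids) {
    g <- spliceable[spliceable$fid == id, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    nm <- g$name[1]
    if (nrow(g) < 2L) next
    if (in_ira(min(g$start), max(g$end))) next
    if (nm %in% seen_intron) next
    seen_intron <- c(seen_intron, nm)
    n_introns <- nrow(g) - 1L
    for (k in seq_len(n_introns)) {
      # introns numbered 5' -> 3' on the gene's own strand
      knum <- if (g$strand[1] == "-") n_introns - k + 1L else k
      s <- substring(p$sequence, g$end[k] + 1L, g$start[k + 1L])
      if (g$strand[1] == "-") s <- revcomp(s)
      label <- if (n_introns == 1L) paste0(nm, "_intron")
               else paste0(nm, "_intron", knum)
      out[[length(out) + 1L]] <- tibble(locus = label, category = "intron",
                                        sequence = s)
    }
  }
  dplyr::bind_rows(out)
}

#' Write a locus collection to per-locus FASTA files plus a manifest
#'
#' @param lc A `locus_collection` from [extract_loci()].
#' @param dir Output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
write_locus_collection <- function(lc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (loc in names(lc$sequences)) {
    write_fasta(lc$sequences[[loc]], file.path(dir, paste0(loc, ".fasta")))
  }
  write_tsv_with_header(lc$manifest, file.path(dir, "locus_manifest.tsv"),
                        params = list(n_loci = nrow(lc$manifest)))
  invisible(lc$manifest)
}
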