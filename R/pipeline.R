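# Pipeline stages: the three analyses (diversity scan, tree-space
# concordance, structural comparison) plus simulation, each independently
# invokable and communicating via files in standard formats. Every output
# table carries '# key=value' header lines recording the configuration, and
# reruns with identical inputs and seed are byte-identical.

#' Run the sliding-window diversity analysis
#'
#' @param alignment An alignment matrix or path to a FASTA alignment.
#' @param groups A data frame (`taxon`, `group`) or path to a two-column TSV.
#' @param window,step Window grid in alignment columns.
#' @param delta_pair Length-2 character vector naming the two groups for the
#'   delta profile (default: the first two groups in table order), with
#'   `delta = pi[first] - pi[second]`.
#' @param out_dir Optional output directory for the profile, delta and
#'   summary tables.
#' @return A list: `profiles` (tibble with `group` column), `delta` (tibble),
#'   `summary` (tibble `group`, `max_pi`, plus delta range columns).
#' @export
run_diversity <- function(alignment, groups, window = 600L, step = 200L,
                          delta_pair = NULL, out_dir = NULL) {
  if (is.character(alignment) && length(alignment) == 1L) {
    alignment <- read_fasta_alignment(alignment)
  }
  if (is.character(groups) && length(groups) == 1L) {
    groups <- readr::read_tsv(groups, col_names = c("taxon", "group"),
                              show_col_types = FALSE, comment = "#")
  }
  groups <- as_tibble(groups)
  if (nrow(groups) == 0L) abort("Empty group table.")
  profiles <- group_diversity_profiles(alignment, groups, window, step)
  group_names <- unique(groups$group)
  if (is.null(delta_pair)) delta_pair <- head(group_names, 2L)
  delta <- NULL
  if (length(delta_pair) == 2L && all(delta_pair %in% group_names)) {
    split_prof <- lapply(delta_pair, function(g) {
      pr <- profiles[profiles$group == g, setdiff(names(profiles), "group")]
      attr(pr, "window") <- attr(profiles, "window")
      attr(pr, "step") <- attr(profiles, "step")
      pr
    })
    delta <- delta_profile(split_prof[[1]], split_prof[[2]])
  }
  summary <- profiles |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(max_pi = max(.data$pi, na.rm = TRUE),
                     mean_pi = mean(.data$pi, na.rm = TRUE),
                     .groups = "drop")
  if (!is.null(delta)) {
    summary$delta_min <- min(delta$delta_pi)
    summary$delta_max <- max(delta$delta_pi)
  }
  params <- list(window = window, step = step,
                 delta = paste(delta_pair, collapse = "-"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_with_header(profiles, file.path(out_dir, "diversity_profiles.tsv"), params)
    if (!is.null(delta)) {
      write_tsv_with_header(delta, file.path(out_dir, "delta_profile.tsv"), params)
    }
    write_tsv_with_header(summary, file.path(out_dir, "diversity_summary.tsv"), params)
  }
  list(profiles = profiles, delta = delta, summary = summary)
}

#' Run the tree-space concordance analysis
#'
#' Builds (or loads) gene trees, takes the majority-rule consensus of the
#' supplied species trees as the reference, clusters all trees in
#' Kendall-Colijn space, nominates the loci sharing the reference's cluster,
#' and screens every gene tree for genus monophyly.
#'
#' @param gene_trees Named list of `phylo`, or a directory of `.nwk`/`.tre`
#'   Newick files (one tree per file, file stem = locus name).
#' @param species_trees Optional list of species trees; their majority-rule
#'   consensus becomes the reference. If omitted, `reference` must name a
#'   gene tree.
#' @param genus_map Data frame (`taxon`, `genus`) or TSV path; required for
#'   the monophyly screen (set `monophyly = FALSE` to skip).
#' @param lambda,n_axes,cutoff_height,linkage,outgroup See [tree_space()].
#' @param threshold Consensus split-frequency threshold.
#' @param monophyly Run the genus-monophyly screen.
#' @param reference Reference tree id (default `"consensus"` when species
#'   trees are given).
#' @param out_dir Optional output directory.
#' @return A list: `space` (`tree_space` object), `clusters` (cluster
#'   table), `nominated` (character), `consensus` (`phylo` or `NULL`),
#'   `monophyly` (`monophyly_report` or `NULL`).
#' @export
run_treespace <- function(gene_trees, species_trees = NULL, genus_map = NULL,
                          lambda = 0, n_axes = 5L, cutoff_height = 100,
                          linkage = "ward", outgroup = NULL, threshold = 0.5,
                          monophyly = TRUE, reference = NULL, out_dir = NULL) {
  if (is.character(gene_trees) && length(gene_trees) == 1L) {
    files <- list.files(gene_trees, pattern = "\\.(nwk|tre|newick|txt)$",
                        full.names = TRUE)
    gene_trees <- lapply(files, ape::read.tree)
    names(gene_trees) <- sub("\\.[^.]+$", "", basename(files))
  }
  gene_trees <- as_tree_list(gene_trees)
  if (length(gene_trees) < 1L) abort("At least one gene tree is required.")

  consensus <- NULL
  all_trees <- gene_trees
  if (!is.null(species_trees)) {
    species_trees <- as_tree_list(species_trees)
    consensus <- majority_rule_consensus(species_trees, threshold = threshold)
    all_trees <- c(gene_trees, list(consensus = consensus))
    if (is.null(reference)) reference <- "consensus"
  }
  space <- tree_space(all_trees, lambda = lambda, n_axes = n_axes,
                      cutoff_height = cutoff_height, linkage = linkage,
                      outgroup = outgroup, reference = reference)
  clusters <- cluster_table(space, min_size = 1L)
  nominated <- space$reference_cluster

  mono <- NULL
  if (monophyly) {
    if (is.null(genus_map)) {
      abort("Monophyly screen requested but no genus map supplied.")
    }
    if (is.character(genus_map) && length(genus_map) == 1L) {
      genus_map <- readr::read_tsv(genus_map, col_names = c("taxon", "genus"),
                                   show_col_types = FALSE, comment = "#")
    }
    mono <- genus_monophyly_report(gene_trees, genus_map)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    params <- list(lambda = lambda, n_axes = n_axes,
                   cutoff_height = space$config$cutoff_height,
                   linkage = linkage, threshold = threshold)
    write_tsv_with_header(tidy(space), file.path(out_dir, "tree_coordinates.tsv"), params)
    write_tsv_with_header(clusters, file.path(out_dir, "tree_clusters.tsv"), params)
    utils::write.table(as.data.frame(space$kc_distances),
                       file.path(out_dir, "kc_distances.tsv"),
                       sep = "\t", quote = FALSE)
    if (!is.null(consensus)) {
      ape::write.tree(consensus, file.path(out_dir, "consensus.nwk"))
    }
    if (!is.null(mono)) {
      write_tsv_with_header(mono$per_tree, file.path(out_dir, "monophyly_report.tsv"),
                            params)
    }
  }
  list(space = space, clusters = clusters, nominated = nominated,
       consensus = consensus, monophyly = mono)
}

#' Run the structural comparison (junctions + indels)
#'
#' @param plastomes List of `plastome` objects, or a directory of GenBank
#'   files. Plastomes are canonicalized here if needed.
#' @param alignment Whole-plastome alignment matrix or FASTA path.
#' @param guide_tree `phylo` or Newick path ordering the junction table.
#' @param indel_cfg An [indel_config()].
#' @param min_ir_length Passed to [canonicalize_orientation()].
#' @param out_dir Optional output directory.
#' @return A list: `junctions` (comparison tibble), `indels` (tibble).
#' @export
run_structure <- function(plastomes, alignment = NULL, guide_tree = NULL,
                          indel_cfg = indel_config(), min_ir_length = 1000L,
                          out_dir = NULL) {
  if (is.character(plastomes) && length(plastomes) == 1L) {
    files <- list.files(plastomes, pattern = "\\.(gb|gbk|genbank)$",
                        full.names = TRUE)
    plastomes <- lapply(files, read_plastome)
  }
  plastomes <- lapply(plastomes, function(p) {
    if (is.null(p$regions)) {
      tryCatch(canonicalize_orientation(p, min_ir_length = min_ir_length),
               error = function(e) {
                 abort(sprintf("Cannot canonicalize plastome '%s': %s",
                               p$taxon_id, conditionMessage(e)))
               })
    } else p
  })
  maps <- dplyr::bind_rows(lapply(plastomes, junction_map))
  junctions <- maps
  if (!is.null(guide_tree)) {
    if (is.character(guide_tree)) guide_tree <- ape::read.tree(guide_tree)
    junctions <- compare_junctions(maps, guide_tree)
  }
  indels <- NULL
  if (!is.null(alignment)) {
    if (is.character(alignment) && length(alignment) == 1L) {
      alignment <- read_fasta_alignment(alignment)
    }
    taxa_aln <- rownames(alignment)
    taxa_p <- vapply(plastomes, function(p) p$taxon_id, character(1))
    if (!setequal(taxa_aln, taxa_p)) {
      diff <- c(setdiff(taxa_aln, taxa_p), setdiff(taxa_p, taxa_aln))
      abort(paste0("Alignment/plastome taxon mismatch: ",
                   paste(diff, collapse = ", ")))
    }
    indels <- scan_indels(alignment, indel_cfg)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    params <- list(min_indel = indel_cfg$min_length,
                   min_taxa = paste0(indel_cfg$min_taxa_rule, indel_cfg$min_taxa),
                   min_ir_length = min_ir_length)
    write_tsv_with_header(junctions, file.path(out_dir, "junction_table.tsv"), params)
    if (!is.null(indels)) {
      write_tsv_with_header(indels, file.path(out_dir, "indel_table.tsv"), params)
    }
  }
  list(junctions = junctions, indels = indels)
}

#' Simulate a synthetic plastome study and write its files
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory; GenBank and FASTA per taxon, the
#'   whole-plastome alignment, ground-truth Newick trees and a ground-truth
#'   manifest are written there.
#' @return The `plastome_synthesis` object, invisibly.
#' @export
run_simulate <- function(cfg = sim_config(), out_dir) {
  syn <- synthesize_plastome_set(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (tx in names(syn$plastomes)) {
    write_genbank(syn$plastomes[[tx]], file.path(out_dir, paste0(tx, ".gb")))
    write_fasta(setNames(syn$plastomes[[tx]]$sequence, tx),
                file.path(out_dir, paste0(tx, ".fasta")))
  }
  write_fasta(syn$alignment, file.path(out_dir, "whole_plastome_alignment.fasta"))
  ape::write.tree(syn$species_tree, file.path(out_dir, "species_tree.nwk"))
  trees <- do.call(c, lapply(syn$gene_trees, list))
  class(trees) <- "multiPhylo"
  ape::write.tree(trees, file.path(out_dir, "gene_trees.nwk"))
  params <- list(seed = cfg$seed, n_taxa = cfg$n_taxa,
                 coalescent_scale = cfg$coalescent_scale,
                 tree_height = cfg$tree_height,
                 ir_rate_multiplier = cfg$ir_rate_multiplier)
  write_tsv_with_header(syn$truth$regions, file.path(out_dir, "truth_regions.tsv"), params)
  write_tsv_with_header(syn$truth$indels, file.path(out_dir, "truth_indels.tsv"), params)
  write_tsv_with_header(syn$truth$junction_shifts,
                        file.path(out_dir, "truth_junction_shifts.tsv"), params)
  write_tsv_with_header(syn$locus_map, file.path(out_dir, "locus_map.tsv"), params)
  invisible(syn)
}
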