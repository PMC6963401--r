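# IR junction mapping and comparison, and scanning of large shared indels
# in whole-plastome alignments.

#' Map the three IR junctions of a canonical plastome
#'
#' Junctions are `J_LB` (LSC/IRb), `J_SB` (IRb/SSC) and `J_SA` (SSC/IRa) in
#' canonical coordinates. For each junction the nearest feature boundary on
#' each side is reported with a signed offset (feature boundary minus
#' junction position); a feature spanning the junction is reported with the
#' spanned lengths on each side.
#'
#' @param p A canonicalized `plastome`.
#' @return A tibble of class `junction_map`: one row per junction with
#'   columns `taxon_id`, `junction`, `position`, `left_feature`,
#'   `left_offset`, `right_feature`, `right_offset`, `spanning_feature`,
#'   `span_left`, `span_right`.
#' @export
junction_map <- function(p) {
  stopifnot(inherits(p, "plastome"))
  if (is.null(p$regions)) {
    abort(sprintf("Plastome '%s' is not canonicalized; regions are unset.", p$taxon_id))
  }
  jpos <- c(J_LB = p$regions$end[p$regions$region == "LSC"],
            J_SB = p$regions$end[p$regions$region == "IRb"],
            J_SA = p$regions$end[p$regions$region == "SSC"])
  jname <- c(J_LB = "LSC-IRb", J_SB = "IRb-SSC", J_SA = "SSC-IRa")
  f <- p$features
  f <- f[f$kind %in% c("gene", "CDS", "tRNA", "rRNA", "pseudogene"), , drop = FALSE]
  foot <- dplyr::summarise(dplyr::group_by(f, .data$fid),
                           name = .data$name[1],
                           start = min(.data$start), end = max(.data$end),
                           .groups = "drop")
  rows <- lapply(names(jpos), function(j) {
    pos <- jpos[[j]]
    if (nrow(foot) == 0L) {
      warn(sprintf("No annotations near junction %s of '%s'; offsets reported against sequence ends.",
                   jname[[j]], p$taxon_id))
      return(tibble(taxon_id = p$taxon_id, junction = jname[[j]], position = pos,
                    left_feature = NA_character_, left_offset = -pos,
                    right_feature = NA_character_,
                    right_offset = nchar(p$sequence) - pos,
                    spanning_feature = NA_character_,
                    span_left = NA_integer_, span_right = NA_integer_))
    }
    span <- foot[foot$start < pos & foot$end > pos, , drop = FALSE]
    sp_name <- if (nrow(span)) span$name[1] else NA_character_
    sp_l <- if (nrow(span)) pos - span$start[1] else NA_integer_
    sp_r <- if (nrow(span)) span$end[1] - pos else NA_integer_
    lefts <- foot[foot$end <= pos, , drop = FALSE]
    rights <- foot[foot$start >= pos, , drop = FALSE]
    lf <- if (nrow(lefts)) lefts[which.max(lefts$end), ] else NULL
    rf <- if (nrow(rights)) rights[which.min(rights$start), ] else NULL
    tibble(taxon_id = p$taxon_id, junction = jname[[j]], position = pos,
           left_feature = if (is.null(lf)) NA_character_ else lf$name,
           left_offset = if (is.null(lf)) NA_integer_ else as.integer(lf$end - pos),
           right_feature = if (is.null(rf)) NA_character_ else rf$name,
           right_offset = if (is.null(rf)) NA_integer_ else as.integer(rf$start - pos),
           spanning_feature = sp_name,
           span_left = as.integer(sp_l), span_right = as.integer(sp_r))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("junction_map", class(out))
  out
}

#' Compare junction maps across taxa against a guide tree
#'
#' Orders taxa by the guide tree's tip order and flags every taxon whose
#' junction-flank configuration (flanking features, offsets and spanning
#' record) differs from the modal configuration at that junction.
#'
#' @param maps A list of `junction_map` tibbles, or one row-bound tibble.
#' @param tree A `phylo` guide tree whose tips match the taxa.
#' @return A tibble: the junction rows ordered by tree tip order with an
#'   added logical `flagged` column.
#' @export
compare_junctions <- function(maps, tree) {
  if (is.list(maps) && !is.data.frame(maps)) maps <- dplyr::bind_rows(maps)
  taxa <- unique(maps$taxon_id)
  if (length(taxa) < 2L) abort("compare_junctions needs maps from >= 2 taxa.")
  if (!setequal(taxa, tree$tip.label)) {
    diff <- c(setdiff(taxa, tree$tip.label), setdiff(tree$tip.label, taxa))
    abort(paste0("Junction maps and guide tree disagree on taxa: ",
                 paste(diff, collapse = ", ")))
  }
  maps <- dplyr::mutate(maps, config = paste(
    .data$left_feature, .data$left_offset, .data$right_feature,
    .data$right_offset, .data$spanning_feature, .data$span_left,
    .data$span_right, sep = "|"))
  modal <- maps |>
    dplyr::count(.data$junction, .data$config) |>
    dplyr::group_by(.data$junction) |>
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
    dplyr::select("junction", modal_config = "config")
  out <- dplyr::left_join(maps, modal, by = "junction")
  out$flagged <- out$config != out$modal_config
  out$config <- NULL; out$modal_config <- NULL
  ord <- order(match(out$taxon_id, tree$tip.label),
               match(out$junction, c("LSC-IRb", "IRb-SSC", "SSC-IRa")))
  out[ord, , drop = FALSE]
}

#' Indel-scan configuration
#'
#' @param min_length Minimum event length in bp (default 50).
#' @param min_taxa Carrier-count threshold (default 5).
#' @param min_taxa_rule `">"` (strictly more than `min_taxa` carriers, the
#'   default reading of "over five species") or `">="`.
#' @return A list of class `indel_config`.
#' @export
indel_config <- function(min_length = 50L, min_taxa = 5L, min_taxa_rule = ">") {
  stopifnot(min_length >= 1L, min_taxa >= 1L)
  structure(list(min_length = as.integer(min_length),
                 min_taxa = as.integer(min_taxa),
                 min_taxa_rule = match.arg(min_taxa_rule, c(">", ">="))),
            class = "indel_config")
}

#' Scan an alignment for large shared indels
#'
#' An event is a maximal run of gap columns over which the set of
#' gap-carrying taxa is constant (nested indels therefore split into
#' multiple events). Events are reported when they span at least
#' `cfg$min_length` columns and the carrier count satisfies the
#' `min_taxa` rule; the carrier set must be a proper, non-empty subset of
#' the taxa. Polarity is `deletion` when the carriers are the minority,
#' `insertion` otherwise.
#'
#' @param aln An alignment matrix.
#' @param cfg An [indel_config()].
#' @param locus_map Optional tibble (`locus`, `start`, `end`; 0-based
#'   half-open alignment columns) used to annotate each event with the locus
#'   overlapping its start.
#' @return A tibble of class `indel_table`: `alignment_start`,
#'   `alignment_end` (0-based half-open), `length`, `n_taxa`, `member_taxa`
#'   (list column), `polarity`, `locus`.
#' @export
scan_indels <- function(aln, cfg = indel_config(), locus_map = NULL) {
  stopifnot(is.matrix(aln))
  gaps <- aln == "-"
  keys <- apply(gaps, 2L, function(col) paste(which(col), collapse = ","))
  r <- rle(keys)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based starts
  rows <- list()
  for (i in seq_along(r$values)) {
    key <- r$values[i]
    if (key == "") next
    members_idx <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
    if (length(members_idx) == nrow(aln)) next  # all-gap: not a shared indel
    len <- r$lengths[i]
    if (len < cfg$min_length) next
    nm <- length(members_idx)
    pass_taxa <- if (cfg$min_taxa_rule == ">") nm > cfg$min_taxa else nm >= cfg$min_taxa
    if (!pass_taxa) next
    polarity <- if (nm < nrow(aln) / 2) "deletion" else "insertion"
    rows[[length(rows) + 1L]] <- tibble(
      alignment_start = starts[i], alignment_end = ends[i],
      length = len, n_taxa = nm,
      member_taxa = list(rownames(aln)[members_idx]),
      polarity = polarity)
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(alignment_start = integer(), alignment_end = integer(),
           length = integer(), n_taxa = integer(), member_taxa = list(),
           polarity = character())
  out$locus <- NA_character_
  if (!is.null(locus_map) && nrow(out)) {
    for (i in seq_len(nrow(out))) {
      hit <- locus_map[locus_map$start <= out$alignment_start[i] &
                         locus_map$end > out$alignment_start[i], , drop = FALSE]
      if (nrow(hit)) out$locus[i] <- hit$locus[1]
    }
  }
  class(out) <- c("indel_table", class(out))
  out
}

#' Export indel events as BED intervals on a reference row
#'
#' Alignment columns are mapped to ungapped 0-based positions of the chosen
#' reference taxon (events where the reference itself is a carrier map to a
#' zero-length insertion point).
#'
#' @param indels An `indel_table` from [scan_indels()].
#' @param aln The alignment the events came from.
#' @param reference Reference row name.
#' @param path Optional output path; when given, a 4-column BED file is
#'   written.
#' @return A tibble `chrom`, `start`, `end`, `name`.
#' @export
indel_bed <- function(indels, aln, reference, path = NULL) {
  stopifnot(reference %in% rownames(aln))
  refrow <- aln[reference, ]
  # ungapped position of each alignment column start (0-based)
  ungapped_before <- cumsum(refrow != "-") - (refrow != "-")
  map_col <- function(col0) {
    if (col0 >= length(refrow)) sum(refrow != "-") else ungapped_before[col0 + 1L]
  }
  out <- tibble(
    chrom = reference,
    start = vapply(indels$alignment_start, map_col, numeric(1)),
    end = vapply(indels$alignment_end, map_col, numeric(1)),
    name = paste0(indels$polarity, "_", indels$length, "bp_",
                  indels$n_taxa, "taxa"))
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  out
}
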