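# Synthetic plastome study generator.
#
# A fixed plastome-like template (quadripartite layout, ~20 genes including
# multi-intron clpP/ycf3 analogues and a single-intron trnK analogue) is
# evolved along a Yule species tree: each template element (gene or spacer)
# gets its own alignment, inverted-repeat elements evolve at a reduced rate
# and are present as one evolving copy mirrored exactly into IRa, large
# indels are injected into spacer elements of chosen carrier taxa, and IR
# junction shifts (expansions) are injected per taxon. Ground truth for
# every injected event is returned for assertions.

#' Simulation configuration
#'
#' @param seed Integer seed driving all randomness.
#' @param n_taxa Number of species (default 10).
#' @param birth_rate Yule speciation rate.
#' @param coalescent_scale Incomplete-lineage-sorting scale for per-locus
#'   gene trees; 0 (default) evolves every element on the species tree.
#' @param tree_height Root-to-tip depth in expected substitutions per site
#'   after rescaling (default 0.2, the deep, order-scale end of plastome
#'   divergence, chosen so that 2 kb loci carry enough signal for
#'   distance-based gene trees).
#' @param min_internal_frac Minimum internal branch length as a fraction of
#'   tree depth (default 0.05); degenerate species trees are redrawn (see
#'   [simulate_species_tree()]).
#' @param n_loci Locus count for stand-alone gene-tree simulation.
#' @param locus_length Locus length for stand-alone simulation (bp).
#' @param kappa HKY transition/transversion ratio.
#' @param base_freqs Stationary base frequencies (named A/C/G/T, sum 1).
#' @param gamma_shape Gamma shape for i.i.d. site rates (`Inf` = none).
#' @param ir_rate_multiplier Rate multiplier in `(0, 1]` for inverted-repeat
#'   elements (default 0.3: IRs evolve more slowly than single-copy DNA).
#' @param indel_spec List of `list(locus =, length =, carriers =)` entries;
#'   `locus` must be a spacer element id (see [plastome_template()]),
#'   `carriers` a character vector of taxa or an integer count.
#' @param junction_shift_spec List of `list(taxa =, junction =, shift =)`
#'   entries; `junction` one of `"LSC-IRb"`, `"IRb-SSC"`, `"SSC-IRa"`;
#'   `shift` a positive expansion in bp. At most one shift per taxon.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_taxa = 10L, birth_rate = 1,
                       coalescent_scale = 0, tree_height = 0.2,
                       min_internal_frac = 0.05,
                       n_loci = 20L, locus_length = 2000L, kappa = 2,
                       base_freqs = c(A = 0.31, C = 0.19, G = 0.19, T = 0.31),
                       gamma_shape = 1, ir_rate_multiplier = 0.3,
                       indel_spec = list(), junction_shift_spec = list()) {
  stopifnot(n_taxa >= 2L, birth_rate > 0, coalescent_scale >= 0,
            tree_height > 0, min_internal_frac >= 0, kappa > 0,
            abs(sum(base_freqs) - 1) < 1e-12,
            ir_rate_multiplier > 0, ir_rate_multiplier <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' The fixed plastome-like template layout
#'
#' @return A tibble of elements in genome order over regions LSC, IRb and
#'   SSC (IRa is the exact mirror of IRb): columns `element` (unique id),
#'   `region`, `type` (`gene`/`igs`), `name`, `kind`, `strand`,
#'   `exon_lengths` and `intron_lengths` (list columns), `length`.
#' @export
plastome_template <- function() {
  g <- function(region, name, kind, strand, exons, introns = integer(0)) {
    tibble(element = name, region = region, type = "gene", name = name,
           kind = kind, strand = strand, exon_lengths = list(exons),
           intron_lengths = list(introns),
           length = sum(exons) + sum(introns))
  }
  s <- function(region, id, len) {
    tibble(element = id, region = region, type = "igs", name = NA_character_,
           kind = NA_character_, strand = NA_character_,
           exon_lengths = list(integer(0)), intron_lengths = list(integer(0)),
           length = len)
  }
  dplyr::bind_rows(
    g("LSC", "psbA", "CDS", "-", 1062),
    s("LSC", "igs_psbA_trnK", 300),
    g("LSC", "trnK", "tRNA", "-", c(37, 35), 700),
    s("LSC", "igs_trnK_matK", 220),
    g("LSC", "matK", "CDS", "-", 900),
    s("LSC", "igs_matK_rps16", 80),
    g("LSC", "rps16", "CDS", "-", 810),
    s("LSC", "igs_rps16_psbK", 250),
    g("LSC", "psbK", "CDS", "+", 186),
    s("LSC", "igs_psbK_atpA", 180),
    g("LSC", "atpA", "CDS", "+", 1524),
    s("LSC", "igs_atpA_ycf3", 150),
    g("LSC", "ycf3", "CDS", "-", c(126, 228, 153), c(740, 710)),
    s("LSC", "igs_ycf3_trnS", 130),
    g("LSC", "trnS", "tRNA", "+", 88),
    s("LSC", "igs_trnS_rbcL", 320),
    g("LSC", "rbcL", "CDS", "+", 1428),
    s("LSC", "igs_rbcL_clpP", 280),
    g("LSC", "clpP", "CDS", "-", c(71, 294, 228), c(540, 630)),
    s("LSC", "igs_clpP_psbB", 200),
    g("LSC", "psbB", "CDS", "+", 1527),
    s("LSC", "igs_psbB_petB", 240),
    g("LSC", "petB", "CDS", "+", 648),
    s("LSC", "igs_petB_rpoA", 160),
    g("LSC", "rpoA", "CDS", "-", 1014),
    s("LSC", "igs_rpoA_rps19", 110),
    g("LSC", "rps19", "CDS", "+", 279),
    s("LSC", "igs_rps19_end", 60),
    g("IRb", "rpl2", "CDS", "-", 822),
    s("IRb", "igs_rpl2_ndhB", 170),
    g("IRb", "ndhB", "CDS", "-", 1476),
    s("IRb", "igs_ndhB_rrn16", 210),
    g("IRb", "rrn16", "rRNA", "+", 1491),
    s("IRb", "igs_rrn16_end", 140),
    g("SSC", "ndhF", "CDS", "-", 2220),
    s("SSC", "igs_ndhF_ndhA", 290),
    g("SSC", "ndhA", "CDS", "-", 1080),
    s("SSC", "igs_ndhA_ycf1", 310),
    g("SSC", "ycf1", "CDS", "+", 1650),
    s("SSC", "igs_ycf1_end", 90)
  )
}

#' The species tree of a simulated study
#'
#' Draws the Yule species tree under the configured study conditions:
#' resolvability conditioning (`min_internal_frac`) followed by rescaling to
#' `tree_height`. Consumes the current RNG state; set a seed first for
#' reproducibility.
#'
#' @param cfg A [sim_config()].
#' @return A rooted ultrametric `phylo` of depth `cfg$tree_height`.
#' @export
simulate_study_tree <- function(cfg) {
  st <- simulate_species_tree(cfg$n_taxa, cfg$birth_rate,
                              min_internal_frac = cfg$min_internal_frac)
  rescale_tree_height(st, cfg$tree_height)
}

#' Synthesize a set of annotated plastomes with ground truth
#'
#' @param cfg A [sim_config()].
#' @return A list of class `plastome_synthesis`:
#'   `species_tree`; `gene_trees` (per element); `plastomes` (named list of
#'   canonical `plastome` objects); `alignment` (whole-plastome alignment in
#'   template coordinates, indel carriers gapped; junction-shift insertions
#'   are deliberately not represented here); `locus_map` (element ->
#'   alignment interval); `truth` (list: `regions`, `indels`,
#'   `junction_shifts`); `template`; `config`.
#' @export
synthesize_plastome_set <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tpl <- plastome_template()

  st <- simulate_study_tree(cfg)
  taxa <- st$tip.label

  # per-element genealogies and alignments
  gene_trees <- list()
  elem_aln <- list()
  for (i in seq_len(nrow(tpl))) {
    el <- tpl$element[i]
    tr <- if (cfg$coalescent_scale > 0) {
      simulate_gene_trees(st, 1L, cfg$coalescent_scale)[[1]]
    } else {
      st
    }
    gene_trees[[el]] <- tr
    rate <- if (tpl$region[i] == "IRb") cfg$ir_rate_multiplier else 1
    elem_aln[[el]] <- evolve_alignment(tr, tpl$length[i], kappa = cfg$kappa,
                                       base_freqs = cfg$base_freqs,
                                       gamma_shape = cfg$gamma_shape,
                                       rate = rate)[taxa, , drop = FALSE]
  }

  # ---- junction guards ----
  # Pin the single-copy bases flanking every (possibly shifted) IR junction
  # to 'A' in all taxa, so the assembled inverted repeat is exactly the
  # constructed repeat: a chance complementary base at a junction would
  # otherwise let the maximal exact match extend past the design boundary.
  region_cols <- function(region) {
    ids <- tpl$element[tpl$region == region]
    lens <- tpl$length[tpl$region == region]
    list(ids = ids, offsets = cumsum(c(0, head(lens, -1))), total = sum(lens))
  }
  pin_region_col <- function(region, col0) {
    rc <- region_cols(region)
    i <- findInterval(col0, rc$offsets)
    el <- rc$ids[i]
    elem_aln[[el]][, col0 - rc$offsets[i] + 1L] <<- "A"
  }
  lsc_total <- region_cols("LSC")$total
  ssc_total <- region_cols("SSC")$total
  guard_cols <- list(LSC = c(0L, lsc_total - 1L), SSC = c(0L, ssc_total - 1L))
  for (spec in cfg$junction_shift_spec) {
    s <- as.integer(spec$shift)
    gc <- switch(spec$junction,
                 "LSC-IRb" = list("LSC", lsc_total - s - 1L),
                 "IRb-SSC" = list("SSC", s),
                 "SSC-IRa" = list("SSC", ssc_total - s - 1L))
    guard_cols[[gc[[1]]]] <- c(guard_cols[[gc[[1]]]], gc[[2]])
  }
  for (region in names(guard_cols)) {
    for (col0 in unique(guard_cols[[region]])) pin_region_col(region, col0)
  }

  # ---- indel injection (spacer elements only) ----
  ref_offset <- setNames(cumsum(c(0, head(tpl$length, -1))), tpl$element)
  indel_truth <- list()
  for (spec in cfg$indel_spec) {
    el <- spec$locus
    if (is.null(el) || !el %in% tpl$element) {
      abort(sprintf("Config error: unknown indel host locus '%s'.", el %||% "<NULL>"))
    }
    row <- tpl[tpl$element == el, ]
    if (row$type != "igs" || !row$region %in% c("LSC", "SSC")) {
      abort(sprintf("Config error: indel host '%s' must be a single-copy spacer element.", el))
    }
    if (spec$length > row$length - 2L) {
      abort(sprintf("Config error: indel of %d bp does not fit inside host locus '%s' (%d bp; the element's edge columns must survive).",
                    spec$length, el, row$length))
    }
    carriers <- resolve_taxa(spec$carriers, st)
    if (length(carriers) >= length(taxa)) {
      abort("Config error: indel carriers must be a proper subset of the taxa.")
    }
    pos0 <- (row$length - spec$length) %/% 2L  # centred within the element
    cols <- seq.int(pos0 + 1L, pos0 + spec$length)
    elem_aln[[el]][carriers, cols] <- "-"
    indel_truth[[length(indel_truth) + 1L]] <- tibble(
      locus = el,
      alignment_start = unname(ref_offset[el]) + pos0,
      alignment_end = unname(ref_offset[el]) + pos0 + spec$length,
      length = spec$length, n_taxa = length(carriers),
      member_taxa = list(sort(carriers)))
  }

  # ---- junction shifts ----
  shift_truth <- list()
  shift_by_taxon <- setNames(vector("list", length(taxa)), taxa)
  for (spec in cfg$junction_shift_spec) {
    stopifnot(spec$junction %in% c("LSC-IRb", "IRb-SSC", "SSC-IRa"))
    if (spec$shift <= 0) {
      abort("Config error: junction shifts must be positive expansions (bp).")
    }
    for (tx in resolve_taxa(spec$taxa, st)) {
      if (!is.null(shift_by_taxon[[tx]])) {
        abort(sprintf("Config error: taxon '%s' carries more than one junction shift.", tx))
      }
      shift_by_taxon[[tx]] <- list(junction = spec$junction, shift = spec$shift)
      shift_truth[[length(shift_truth) + 1L]] <-
        tibble(taxon_id = tx, junction = spec$junction, shift = spec$shift)
    }
  }

  # a junction guard pinned in template coordinates would drift for a taxon
  # whose same-region indel removes bases before it, so that combination is
  # rejected
  if (length(indel_truth) && any(lengths(shift_by_taxon) > 0)) {
    for (it in indel_truth) {
      region_of_indel <- tpl$region[tpl$element == it$locus]
      for (tx in it$member_taxa[[1]]) {
        sh <- shift_by_taxon[[tx]]
        if (is.null(sh)) next
        shift_region <- if (sh$junction == "LSC-IRb") "LSC" else "SSC"
        if (identical(region_of_indel, shift_region)) {
          abort(sprintf(
            "Config error: taxon '%s' carries both an indel and a junction shift in the %s region.",
            tx, shift_region))
        }
      }
    }
  }

  # ---- per-taxon assembly ----
  plastomes <- list()
  region_truth <- list()
  for (tx in taxa) {
    asm <- assemble_taxon(tx, tpl, elem_aln, shift_by_taxon[[tx]])
    plastomes[[tx]] <- asm$plastome
    region_truth[[length(region_truth) + 1L]] <-
      dplyr::mutate(asm$plastome$regions, taxon_id = tx, .before = 1)
  }

  # ---- whole-plastome alignment in template coordinates ----
  irb_ids <- tpl$element[tpl$region == "IRb"]
  ira_aln <- lapply(rev(irb_ids), function(el) revcomp_alignment(elem_aln[[el]]))
  aln <- do.call(cbind, c(elem_aln[tpl$element], ira_aln))
  aln <- as_alignment(aln)

  full_elements <- c(tpl$element, paste0(rev(irb_ids), "_ira"))
  full_lengths <- c(tpl$length, rev(tpl$length[tpl$region == "IRb"]))
  locus_map <- tibble(locus = full_elements,
                      start = cumsum(c(0, head(full_lengths, -1))),
                      end = cumsum(full_lengths))

  structure(list(
    species_tree = st,
    gene_trees = gene_trees,
    plastomes = plastomes,
    alignment = aln,
    locus_map = locus_map,
    truth = list(
      regions = dplyr::bind_rows(region_truth),
      indels = if (length(indel_truth)) dplyr::bind_rows(indel_truth) else
        tibble(locus = character(), alignment_start = integer(),
               alignment_end = integer(), length = integer(),
               n_taxa = integer(), member_taxa = list()),
      junction_shifts = if (length(shift_truth)) dplyr::bind_rows(shift_truth) else
        tibble(taxon_id = character(), junction = character(), shift = integer())
    ),
    template = tpl,
    config = cfg
  ), class = "plastome_synthesis")
}

#' @export
print.plastome_synthesis <- function(x, ...) {
  cat(sprintf("<plastome_synthesis> %d taxa, %d template elements, %d injected indel(s), %d junction shift(s)\n",
              length(x$plastomes), nrow(x$template),
              nrow(x$truth$indels), nrow(x$truth$junction_shifts)))
  invisible(x)
}

rescale_tree_height <- function(tree, height) {
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * height / depth
  tree
}

revcomp_alignment <- function(aln) {
  out <- t(apply(aln, 1L, function(row) rev(complement_chars(row))))
  rownames(out) <- rownames(aln)
  out
}

# carriers: explicit taxa, or an integer k -> the first clade with exactly k
# tips (cladewise node order); fallback: the first k tips in cladewise order
resolve_taxa <- function(x, tree) {
  if (is.character(x)) {
    missing <- setdiff(x, tree$tip.label)
    if (length(missing)) {
      abort(paste0("Config error: unknown taxa ", paste(missing, collapse = ", ")))
    }
    return(x)
  }
  k <- as.integer(x)
  n <- length(tree$tip.label)
  stopifnot(k >= 1L, k <= n)
  for (node in seq.int(n + 1L, n + tree$Nnode)) {
    tips <- ape::extract.clade(tree, node)$tip.label
    if (length(tips) == k) return(tips)
  }
  tree$tip.label[seq_len(k)]
}

# Assemble one taxon's circular genome, features and regions from the
# per-element alignments (its rows), applying at most one junction shift.
assemble_taxon <- function(tx, tpl, elem_aln, shift) {
  elem_seq <- lapply(tpl$element, function(el) {
    paste(elem_aln[[el]][tx, elem_aln[[el]][tx, ] != "-"], collapse = "")
  })
  names(elem_seq) <- tpl$element
  elem_len <- vapply(elem_seq, nchar, integer(1))

  lsc_ids <- tpl$element[tpl$region == "LSC"]
  irb_ids <- tpl$element[tpl$region == "IRb"]
  ssc_ids <- tpl$element[tpl$region == "SSC"]

  lsc_seq <- paste(unlist(elem_seq[lsc_ids]), collapse = "")
  irb_seq <- paste(unlist(elem_seq[irb_ids]), collapse = "")
  ssc_seq <- paste(unlist(elem_seq[ssc_ids]), collapse = "")

  lb <- 0L; sb <- 0L; sa <- 0L
  ins_irb_end <- ""; ins_ira_start <- ""; ins_ira_end <- ""
  if (!is.null(shift)) {
    s <- as.integer(shift$shift)
    if (shift$junction == "LSC-IRb") {
      lb <- s
      tail_s <- substr(lsc_seq, nchar(lsc_seq) - s + 1L, nchar(lsc_seq))
      ins_ira_end <- revcomp(tail_s)
    } else if (shift$junction == "IRb-SSC") {
      sb <- s
      head_s <- substr(ssc_seq, 1L, s)
      ins_ira_start <- revcomp(head_s)
    } else {
      sa <- s
      tail_s <- substr(ssc_seq, nchar(ssc_seq) - s + 1L, nchar(ssc_seq))
      ins_irb_end <- revcomp(tail_s)
    }
  }

  ira_seq <- revcomp(irb_seq)
  genome <- paste0(lsc_seq, irb_seq, ins_irb_end, ssc_seq,
                   ins_ira_start, ira_seq, ins_ira_end)

  L0 <- nchar(lsc_seq); I0 <- nchar(irb_seq); S0 <- nchar(ssc_seq)
  # J_SB absorbs the duplicated segment sitting at the IRb end (sa) or the
  # single-copy bases reassigned to IRb (sb); J_SA always sits where the
  # IR-owned SSC tail (sa) or the inserted copy (sb) begins.
  j_lb <- L0 - lb
  j_sb <- L0 + I0 + sa + sb
  j_sa <- L0 + I0 + sa + S0 - sa
  regions <- tibble(
    region = c("LSC", "IRb", "SSC", "IRa"),
    start = c(0L, j_lb, j_sb, j_sa),
    end = c(j_lb, j_sb, j_sa, nchar(genome))
  )

  # ---- features ----
  feats <- list()
  fid_counter <- 0L
  emit_gene <- function(row, elem_start, mirrored = FALSE) {
    fid_counter <<- fid_counter + 1L
    exons <- row$exon_lengths[[1]]
    introns <- row$intron_lengths[[1]]
    strand <- row$strand
    if (mirrored) strand <- if (strand == "+") "-" else "+"
    # genome-order intervals of exons within the element
    offs <- 0L
    ivs <- list()
    for (k in seq_along(exons)) {
      ivs[[k]] <- c(offs, offs + exons[k])
      offs <- offs + exons[k] + if (k <= length(introns)) introns[k] else 0L
    }
    if (mirrored) {
      tot <- row$length
      ivs <- rev(lapply(ivs, function(iv) c(tot - iv[2], tot - iv[1])))
    }
    dplyr::bind_rows(lapply(seq_along(ivs), function(k) {
      tibble(fid = fid_counter, name = row$name, kind = row$kind,
             start = as.integer(elem_start + ivs[[k]][1]),
             end = as.integer(elem_start + ivs[[k]][2]),
             strand = strand, part = k)
    }))
  }

  offset <- 0L
  for (el in c(lsc_ids, irb_ids)) {
    row <- tpl[tpl$element == el, ]
    if (row$type == "gene") {
      feats[[length(feats) + 1L]] <- emit_gene(row, offset)
    }
    offset <- offset + elem_len[[el]]
  }
  offset <- offset + nchar(ins_irb_end)
  for (el in ssc_ids) {
    row <- tpl[tpl$element == el, ]
    if (row$type == "gene") {
      feats[[length(feats) + 1L]] <- emit_gene(row, offset)
    }
    offset <- offset + elem_len[[el]]
  }
  offset <- offset + nchar(ins_ira_start)
  for (el in rev(irb_ids)) {
    row <- tpl[tpl$element == el, ]
    if (row$type == "gene") {
      feats[[length(feats) + 1L]] <- emit_gene(row, offset, mirrored = TRUE)
    }
    offset <- offset + elem_len[[el]]
  }

  features <- renumber_parts(dplyr::bind_rows(feats))
  p <- new_plastome(tx, genome, features, regions = regions)
  list(plastome = p)
}
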