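test_that("GenBank records parse into plastomes with correct coordinates", {
  txt <- make_genbank_text()
  p <- read_plastome(txt)
  expect_s3_class(p, "plastome")
  expect_equal(nchar(p$sequence), 200)
  cds <- p$features[p$features$kind == "CDS", ]
  expect_equal(nrow(cds), 2)
  a <- cds[cds$name == "geneA", ]
  expect_equal(c(a$start, a$end), c(10, 40))  # 1-based 11..40 -> 0-based [10, 40)
  b <- cds[cds$name == "geneB", ]
  expect_equal(b$strand, "-")
  expect_equal(c(b$start, b$end), c(60, 130))
})

test_that("joined two-interval CDS becomes one feature with ordered parts", {
  feats <- c(
    "     CDS             join(11..40,81..110)",
    "                     /gene=\"split1\""
  )
  p <- read_plastome(make_genbank_text(features = feats))
  f <- p$features[p$features$name == "split1", ]
  expect_equal(nrow(f), 2)
  expect_equal(f$part, c(1L, 2L))
  expect_equal(f$start, c(10L, 80L))
  expect_equal(f$end, c(40L, 110L))
  expect_equal(unique(f$fid), f$fid[1])
})

test_that("records without a sequence are rejected with an input error", {
  lines <- c("LOCUS       bad 0 bp", "FEATURES             Location/Qualifiers")
  expect_error(read_plastome(lines), "ORIGIN")
  lines2 <- c("LOCUS       bad 0 bp", "ORIGIN", "//")
  expect_error(read_plastome(lines2), "empty sequence")
})

test_that("malformed feature locations name the offending line", {
  feats <- c("     CDS             11..x40", "                     /gene=\"bad\"")
  expect_error(read_plastome(make_genbank_text(features = feats)), "11\\.\\.x40")
})

test_that("GenBank writing round-trips sequence and features", {
  syn <- synthesize_plastome_set(sim_config(seed = 21, n_taxa = 4))
  p <- syn$plastomes[[1]]
  tf <- withr::local_tempfile(fileext = ".gb")
  write_genbank(p, tf)
  q <- read_plastome(tf)
  expect_identical(q$sequence, p$sequence)
  expect_identical(
    extract_loci(list(canonicalize_orientation(q)))$sequences,
    extract_loci(list(p))$sequences
  )
})

test_that("canonicalization is idempotent and invariant to rotation and strand", {
  syn <- synthesize_plastome_set(sim_config(seed = 22, n_taxa = 4))
  p <- syn$plastomes[[2]]
  raw <- new_plastome(p$taxon_id, p$sequence, p$features)
  canon <- canonicalize_orientation(raw)
  expect_identical(canon$sequence, p$sequence)
  expect_identical(canon$regions, p$regions)
  # idempotence
  again <- canonicalize_orientation(canon)
  expect_identical(again$sequence, canon$sequence)
  expect_identical(again$regions, canon$regions)
  # rotation invariance (several offsets)
  for (at in c(137, 5000, nchar(p$sequence) - 3)) {
    rot <- canonicalize_orientation(plastomics:::rotate_plastome(raw, at))
    expect_identical(rot$sequence, canon$sequence)
    expect_identical(extract_loci(list(rot))$sequences,
                     extract_loci(list(canon))$sequences)
  }
  # full reverse-complement invariance
  rc <- canonicalize_orientation(plastomics:::revcomp_plastome(raw))
  expect_identical(rc$sequence, canon$sequence)
  expect_identical(rc$regions, canon$regions)
})

test_that("a plastome built as IRa|SSC|IRb|LSC canonicalizes to constructed lengths", {
  q <- make_quadripartite(lsc = 5200, ir = 1300, ssc = 1600, seed = 7)
  # assemble in scrambled order: IR|SSC|rc(IR)|LSC corresponds to reading the
  # canonical circle from IRb
  scrambled <- paste0(q$ir, q$ssc, plastomics::revcomp(q$ir), q$lsc)
  p <- new_plastome("scrambled", scrambled)
  canon <- canonicalize_orientation(p, min_ir_length = 500)
  expect_equal(canon$regions$end - canon$regions$start, c(5200, 1300, 1600, 1300))
  # without annotations the lexicographic rule decides the strand; either
  # way the canonical LSC holds the constructed LSC content
  canon_lsc <- substr(canon$sequence, 1, 5200)
  expect_true(canon_lsc == q$lsc || canon_lsc == plastomics::revcomp(q$lsc))
})

test_that("locus extraction honours the spacer-length threshold", {
  # two genes separated by 150 bp -> 2 CDS + 1 IGS; an 80 bp gap -> no IGS
  build <- function(gap) {
    q <- make_quadripartite(lsc = 4000, ir = 1100, ssc = 1400, seed = 13)
    feats <- tibble::tibble(
      fid = c(1L, 2L), name = c("gA", "gB"), kind = "CDS",
      start = c(100L, 400L + gap), end = c(400L, 700L + gap),
      strand = "+", part = 1L)
    regions <- tibble::tibble(region = c("LSC", "IRb", "SSC", "IRa"),
                              start = c(0L, 4000L, 5100L, 6500L),
                              end = c(4000L, 5100L, 6500L, 7600L))
    new_plastome("t1", q$genome, feats, regions)
  }
  lc150 <- extract_loci(list(build(150L)))
  expect_setequal(lc150$manifest$locus, c("gA", "gB", "gA_gB", "gB_gA"))
  expect_equal(sum(lc150$manifest$category == "CDS"), 2)
  lc80 <- extract_loci(list(build(80L)))
  expect_false("gA_gB" %in% lc80$manifest$locus)
  expect_equal(sum(lc80$manifest$category == "CDS"), 2)
})

test_that("synthetic plastomes yield the template locus inventory", {
  syn <- synthesize_plastome_set(sim_config(seed = 23, n_taxa = 5))
  lc <- extract_loci(syn$plastomes)
  counts <- table(lc$manifest$category)
  tpl <- syn$template
  expect_equal(unname(counts[["CDS"]]),
               sum(tpl$type == "gene" & tpl$kind == "CDS"))
  expect_equal(unname(counts[["intron"]]), 5)  # clpP x2, ycf3 x2, trnK x1
  expect_setequal(lc$manifest$locus[lc$manifest$category == "intron"],
                  c("clpP_intron1", "clpP_intron2", "ycf3_intron1",
                    "ycf3_intron2", "trnK_intron"))
  # every locus present in every taxon on a gap-free backbone
  expect_true(all(lc$manifest$n_taxa == 5))
  # partition sanity: extracted loci + tRNA/rRNA exon bodies + the two
  # dropped sub-threshold interior gaps tile LSC+IRb+SSC exactly, up to the
  # IRa overhang of the single spacer crossing the SSC-IRa junction
  one_ir_span <- syn$plastomes[[1]]$regions$end[3]
  extracted <- sum(nchar(vapply(lc$sequences, function(s) s[[1]], character(1))))
  trna_rrna_exons <- sum(tpl$length[tpl$type == "gene" & tpl$kind != "CDS"]) -
    sum(unlist(tpl$intron_lengths[tpl$kind %in% c("tRNA", "rRNA")]))
  dropped_gaps <- 80L + 60L   # matK/rps16 interior gap + rps19/rpl2 junction gap
  ira_overhang <- 140L        # IRa half of the ycf1_rrn16 spacer
  expect_equal(extracted + trna_rrna_exons + dropped_gaps - ira_overhang,
               one_ir_span)
})

test_that("taxa missing a locus are recorded as absent, not an error", {
  syn <- synthesize_plastome_set(sim_config(seed = 24, n_taxa = 4))
  p1 <- syn$plastomes[[1]]
  # drop one gene annotation from the first taxon
  keep <- p1$features$name != "rbcL"
  p1b <- new_plastome(p1$taxon_id, p1$sequence, p1$features[keep, ], p1$regions)
  lc <- extract_loci(c(list(p1b), syn$plastomes[-1]))
  expect_false(p1$taxon_id %in% names(lc$sequences[["rbcL"]]))
  expect_equal(lc$manifest$n_taxa[lc$manifest$locus == "rbcL"], 3)
})
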