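test_that("IR detection recovers a constructed quadripartite circle exactly", {
  q <- make_quadripartite(lsc = 10000, ir = 2000, ssc = 3000, seed = 61)
  det <- detect_inverted_repeats(q$genome, min_ir_length = 1000)
  expect_equal(det$region, c("LSC", "IR1", "SSC", "IR2"))
  expect_equal(det$length, c(10000, 2000, 3000, 2000))
  expect_equal(det$start, c(0, 10000, 12000, 15000))
  # rotation invariance of the region lengths
  for (at in c(1000, 9999, 14321)) {
    det2 <- detect_inverted_repeats(plastomics:::rotate_string(q$genome, at),
                                    min_ir_length = 1000)
    expect_equal(sort(det2$length), sort(det$length))
  }
  # global reverse complement invariance
  det3 <- detect_inverted_repeats(revcomp(q$genome), min_ir_length = 1000)
  expect_equal(sort(det3$length), sort(det$length))
})

test_that("a substitution inside the IR truncates the exact core as brute force says", {
  q <- make_quadripartite(lsc = 2000, ir = 600, ssc = 800, seed = 62)
  g <- q$genome
  # mutate one base 100 bp into IRb (position 2100, 0-based)
  pos <- 2100
  old <- substr(g, pos + 1, pos + 1)
  new <- setdiff(c("A", "C", "G", "T"), old)[1]
  substr(g, pos + 1, pos + 1) <- new
  det <- suppressMessages(detect_inverted_repeats(g, min_ir_length = 300))
  # brute-force longest exact reverse-complement run between the two arms
  irb <- strsplit(substr(g, 2001, 2600), "")[[1]]
  ira_rc <- strsplit(plastomics::revcomp(substr(g, 3401, 4000)), "")[[1]]
  match_run <- rle(irb == ira_rc)
  best <- max(match_run$lengths[match_run$values])
  expect_equal(det$length[det$region == "IR1"], best)
  # the tolerant extension reports the remainder beyond the exact core
  expect_true(sum(attr(det, "mismatch_extension")) > 0)
})

test_that("structure errors are raised for absent or degenerate repeats", {
  set.seed(63)
  plain <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE),
                 collapse = "")
  expect_error(detect_inverted_repeats(plain, min_ir_length = 1000),
               "no inverted repeat|no disjoint")
  expect_error(detect_inverted_repeats(plain, min_ir_length = 2000),
               "shorter than 4 x")
})

test_that("junction offsets are signed distances to the nearest flanks", {
  syn <- synthesize_plastome_set(sim_config(seed = 64, n_taxa = 4))
  jm <- junction_map(syn$plastomes[[1]])
  expect_equal(jm$junction, c("LSC-IRb", "IRb-SSC", "SSC-IRa"))
  lb <- jm[jm$junction == "LSC-IRb", ]
  # template: rps19 ends 60 bp before the junction, rpl2 starts at it
  expect_equal(lb$left_feature, "rps19")
  expect_equal(lb$left_offset, -60L)
  expect_equal(lb$right_feature, "rpl2")
  expect_equal(lb$right_offset, 0L)
  sa <- jm[jm$junction == "SSC-IRa", ]
  expect_equal(sa$left_feature, "ycf1")
  expect_equal(sa$left_offset, -90L)
})

test_that("a gene cut by an IR expansion is reported as spanning the junction", {
  cfg <- sim_config(seed = 65, n_taxa = 6,
                    junction_shift_spec = list(list(taxa = 2, junction = "SSC-IRa",
                                                    shift = 500)))
  syn <- synthesize_plastome_set(cfg)
  shifted <- syn$truth$junction_shifts$taxon_id[1]
  jm <- junction_map(syn$plastomes[[shifted]])
  sa <- jm[jm$junction == "SSC-IRa", ]
  expect_equal(sa$spanning_feature, "ycf1")
  expect_equal(sa$span_right, 500L - 90L)   # 90 bp spacer sat behind ycf1
  expect_equal(sa$span_left, 1650L - (500L - 90L))
})

test_that("junction comparison flags exactly the shifted clade", {
  cfg <- sim_config(seed = 66, n_taxa = 10,
                    junction_shift_spec = list(list(taxa = 3, junction = "SSC-IRa",
                                                    shift = 400)))
  syn <- synthesize_plastome_set(cfg)
  maps <- lapply(syn$plastomes, junction_map)
  cmp <- compare_junctions(maps, syn$species_tree)
  flagged <- sort(unique(cmp$taxon_id[cmp$flagged]))
  expect_equal(flagged, sort(syn$truth$junction_shifts$taxon_id))
  # identical maps -> zero flags
  cfg0 <- sim_config(seed = 66, n_taxa = 10)
  syn0 <- synthesize_plastome_set(cfg0)
  cmp0 <- compare_junctions(lapply(syn0$plastomes, junction_map),
                            syn0$species_tree)
  expect_equal(sum(cmp0$flagged), 0)
  # taxon mismatch errors
  expect_error(compare_junctions(maps, ape::rtree(4)), "disagree")
})

test_that("indel scanning applies the length and carrier thresholds", {
  base <- matrix("A", nrow = 10, ncol = 300,
                 dimnames = list(paste0("t", 1:10), NULL))
  a <- base
  a[1:6, 101:160] <- "-"     # 60 cols, 6 carriers -> one event
  got <- scan_indels(as_alignment(a))
  expect_equal(nrow(got), 1)
  expect_equal(got$alignment_start, 100)
  expect_equal(got$alignment_end, 160)
  expect_equal(got$n_taxa, 6)
  expect_setequal(got$member_taxa[[1]], paste0("t", 1:6))
  # 49 columns -> below min_length
  b <- base; b[1:6, 101:149] <- "-"
  expect_equal(nrow(scan_indels(as_alignment(b))), 0)
  # 5 carriers fails the strict "over five" rule, >= rule accepts it
  c5 <- base; c5[1:5, 101:160] <- "-"
  expect_equal(nrow(scan_indels(as_alignment(c5))), 0)
  expect_equal(nrow(scan_indels(as_alignment(c5),
                                indel_config(min_taxa_rule = ">="))), 1)
  # polarity: minority carriers are deletions, majority insertions
  d3 <- base; d3[1:3, 101:160] <- "-"
  expect_equal(scan_indels(as_alignment(d3), indel_config(min_taxa = 2))$polarity,
               "deletion")
  d7 <- base; d7[1:7, 101:160] <- "-"
  expect_equal(scan_indels(as_alignment(d7))$polarity, "insertion")
})

test_that("runs split when the carrier set changes and ignore all-gap columns", {
  base <- matrix("A", nrow = 10, ncol = 400,
                 dimnames = list(paste0("t", 1:10), NULL))
  a <- base
  a[1:6, 101:220] <- "-"
  a[1:7, 161:220] <- "-"     # nested wider indel in the second half
  got <- scan_indels(as_alignment(a))
  expect_equal(nrow(got), 2)
  expect_equal(got$alignment_start, c(100, 160))
  expect_equal(got$n_taxa, c(6L, 7L))
  # all-gap columns are not shared indels
  b <- base; b[, 101:160] <- "-"
  expect_equal(nrow(scan_indels(as_alignment(b))), 0)
})

test_that("indel events shift coherently under concatenation and row permutation", {
  base <- matrix("A", nrow = 10, ncol = 200,
                 dimnames = list(paste0("t", 1:10), NULL))
  a1 <- base; a1[1:6, 51:120] <- "-"
  a2 <- base; a2[3:9, 21:90] <- "-"
  cat12 <- cbind(a1, a2)
  e1 <- scan_indels(as_alignment(a1)); e2 <- scan_indels(as_alignment(a2))
  ec <- scan_indels(as_alignment(cat12))
  expect_equal(ec$alignment_start, c(e1$alignment_start, e2$alignment_start + 200))
  expect_equal(ec$length, c(e1$length, e2$length))
  # permuting non-member rows leaves the member set unchanged
  perm <- c(1:6, sample(7:10))
  ep <- scan_indels(as_alignment(a1[perm, ]))
  expect_setequal(ep$member_taxa[[1]], e1$member_taxa[[1]])
})

test_that("injected indels are recovered exactly; sub-threshold ones never", {
  cfg <- sim_config(seed = 67, n_taxa = 10,
    indel_spec = list(
      list(locus = "igs_trnS_rbcL", length = 60, carriers = 6),
      list(locus = "igs_rbcL_clpP", length = 120, carriers = 7),
      list(locus = "igs_psbA_trnK", length = 49, carriers = 7),   # too short
      list(locus = "igs_ndhF_ndhA", length = 80, carriers = 5)))  # too few
  syn <- synthesize_plastome_set(cfg)
  got <- scan_indels(syn$alignment, indel_config(), locus_map = syn$locus_map)
  truth <- syn$truth$indels
  qualifying <- truth[truth$length >= 50 & truth$n_taxa > 5, ]
  expect_equal(nrow(got), nrow(qualifying))
  expect_setequal(got$alignment_start, qualifying$alignment_start)
  expect_setequal(got$alignment_end, qualifying$alignment_end)
  expect_setequal(got$locus, qualifying$locus)
  for (i in seq_len(nrow(got))) {
    tr <- qualifying[qualifying$alignment_start == got$alignment_start[i], ]
    expect_setequal(got$member_taxa[[i]], tr$member_taxa[[1]])
  }
})

test_that("BED export maps alignment columns to ungapped reference positions", {
  a <- matrix("A", nrow = 10, ncol = 200,
              dimnames = list(paste0("t", 1:10), NULL))
  a[1:6, 51:120] <- "-"
  events <- scan_indels(as_alignment(a))
  bed <- indel_bed(events, a, reference = "t10")
  expect_equal(bed$start, 50)
  expect_equal(bed$end, 120)
  # reference inside the carriers: interval collapses to an insertion point
  bed2 <- indel_bed(events, a, reference = "t1")
  expect_equal(bed2$start, bed2$end)
})
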