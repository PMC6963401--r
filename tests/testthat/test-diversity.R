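test_that("complete deletion removes every column with missing data", {
  m <- as_alignment(c(a = "ACG-T", b = "ACGTT", c = "ACGTT"))
  expect_equal(ncol(complete_deletion(m)), 4)
  m2 <- as_alignment(c(a = "ACGNT", b = "ACGTT"))
  expect_equal(ncol(complete_deletion(m2)), 4)   # N is missing data
  m3 <- as_alignment(c(a = "AC-", b = "AC-", c = "AC-"))
  expect_equal(ncol(complete_deletion(m3)), 2)   # all-gap column removed
  m4 <- as_alignment(c(a = "ACRT", b = "ACGT"))  # IUPAC ambiguity removed
  expect_equal(ncol(complete_deletion(m4)), 3)
})

test_that("nucleotide diversity matches hand-computed values", {
  id <- matrix("A", nrow = 2, ncol = 600)
  expect_equal(nucleotide_diversity(id), 0)
  # 2 rows differing at 3 of 600 sites -> 0.005
  m <- matrix("A", nrow = 2, ncol = 600)
  m[2, 1:3] <- "C"
  expect_equal(nucleotide_diversity(m), 3 / 600)
  # 4 rows, one ACGT column among 99 constant: all 6 pairs differ once
  m4 <- matrix("G", nrow = 4, ncol = 100)
  m4[, 1] <- c("A", "C", "G", "T")
  expect_equal(nucleotide_diversity(m4), 0.01)
  # zero retained columns -> no-data marker
  expect_true(is.na(nucleotide_diversity(matrix(character(0), nrow = 2))))
})

test_that("pi equals the brute-force mean pairwise difference on random alignments", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(2:6, 1); L <- sample(5:50, 1)
    m <- random_alignment(n, L)
    kept <- complete_deletion(m)
    expect_equal(nucleotide_diversity(kept), oracle_pi(m), tolerance = 1e-12)
  }
})

test_that("pi is permutation-invariant and responds to dilution as expected", {
  set.seed(102)
  m <- random_alignment(5, 40, p_missing = 0)
  kept <- complete_deletion(m)
  base_pi <- nucleotide_diversity(kept)
  perm <- kept[sample(nrow(kept)), , drop = FALSE]
  expect_equal(nucleotide_diversity(perm), base_pi)
  # appending a copy of an existing row strictly decreases pi when pi > 0
  if (base_pi > 0) {
    dup <- rbind(kept, kept[1, , drop = FALSE])
    expect_lt(nucleotide_diversity(dup), base_pi)
  }
  # pi never exceeds the maximum pairwise difference
  pair_max <- max(vapply(utils::combn(nrow(kept), 2, simplify = FALSE),
                         function(ij) mean(kept[ij[1], ] != kept[ij[2], ]),
                         numeric(1)))
  expect_lte(base_pi, pair_max)
})

test_that("sliding windows follow the grid and report GC correctly", {
  m <- as_alignment(setNames(rep(strrep("ACGT", 250), 3), c("a", "b", "c")))
  prof <- sliding_window_profile(m, window = 600, step = 200)
  expect_equal(prof$window_start, seq(0, 800, by = 200))
  expect_true(all(prof$pi == 0))
  expect_true(all(abs(prof$gc - 0.5) < 1e-12))   # ACGT is 50% GC
  expect_equal(prof$n_retained_sites[1], 600)
  # truncated final window reports its actual length
  expect_equal(prof$n_retained_sites[length(prof$n_retained_sites)], 200)
  # GC + AT = 1 on retained columns of random data
  set.seed(103)
  r <- random_alignment(4, 900, p_missing = 0.05)
  pr <- sliding_window_profile(r, 300, 100)
  at <- vapply(seq_len(nrow(pr)), function(i) {
    s0 <- pr$window_start[i]
    sl <- complete_deletion(r[, (s0 + 1):min(s0 + 300, ncol(r)), drop = FALSE])
    sum(sl %in% c("A", "T")) / length(sl)
  }, numeric(1))
  expect_equal(pr$gc + at, rep(1, nrow(pr)), tolerance = 1e-12)
})

test_that("window profile equals direct per-window recomputation", {
  set.seed(104)
  syn <- synthesize_plastome_set(sim_config(seed = 31, n_taxa = 6))
  aln <- syn$alignment[, 1:3000]
  prof <- sliding_window_profile(aln, window = 600, step = 200)
  for (i in seq_len(nrow(prof))) {
    s0 <- prof$window_start[i]
    slice <- aln[, (s0 + 1):min(s0 + 600, ncol(aln)), drop = FALSE]
    expect_equal(prof$pi[i], oracle_pi(slice), tolerance = 1e-12)
  }
})

test_that("short alignments collapse to a single window", {
  m <- as_alignment(c(a = "ACGTACGT", b = "ACGTACGA"))
  prof <- sliding_window_profile(m, window = 600, step = 200)
  expect_equal(nrow(prof), 1)
  expect_equal(prof$n_retained_sites, 8)
})

test_that("delta profiles subtract on a shared grid and reject mismatches", {
  set.seed(105)
  aln <- random_alignment(8, 1200, p_missing = 0.02)
  groups <- tibble::tibble(taxon = rownames(aln),
                           group = rep(c("G1", "G2"), each = 4))
  profs <- group_diversity_profiles(aln, groups, window = 300, step = 100)
  p1 <- profs[profs$group == "G1", -1]; attr(p1, "window") <- 300L; attr(p1, "step") <- 100L
  p2 <- profs[profs$group == "G2", -1]; attr(p2, "window") <- 300L; attr(p2, "step") <- 100L
  d0 <- delta_profile(p1, p1)
  expect_true(all(d0$delta_pi == 0))
  d12 <- delta_profile(p1, p2)
  expect_equal(d12$delta_pi, p1$pi[match(d12$window_start, p1$window_start)] -
                 p2$pi[match(d12$window_start, p2$window_start)])
  # mismatched grids -> coordinate error
  p3 <- sliding_window_profile(aln, window = 400, step = 100)
  expect_error(delta_profile(p1, p3), "window grid")
})

test_that("groups with fewer than two taxa are rejected by name", {
  aln <- as_alignment(c(x = "ACGT", y = "ACGT", z = "ACGT"))
  groups <- tibble::tibble(taxon = c("x", "y", "z"),
                           group = c("G1", "G1", "G2"))
  expect_error(group_diversity_profiles(aln, groups, 4, 2), "fewer than 2")
})

test_that("IR windows are less diverse than LSC windows when the IR evolves slower", {
  syn <- synthesize_plastome_set(sim_config(seed = 33, n_taxa = 8,
                                            ir_rate_multiplier = 0.3))
  prof <- sliding_window_profile(syn$alignment, window = 600, step = 200)
  regions <- syn$plastomes[[1]]$regions
  mids <- prof$window_mid
  in_lsc <- mids < regions$end[1]
  in_ir <- (mids >= regions$start[2] & mids < regions$end[2]) |
    (mids >= regions$start[4])
  expect_lt(mean(prof$pi[in_ir], na.rm = TRUE),
            mean(prof$pi[in_lsc], na.rm = TRUE))
})
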