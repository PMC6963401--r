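test_that("Yule simulation is deterministic and structurally correct", {
  t1 <- simulate_species_tree(8, seed = 71)
  t2 <- simulate_species_tree(8, seed = 71)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(ape::is.rooted(t1))
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))
  expect_equal(ape::Ntip(t1), 8)
  # n = 2: a single cherry whose depth is one exponential draw
  c2 <- simulate_species_tree(2, birth_rate = 1, seed = 72)
  expect_equal(ape::Ntip(c2), 2)
  expect_equal(c2$edge.length[1], c2$edge.length[2])
  expect_error(simulate_species_tree(1), "n_taxa")
})

test_that("mean Yule depth at n = 3 matches the waiting-time closed form", {
  # depth = Exp(2b) + Exp(3b); E = 1/(2b) + 1/(3b)
  b <- 1.5
  set.seed(73)
  depths <- vapply(1:4000, function(i) {
    tr <- simulate_species_tree(3, birth_rate = b)
    max(ape::node.depth.edgelength(tr))
  }, numeric(1))
  expected <- 1 / (2 * b) + 1 / (3 * b)
  se <- stats::sd(depths) / sqrt(length(depths))
  expect_lt(abs(mean(depths) - expected), 3 * se)
})

test_that("coalescent scale 0 reproduces the species tree exactly", {
  st <- simulate_species_tree(7, seed = 74)
  gts <- simulate_gene_trees(st, 5, coalescent_scale = 0, seed = 75)
  for (gt in gts) {
    expect_equal(topo_dist(ape::unroot(gt), ape::unroot(st)), 0)
    # node times coincide with the speciation times
    expect_equal(sort(ape::branching.times(gt)), sort(ape::branching.times(st)),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # determinism
  gts2 <- simulate_gene_trees(st, 5, coalescent_scale = 0, seed = 75)
  expect_identical(lapply(gts, ape::write.tree), lapply(gts2, ape::write.tree))
})

test_that("three-taxon concordance follows 1 - (2/3) exp(-T)", {
  # species tree ((A,B),C) with internal branch length L; T = L / scale
  st <- ape::read.tree(text = "((A:1.5,B:1.5):1.0,C:2.5);")
  scale <- 0.8
  T_coal <- 1.0 / scale
  p_exp <- 1 - (2 / 3) * exp(-T_coal)
  set.seed(76)
  n <- 1500
  gts <- simulate_gene_trees(st, n, coalescent_scale = scale)
  concordant <- vapply(gts, function(gt) is_monophyletic(gt, c("A", "B")),
                       logical(1))
  p_hat <- mean(concordant)
  se <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(p_hat - p_exp), 3 * se)
})

test_that("sequence evolution hits the JC expectation and stationary frequencies", {
  # two taxa at divergence 2t: E[p] = (3/4)(1 - exp(-8t/3))
  t <- 0.05
  two <- ape::read.tree(text = sprintf("(x:%f,y:%f);", t, t))
  L <- 20000
  aln <- evolve_alignment(two, L, kappa = 1,
                          base_freqs = c(A = .25, C = .25, G = .25, T = .25),
                          seed = 77)
  p_hat <- mean(aln["x", ] != aln["y", ])
  p_exp <- 3 / 4 * (1 - exp(-8 * t / 3))
  se <- sqrt(p_exp * (1 - p_exp) / L)
  expect_lt(abs(p_hat - p_exp), 3 * se)
  # zero branch lengths -> identical rows
  z <- ape::read.tree(text = "(x:0,y:0);")
  az <- evolve_alignment(z, 500, seed = 78)
  expect_equal(az["x", ], az["y", ], ignore_attr = TRUE)
  # base composition follows the stationary distribution
  freqs <- c(A = 0.4, C = 0.1, G = 0.2, T = 0.3)
  am <- evolve_alignment(two, 20000, base_freqs = freqs, seed = 79)
  obs <- table(am)[c("A", "C", "G", "T")] / length(am)
  expect_true(all(abs(obs - freqs) < 3 * sqrt(freqs * (1 - freqs) / length(am))))
  # determinism
  expect_identical(evolve_alignment(two, 100, seed = 80),
                   evolve_alignment(two, 100, seed = 80))
})

test_that("HKY transition probabilities match the matrix exponential", {
  model <- plastomics:::hky_model(kappa = 3,
                                  base_freqs = c(A = .35, C = .15, G = .2, T = .3))
  # reference via eigen-based expm on the generator itself
  P_ref <- function(t) {
    e <- eigen(model$Q)
    Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
  }
  for (t in c(0.01, 0.2, 1.5)) {
    ref <- P_ref(t)
    for (s in 1:4) {
      got <- plastomics:::hky_probs_from(model, s, t)
      expect_equal(as.numeric(got), ref[s, ], tolerance = 1e-8)
    }
  }
})

test_that("synthesis is deterministic and the alignment matches the genomes", {
  cfg <- sim_config(seed = 81, n_taxa = 5)
  s1 <- synthesize_plastome_set(cfg)
  s2 <- synthesize_plastome_set(cfg)
  expect_identical(s1$plastomes[[3]]$sequence, s2$plastomes[[3]]$sequence)
  expect_identical(s1$alignment, s2$alignment)
  # without injections, each taxon's genome is its alignment row (one IR
  # copy mirrored) and the regions match detection
  tx <- names(s1$plastomes)[2]
  row <- paste(s1$alignment[tx, ], collapse = "")
  expect_identical(row, s1$plastomes[[tx]]$sequence)
  det <- detect_inverted_repeats(s1$plastomes[[tx]]$sequence)
  truth <- s1$truth$regions[s1$truth$regions$taxon_id == tx, ]
  expect_equal(det$start, truth$start)
  expect_equal(det$length, truth$end - truth$start)
})

test_that("resolvability conditioning floors internal branches as configured", {
  set.seed(82)
  cfg <- sim_config(seed = 82)
  for (i in 1:10) {
    st <- simulate_study_tree(cfg)
    internal <- st$edge[, 2] > ape::Ntip(st)
    expect_gte(min(st$edge.length[internal]),
               cfg$min_internal_frac * cfg$tree_height - 1e-12)
    expect_equal(max(ape::node.depth.edgelength(st)), cfg$tree_height,
                 tolerance = 1e-9)
  }
})
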