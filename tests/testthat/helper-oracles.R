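# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the code paths they are used to check.

# brute-force nucleotide diversity: mean pairwise mismatch fraction over
# columns that are pure A/C/G/T in every row
oracle_pi <- function(mat) {
  ok <- apply(mat, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  mat <- mat[, ok, drop = FALSE]
  if (ncol(mat) == 0) return(NA_real_)
  n <- nrow(mat)
  diffs <- c()
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    diffs <- c(diffs, mean(mat[i, ] != mat[j, ]))
  }
  mean(diffs)
}

# random alignment with gaps/Ns sprinkled in
random_alignment <- function(n, L, p_missing = 0.1) {
  chars <- sample(c("A", "C", "G", "T"), n * L, replace = TRUE)
  miss <- runif(n * L) < p_missing
  chars[miss] <- sample(c("-", "N"), sum(miss), replace = TRUE)
  m <- matrix(chars, nrow = n)
  rownames(m) <- paste0("t", seq_len(n))
  plastomics::as_alignment(m)
}

# unrooted bipartitions of a tree, canonicalized as sorted-label strings of
# the side containing the alphabetically first tip; trivial splits excluded
oracle_splits <- function(tree) {
  n <- length(tree$tip.label)
  first <- sort(tree$tip.label)[1]
  # descendants of each internal edge by manual accumulation
  desc <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  internal_children <- setdiff(tree$edge[, 2], seq_len(n))
  splits <- character(0)
  for (node in internal_children) {
    side <- desc(node)
    if (length(side) <= 1 || length(side) >= n - 1) next
    if (!(first %in% side)) side <- setdiff(tree$tip.label, side)
    splits <- c(splits, paste(sort(side), collapse = "|"))
  }
  unique(splits)
}

# majority-rule split set by direct counting
oracle_majority_splits <- function(trees, threshold = 0.5) {
  counts <- table(unlist(lapply(trees, oracle_splits)))
  names(counts)[counts / length(trees) > threshold]
}

# tiny synthetic GenBank record builder
make_genbank_text <- function(taxon = "toy1", sequence = NULL, features = NULL) {
  if (is.null(sequence)) {
    sequence <- paste(rep("ACGTACGTGG", 20), collapse = "")
  }
  if (is.null(features)) {
    features <- c(
      "     gene            11..40",
      "                     /gene=\"geneA\"",
      "     CDS             11..40",
      "                     /gene=\"geneA\"",
      "     gene            complement(61..130)",
      "                     /gene=\"geneB\"",
      "     CDS             complement(61..130)",
      "                     /gene=\"geneB\""
    )
  }
  c(sprintf("LOCUS       %s %d bp    DNA     circular PLN", taxon, nchar(sequence)),
    "FEATURES             Location/Qualifiers",
    features,
    "ORIGIN",
    vapply(seq(1, nchar(sequence), 60), function(i) {
      sprintf("%9d %s", i, tolower(substr(sequence, i, min(i + 59, nchar(sequence)))))
    }, character(1)),
    "//")
}

# a constructed quadripartite circle with non-complementary junction flanks
make_quadripartite <- function(lsc = 5000, ir = 1200, ssc = 1500, seed = 99) {
  set.seed(seed)
  draw <- function(k) paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                            collapse = "")
  repeat {
    lsc_s <- draw(lsc); ir_s <- draw(ir); ssc_s <- draw(ssc)
    g <- paste0(lsc_s, ir_s, ssc_s, plastomics::revcomp(ir_s))
    ok <- substr(lsc_s, lsc, lsc) != chartr("ACGT", "TGCA", substr(lsc_s, 1, 1)) &&
      substr(ssc_s, ssc, ssc) != chartr("ACGT", "TGCA", substr(ssc_s, 1, 1))
    if (ok) return(list(genome = g, lsc = lsc_s, ir = ir_s, ssc = ssc_s))
  }
}

# scalar unrooted topological (RF) distance; strips the "dist" attributes
topo_dist <- function(a, b) as.numeric(ape::dist.topo(a, b))
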