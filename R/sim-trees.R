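# Tree simulators: pure-birth (Yule) species trees and
# multispecies-coalescent (MSC) gene trees with one sampled lineage per
# species. Both are pure functions of (parameters, seed).

#' Simulate a pure-birth (Yule) species tree
#'
#' Forward simulation: starting from the root split (two lineages), each
#' interval with `k` active lineages lasts `Exp(k * birth_rate)`, a uniformly
#' chosen lineage splits, and after the n-th lineage appears a final
#' `Exp(n * birth_rate)` stretch runs to the present. The result is rooted,
#' ultrametric and binary; for `n_taxa = 2` the depth is a single
#' `Exp(2 * birth_rate)` draw.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param birth_rate Speciation rate (> 0).
#' @param seed Optional integer seed (deterministic output given the seed).
#' @param tip_prefix Prefix for tip labels (`sp01`, `sp02`, ...).
#' @param min_internal_frac Resolvability conditioning: when > 0, trees are
#'   redrawn until every internal branch is at least this fraction of the
#'   root-to-tip depth. The default 0 is the unconditioned Yule process;
#'   study generators condition on resolvable trees so that finite loci can
#'   recover the topology.
#' @return A rooted ultrametric `phylo`.
#' @export
simulate_species_tree <- function(n_taxa, birth_rate = 1, seed = NULL,
                                  tip_prefix = "sp", min_internal_frac = 0) {
  if (n_taxa < 2L) abort("Input error: n_taxa must be >= 2.")
  stopifnot(birth_rate > 0, min_internal_frac >= 0, min_internal_frac < 0.5)
  if (!is.null(seed)) set.seed(seed)
  if (min_internal_frac > 0 && n_taxa > 2L) {
    for (attempt in 1:1000) {
      tr <- simulate_species_tree(n_taxa, birth_rate, seed = NULL,
                                  tip_prefix = tip_prefix)
      depth <- max(ape::node.depth.edgelength(tr))
      internal <- tr$edge[, 2] > n_taxa
      if (min(tr$edge.length[internal]) >= min_internal_frac * depth) return(tr)
    }
    abort("Could not draw a tree satisfying min_internal_frac in 1000 attempts.")
  }
  # lineages: id, parent event node, birth time
  next_node <- 1L
  lineages <- list(list(parent = 0L, birth = 0), list(parent = 0L, birth = 0))
  events <- list()  # internal nodes: id, parent, time
  events[[1]] <- list(id = 0L, parent = NA_integer_, time = 0)
  t <- 0
  k <- 2L
  while (k < n_taxa) {
    t <- t + rexp(1, k * birth_rate)
    pick <- sample.int(k, 1L)
    node_id <- next_node; next_node <- next_node + 1L
    events[[length(events) + 1L]] <- list(id = node_id,
                                          parent = lineages[[pick]]$parent,
                                          time = t,
                                          birth = lineages[[pick]]$birth)
    lineages[[pick]] <- list(parent = node_id, birth = t)
    lineages[[k + 1L]] <- list(parent = node_id, birth = t)
    k <- k + 1L
  }
  t_present <- t + rexp(1, k * birth_rate)

  # assemble the phylo object
  n <- n_taxa
  n_internal <- length(events)
  # internal ape ids: root (event id 0) = n+1; others in creation order
  int_id <- function(ev_id) n + 1L + ev_id
  edges <- matrix(0L, nrow = 0, ncol = 2)
  elens <- numeric(0)
  for (e in events[-1]) {
    edges <- rbind(edges, c(int_id(e$parent), int_id(e$id)))
    elens <- c(elens, e$time - e$birth)
  }
  for (i in seq_along(lineages)) {
    edges <- rbind(edges, c(int_id(lineages[[i]]$parent), i))
    elens <- c(elens, t_present - lineages[[i]]$birth)
  }
  tr <- structure(list(edge = edges, edge.length = elens,
                       tip.label = sprintf("%s%02d", tip_prefix, seq_len(n)),
                       Nnode = n_internal),
                  class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

#' Simulate multispecies-coalescent gene trees within a species tree
#'
#' One gene lineage is sampled per species. Within each species-tree branch,
#' `k` lineages coalesce at rate `choose(k, 2) / coalescent_scale` per unit
#' of species-tree branch length; remaining lineages coalesce above the
#' root. `coalescent_scale = 0` forces immediate coalescence at each
#' speciation node, so every gene tree matches the species tree exactly
#' (topology and node times).
#'
#' @param species_tree Rooted `phylo` with branch lengths.
#' @param n_loci Number of gene trees to simulate.
#' @param coalescent_scale Coalescent time scale relative to species-tree
#'   branch lengths (>= 0). Larger values mean more incomplete lineage
#'   sorting.
#' @param seed Optional integer seed.
#' @return A named list of rooted `phylo` gene trees (`locus1`, ...), branch
#'   lengths in species-tree time units.
#' @export
simulate_gene_trees <- function(species_tree, n_loci, coalescent_scale = 0.1,
                                seed = NULL) {
  stopifnot(inherits(species_tree, "phylo"), !is.null(species_tree$edge.length),
            ape::is.rooted(species_tree), coalescent_scale >= 0, n_loci >= 1)
  if (!is.null(seed)) set.seed(seed)
  st <- species_tree
  n <- length(st$tip.label)
  root <- n + 1L
  # node ages (time before present); tips at age 0
  depth <- ape::node.depth.edgelength(st)
  age <- max(depth) - depth
  age[seq_len(n)] <- 0
  out <- lapply(seq_len(n_loci), function(l) msc_one_locus(st, age, coalescent_scale))
  names(out) <- paste0("locus", seq_len(n_loci))
  out
}

msc_one_locus <- function(st, age, scale) {
  n <- length(st$tip.label)
  root <- n + 1L
  children <- split(st$edge[, 2], st$edge[, 1])
  # gene-tree bookkeeping: growing node table
  g_parent <- integer(0); g_len <- numeric(0)
  g_next <- n + 1L
  g_age <- numeric(0)  # age of each gene node (tips implicitly 0)
  node_age <- function(id) if (id <= n) 0 else g_age[[id - n]]
  merges <- list()

  # coalesce within [t_from, t_to] (ages increasing toward the root);
  # returns surviving lineage ids
  coalesce_interval <- function(lin, t_from, t_to) {
    t <- t_from
    while (length(lin) >= 2L) {
      if (scale == 0) {
        # immediate coalescence where the lineages first meet
        while (length(lin) >= 2L) {
          pair <- sample.int(length(lin), 2L)
          lin <- do_merge(lin, pair, t_from)
        }
        break
      }
      w <- rexp(1, choose(length(lin), 2) / scale)
      if (t + w > t_to) break
      t <- t + w
      pair <- sample.int(length(lin), 2L)
      lin <- do_merge(lin, pair, t)
    }
    lin
  }
  do_merge <- function(lin, pair, t_new) {
    new_id <- g_next
    g_next <<- g_next + 1L
    g_age[[new_id - n]] <<- t_new
    merges[[length(merges) + 1L]] <<- list(id = new_id, kids = lin[pair],
                                           time = t_new)
    c(lin[-pair], new_id)
  }

  # postorder over species nodes by increasing age
  sp_nodes <- order(age)  # tips first
  lineages_at <- vector("list", n + st$Nnode)
  for (tip in seq_len(n)) lineages_at[[tip]] <- tip
  internal <- sp_nodes[sp_nodes > n]
  for (v in internal[order(age[internal])]) {
    kids <- children[[as.character(v)]]
    merged <- integer(0)
    for (ch in kids) {
      lin <- lineages_at[[ch]]
      lin <- coalesce_interval(lin, age[ch], age[v])
      merged <- c(merged, lin)
    }
    lineages_at[[v]] <- merged
  }
  root_lin <- lineages_at[[root]]
  # above the root: coalesce to one
  if (length(root_lin) >= 2L) {
    if (scale == 0) {
      root_lin <- coalesce_interval(root_lin, age[root], age[root])
    } else {
      t <- age[root]
      while (length(root_lin) >= 2L) {
        t <- t + rexp(1, choose(length(root_lin), 2) / scale)
        pair <- sample.int(length(root_lin), 2L)
        root_lin <- do_merge(root_lin, pair, t)
      }
    }
  }

  # build phylo from merges
  n_int <- length(merges)
  edges <- matrix(0L, nrow = 0, ncol = 2)
  elens <- numeric(0)
  for (m in merges) {
    for (kid in m$kids) {
      edges <- rbind(edges, c(m$id, kid))
      elens <- c(elens, m$time - node_age(kid))
    }
  }
  # renumber internal nodes so the last merge (the root) becomes n+1
  ids <- vapply(merges, function(m) m$id, integer(1))
  times <- vapply(merges, function(m) m$time, numeric(1))
  new_ids <- setNames(n + 1L + rank(-times, ties.method = "first") - 1L,
                      as.character(ids))
  remap <- function(v) ifelse(v <= n, v, new_ids[as.character(v)])
  edges2 <- cbind(as.integer(remap(edges[, 1])), as.integer(remap(edges[, 2])))
  tr <- structure(list(edge = edges2, edge.length = elens,
                       tip.label = st$tip.label, Nnode = n_int),
                  class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  if (length(unique(edges2[, 1])) != n_int) {
    abort("Internal error: malformed coalescent tree.")
  }
  # zero-length multifurcation-equivalents from scale = 0 are kept binary
  tr
}
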