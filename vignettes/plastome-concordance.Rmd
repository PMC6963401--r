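---
title: "Comparative plastome phylogenomics with plastomics: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastome phylogenomics with plastomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomics)
library(ape)
```

## The analysis this package implements

Plastid genomes (plastomes) are ~150 kb circles with a conserved
quadripartite architecture: a large single-copy region (LSC), a small
single-copy region (SSC), and two identical inverted repeats (IRb, IRa)
separating them. Because gene content and order are stable, whole-plastome
comparisons within a genus or family support three complementary analyses,
and `plastomics` implements all three as one pipeline:

1. **Sliding-window nucleotide diversity.** On a whole-plastome alignment,
   per-window diversity `pi` (mean pairwise differences per retained site)
   and GC content locate the variable regions that make good markers, and
   the difference of two groups' profiles (delta `pi`) contrasts their
   mutational dynamics.
2. **Gene-tree/species-tree concordance in Kendall–Colijn tree space.**
   Each extracted locus yields a gene tree; gene trees plus a reference
   species tree (here, the majority-rule consensus of several species-tree
   estimates) are embedded by their Kendall–Colijn vectors, projected onto
   principal coordinates, and clustered. Loci whose gene trees share the
   reference's cluster are nominated as phylogenetic markers; a per-tree
   genus-monophyly screen provides an orthogonal concordance measure.
3. **Structural comparison.** IR detection and canonical orientation give
   every plastome comparable coordinates; the three junctions (LSC–IRb,
   IRb–SSC, SSC–IRa) are mapped against their flanking genes to reveal IR
   expansion/contraction, and the whole-plastome alignment is scanned for
   large indels shared by several taxa.

A fully seeded synthetic-data generator stands in for the archive downloads
a real study would start from, so every stage can be exercised and verified
against known ground truth.

## Nucleotide diversity

For an alignment slice of `n` sequences and `L` retained sites,

$$\pi = \frac{2}{n(n-1)} \sum_{i<j} \frac{d_{ij}}{L},$$

with `d_ij` the number of differing retained sites for pair `(i, j)`.
Retention is *complete deletion*: every column containing anything other
than `A/C/G/T` in any profiled row — gaps, `N`, or IUPAC ambiguity codes —
is removed before computing either `pi` or GC content. Ambiguity codes are
treated as missing rather than as partial information because the
complete-deletion convention makes the retained-site denominator exact and
shared between `pi` and GC.

Windows are laid on **alignment columns** (0-based starts at `0, step,
2*step, ...`), not on ungapped genome positions, so profiles from different
groups of rows share a coordinate system and can be subtracted. Defaults
are `window = 600`, `step = 200` (bp of alignment). The final window may be
truncated and is reported at its true width; a window retaining zero sites
is kept with `pi = NA` rather than dropped, so window grids always align.
The delta convention is `delta = pi[first-named group] - pi[second]`.

Two caveats worth knowing when reading profiles: complete deletion makes
`pi` sensitive to large deletions in single taxa (the surviving columns
may be atypical), and small palindromic repeats can locally inflate
apparent diversity through alignment ambiguity. Neither effect is modelled
by the generator; on synthetic data the profile reflects substitution rates
only.

## Distance-based gene trees

Gene trees are estimated with JC69 distances and neighbor joining:
`d = -(3/4) log(1 - (4/3) p)` on pairwise-complete sites (pairwise rather
than complete deletion, so sparse loci stay usable; complete deletion is a
flag). Saturated pairs (`p >= 3/4`) are reported and set to a configurable
cap (default 5 substitutions/site) instead of propagating infinities.
Negative NJ branch estimates are clamped to zero with the deficit logged.
This estimator is deliberately simple — deterministic, assumption-light,
and consistent on additive distances — and every downstream entry point
also accepts externally built Newick trees, so maximum-likelihood or
Bayesian gene trees can replace the internal ones without touching the
rest of the pipeline.

## Kendall–Colijn tree space

A rooted tree on `n` tips maps to the vector of, for every unordered tip
pair in fixed lexicographic order,

$$m_{ij} = \lambda\,(\text{root-to-MRCA path length}) +
           (1-\lambda)\,(\text{root-to-MRCA edge count}),$$

followed by one pendant entry per tip
(`lambda * pendant length + (1 - lambda)`). The KC distance is the
Euclidean distance between vectors. `lambda = 0` (the default) compares
topology only; the comparison the concordance analysis needs is
topological, and the default also keeps the metric invariant to
branch-length rescaling. `lambda` is exposed for users who want
branch-length-aware distances.

Unrooted inputs (NJ trees, the consensus) are rooted on a user-supplied
outgroup before vectorization, with the root placed at the midpoint of the
outgroup edge. Trees with unequal tip sets are restricted to the shared
taxon set, with a message; this mirrors how loci missing from a few taxa
are handled in practice.

The distance matrix is projected by classical metric multidimensional
scaling (double-centred `-D^2/2` eigendecomposition). Because KC vectors
live in Euclidean space, the projection is exact at full rank; negative
eigenvalues can only arise numerically and are dropped with a warning.
Five axes are retained by default. Cluster discovery is agglomerative
(Ward linkage by default, on Euclidean distances in the projected space)
with the dendrogram cut at `cutoff_height` (default 100, matching the
scale of bootstrap-supported studies with ~190 trees). On desk-scale
synthetic data the KC distances are far smaller, so `cutoff_height = NULL`
selects the cut automatically in the middle of the largest gap between
successive merge heights; the height actually used is always recorded in
the result and in output headers. Cluster labels are numbered by first
appearance, and the marker-nomination rule is: every tree sharing the
reference tree's cluster, reference excluded.

The cluster report lists clusters of three or more trees by default
(`min_size = 3`), the usual reporting convention for "clusters of similar
trees"; `min_size = 1` lists all.

## Consensus and monophyly

The majority-rule consensus keeps exactly the splits occurring in strictly
more than `threshold` (default 0.5) of the input trees; ties at exactly
the threshold are excluded (strict majority). Rooted inputs produce a
rooted consensus (clade-based counting), unrooted inputs an unrooted one;
retained splits carry their frequency as node labels. As `threshold -> 1`
the result converges to the strict consensus.

Monophyly uses split semantics on unrooted trees (the tip set must form
one side of some bipartition) and clade semantics on rooted trees;
singletons and the full tip set are monophyletic by convention. A gene
tree passes the genus screen when every genus with at least two sampled
tips in that tree is monophyletic.

## Genome structure

**IR detection** is exact seed-and-extend matching: seeds of half the
minimum IR length are matched against the reverse complement of the circle
and extended to maximal exactly reverse-complementary pairs; the longest
disjoint pair wins, the shorter single-copy interval between the arms is
labelled SSC, and equal-length ambiguous candidates are an error that
lists them. Exactness keeps the core invariant testable (`revcomp(IRb) ==
IRa` bit-for-bit); a mismatch-tolerant extension beyond the exact core is
computed separately and only reported. The default minimum IR length is
1,000 bp — far above chance matches, far below real plastome IRs.

**Canonical orientation** rotates (and if necessary reverse-complements)
the circle to `LSC | IRb | SSC | IRa` with LSC starting at position 0.
Two readings satisfy that order; the tie is broken by placing the IR copy
adjacent to the *ycf1*-bearing SSC end as IRa (the near-universal
annotation convention), falling back to the lexicographically smaller LSC
strand when no *ycf1* annotation exists. Canonicalization is idempotent
and invariant to rotation and strand of the input.

**Junction maps** report, for each of the three junctions, the nearest
feature boundary on each side with signed offsets, plus any feature
spanning the junction with its spanned lengths (the partial genes
characteristic of IR boundary shifts). `compare_junctions()` orders taxa
by a guide tree and flags every taxon whose junction-flank configuration
differs from the modal configuration at that junction — a deliberate,
simple reference: with shifts confined to a minority of taxa the mode is
the ancestral state, which is the regime the comparison is designed for.

**Indel scanning** finds maximal runs of gap columns with a constant
carrier set (so nested indels split into separate events), keeps events of
at least `min_length` (default 50 bp) whose carrier count satisfies the
`min_taxa` rule, and assigns polarity by the minority rule (carriers in
the minority = deletion). "Occurring in over five species" is read
strictly (`> 5`, i.e. at least 6 carriers); `>=` is available as a flag
because the boundary convention is genuinely ambiguous.

## The synthetic-data generator

The generator emulates the statistical structure the analyses assume,
not any particular genome:

* **Species trees** are pure-birth (Yule): with `k` lineages the next
  split waits `Exp(k * birth_rate)`, and a final `Exp(n * birth_rate)`
  stretch runs to the present. Trees are rescaled to `tree_height`
  root-to-tip expected substitutions per site.
* **Gene trees** follow the multispecies coalescent with one lineage per
  species; `coalescent_scale` converts species-tree branch lengths into
  coalescent units (0 = every gene tree equals the species tree; large
  values approach the star-tree limit). Uniparental plastome inheritance
  motivates the no-migration, no-hybridization model.
* **Sequences** evolve under HKY85 with i.i.d. gamma site rates, via the
  spectral decomposition of the normalized generator (so per-site
  distances vectorize exactly rather than through discretized rate
  categories). Defaults: `kappa = 2`, AT-rich stationary frequencies
  (A/T 0.31, C/G 0.19), `gamma_shape = 1`.
* **Plastomes** are assembled from a fixed ~29 kb template
  (LSC 14.6 kb, IR 4.3 kb, SSC 5.6 kb; 20 genes including two-intron
  *clpP*/*ycf3* analogues, a one-intron *trnK* analogue, *rps19* near the
  LSC–IRb junction and *ycf1* near the SSC–IRa junction). Each template
  element evolves on its own genealogy; IR elements evolve at
  `ir_rate_multiplier` (default 0.3) of the single-copy rate and exist as
  one evolving copy mirrored exactly into IRa, reproducing both concerted
  IR evolution and the IR diversity depression.
* **Structural variants** are injected with exact ground truth: indels
  into single-copy spacer elements (carriers' alignment rows gapped and
  their genomes shortened coherently), and junction shifts as IR
  expansions (region boundaries move and the duplicated segment's reverse
  complement is inserted into the other IR copy, so `IRa == revcomp(IRb)`
  is preserved exactly). The whole-plastome alignment deliberately omits
  junction-shift duplications — shifts are exercised through the genome
  route (detection, junction maps), indels through the alignment route —
  which keeps both ground truths exact instead of coupling them.

Two generator details are worth stating explicitly:

* **Junction guards.** The single-copy alignment columns flanking every
  (possibly shifted) junction are pinned to `A` in all taxa. A chance
  complementary base at a junction would otherwise let the maximal exact
  reverse-complement match extend a few bases past the designed boundary,
  making "recovered exactly" an ill-posed assertion. The pinned columns
  are a negligible fraction of the genome.
* **Resolvability conditioning.** Pure Yule trees contain, with
  appreciable probability, internal branches carrying less than one
  expected substitution at realistic locus lengths; no finite-locus
  estimator can recover those. The study generator therefore redraws
  species trees until every internal branch is at least
  `min_internal_frac` (default 0.05) of the tree depth, and sets
  `tree_height = 0.2` — the deep (order-scale) end of plastome divergence.
  Under these conditions NJ on 2 kb loci recovers the species-tree
  topology for ~99% of loci (measured over 20 seeds x 10 loci). The raw
  `simulate_species_tree()` operation keeps `min_internal_frac = 0` so
  the unconditioned Yule waiting-time laws hold exactly.

What passing tests on synthetic data do **not** show about real data:
alignment error (the generator's loci are alignment-free by construction),
rate variation across loci beyond the IR/single-copy contrast,
recombination-free but estimation-noisy gene trees (real discordance mixes
lineage sorting with estimation error), pseudogenes, and small repeats.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run entirely at desk scale:
12 or fewer taxa, a ~29 kb template, 2 kb loci, 60–200 simulated trees,
100 kb for the sequence-evolution limit check — sizes chosen so the whole
suite completes in a couple of minutes while keeping Monte-Carlo checks at
3-standard-error resolution. Tolerances: oracle equivalences are exact to
1e-12; embeddings to 1e-9; stochastic checks use closed-form standard
errors. Ties in clustering are resolved by `hclust`'s deterministic merge
order; NJ ties by `ape`'s implementation, with determinism guaranteed for
fixed input order and seeds everywhere else.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 11, n_taxa = 10,
                  indel_spec = list(list(locus = "igs_trnS_rbcL",
                                         length = 60, carriers = 6)),
                  junction_shift_spec = list(list(taxa = 3,
                                                  junction = "SSC-IRa",
                                                  shift = 500)))
syn <- synthesize_plastome_set(cfg)

groups <- data.frame(taxon = names(syn$plastomes),
                     group = rep(c("GenusA", "GenusB"), each = 5))
div <- run_diversity(syn$alignment, groups)
autoplot(div$profiles)

struct <- run_structure(syn$plastomes, alignment = syn$alignment,
                        guide_tree = syn$species_tree)
struct$indels
subset(struct$junctions, flagged)
```

## Known limitations

* The internal tree estimator is distance-based; supply external ML/
  Bayesian gene trees for publication-grade topologies.
* `compare_junctions()` flags against the global modal configuration, not
  a per-clade ancestral-state reconstruction; with shifts in half or more
  of the taxa the mode may not be ancestral.
* IR detection is exact-match; highly diverged IR copies (rare in
  plastomes) would be reported only through the mismatch-tolerant
  extension attribute.
* GenBank parsing covers the location grammar plastome annotations use
  (`join`, `complement`, partial markers); exotic operators such as
  `order()` are rejected with a parse error.
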