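---
title: "Estimating haplotype population size by line-graph editing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating haplotype population size by line-graph editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linehap)
```

## The model

A diploid individual genotyped at bi-allelic SNPs carries two unobserved
haplotypes; the genotype records, per site, only the unordered pair of
alleles (hom-ref `0`, het `1`, hom-alt `2`). Two individuals *can* share a
haplotype only if their genotypes never disagree by opposite homozygotes.
Encoding this pairwise test as a graph — one node per individual, an edge
where sharing is possible — gives the Clark-consistency (CC) graph.

If every edge of the CC graph were a *true* sharing, the graph would be
the line graph of a hidden root graph whose nodes are haplotypes and whose
edges are genotypes (each genotype joins its two haplotypes; adjacent
genotypes are exactly those sharing an endpoint). Counting the root
graph's nodes estimates the haplotype population size without phasing
anyone. Equivalently, a graph is a line graph iff it is *allelable*: its
nodes can be assigned color pairs so that adjacent nodes share exactly one
color and non-adjacent nodes share none; colors are haplotypes, and the
number of colors used is the estimate. We implement the non-adjacent
clause as "share no color" (rather than merely "distinct color sets")
because a shared color *is* a shared haplotype and would force an edge.

Real data contain spurious edges (consistency by state, missing data) and
bad nodes (partially observed or erroneous genotypes), so the CC graph is
only close to a line graph. The estimator therefore removes a minimum-cost
set of edges and/or nodes to reach a line graph, then counts colors:

* **edge mode** — minimise the number of deleted edges;
* **node mode** — minimise deleted nodes (a hitting set over all
  occurrences of the nine forbidden induced subgraphs, since node deletion
  never creates a new occurrence);
* **combined mode** — deleted edges cost 1, deleted nodes cost `alpha`;
* **edit mode** — edges may also be inserted, with weights (by default an
  insertion costs the number of conflicting sites it would explain away as
  miscalls, capped by the `insert_cap` candidate filter);
* **parsimony mode** — minimise the number of colors directly, allowing
  edges to drop out of the sharing silently; this is the pure-parsimony
  lower bound on the haplotype count and the engine of the phasing loop.

## Recognition and reconstruction

Two independent routes decide line-graphness. The *catalog* route scans
for induced occurrences of the nine minimal non-line graphs (via igraph's
LAD induced-subgraph isomorphism); the *Krausz* route partitions the edges
into cliques with every vertex in at most two cliques, by backtracking
over cell growth, and reads the root graph off the partition (cells and
singly-covered vertices become haplotypes). The shipped catalog was
derived by exhaustive enumeration of all connected graphs on 4–6 vertices
under the Krausz recogniser and cross-checked against networkx's
independent implementation; both agree on exactly nine graphs, the claw
first. One catalog member (the complement of a 4-cycle joined to two
universal vertices) has 11 edges, although the catalog is often quoted as
having at most 10; the enumeration is complete because no minimal
non-line graph has more than six vertices, so we ship the 11-edge graph.

The root graph is unique per connected component except for a triangle
component, which is both `L(K3)` and `L(K1,3)`. We resolve the ambiguity
toward the `K3` root (3 haplotypes, not 4), keeping the estimate a lower
bound, in the same spirit as the parsimony objective. An isolated genotype
contributes a pendant root edge: two fresh haplotypes.

## The integer programs

All five programs are binary programs over color variables `x[v,j]`
(node `v` uses color `j ∈ [1, 2n]`), sharing variables `s[e,j]`, and
deletion/insertion indicators, following the allelability clauses
directly. Color permutation symmetry is broken by an ownership scheme:
nodes are ordered (by descending degree, ties by name — high-degree nodes
first makes the ownership constraints bite earliest; the ordering is
otherwise free), node `i` owns colors `2i-1` and `2i`, a color may be used
only if its owner uses it, and owners use their odd color first. Under
this scheme a node can only use colors introduced at or before its own
position, and a color owned by `i` is unusable by `v` unless `i` and `v`
are adjacent — so the solver-facing model materialises only those `x` and
`s` variables, plus the constraint rows that touch them. The exposed
builders (`build_edge_deletion_ilp()`, `add_symmetry_breaking()`,
`prune_variables()`) construct the full dense model and transform it
stepwise; paired solves in the test suite confirm that symmetry breaking,
pruning and the sparse direct construction all preserve the optimum.

Models are solved with the GLPK branch-and-cut solver (`glpsol`,
single-threaded and deterministic, relative gap 0) through a plain
LP-file interface; the backend sits behind a small solver contract
(`solve_ilp()`) and reports `optimal`, `feasible` (time limit hit, best
incumbent returned and flagged), `timeout` or `infeasible`. The combined
program is solved with pseudocost branching and clique cuts — its
pairwise color-conflict rows aggregate into cliques, which turns hard
masked instances from hours into seconds — while the other programs use
GLPK's defaults, which empirically dominate on dense edge-deletion
instances. The default
wall-clock cap is 600 s per component. Connected components are solved
independently — line-graphness and coloring are component-local — and
components that already are line graphs skip the ILP: their coloring is
read off the reconstructed root, which also pins the triangle ambiguity.
Solutions are verified post hoc: the surviving graph must pass
recognition and the extracted assignment must verify as allelable.

Two formulation details differ deliberately from naive readings of the
program families. In the editing program, the pair constraint is
`x[v,j] + x[u,j] <= 1 + adjacency-after-editing`, where adjacency after
editing is `b_e - d_e + c_e`; this is the only bound consistent with the
sharing family `sum_j s[e,j] = b_e + c_e - d_e` (an inserted edge must be
allowed to share). In the phasing cut, the inner sum ranges over all `2n`
colors of the edges in the conflicting set.

## The phasing loop

The parsimony program proposes a sharing set `I`. For each `I`-connected
set, a partial phasing is grown from a seed edge: the shared haplotype is
fixed wherever either endpoint is homozygous (the homozygote's allele is
the only one consistent with sharing — at a site where one individual is
homozygous and the other heterozygous, the shared haplotype must carry
the homozygote's allele), complements propagate through heterozygous
sites, and new nodes join by the triangle rule (if `u`, `v`, `w` all
share under `I`, then `v` takes the haplotype `u` shares with `w`,
otherwise `u`'s other haplotype). Every site, once fixed, never flips;
propagation runs to a fixed point after each extension, and all of a
node's connections into the grown set must agree on which haplotype is
shared. A contradiction yields a cut — over the implicated sharing edges
`C`, `sum_{e in C} sum_j s[e,j] <= |C| - 1` — and the program is
re-solved; each cut excludes the incumbent sharing pattern, so the loop
terminates (bounded further by `max_rounds`). If the cut-augmented
program ever becomes infeasible the loop stops and reports it (status
`stalled`) rather than guessing a phasing. Sites never forced either way
are reported as `?`; a genotype's two output haplotypes reproduce it at
every fixed site.

## The simulators and what they (do not) show

**Bottleneck scenario.** An ancestral pool of `k` *distinct* haplotypes
expands; each sampled individual draws two distinct pool haplotypes with
replacement, so present-day sharing is pure identity by descent and the
true count is the number of distinct pool haplotypes drawn. Pool
haplotypes span a long (multi-centimorgan) locus, which we emulate by
giving each 10-marker block an independent neutral genealogy (sites
placed on an `ape::rcoal` tree in proportion to branch length, tip labels
re-randomised per block since `rcoal`'s tip numbering follows the tree
shape); one private marker per haplotype guarantees distinctness. Block
independence matters: a single shared genealogy would leave a third or
more of unrelated pairs consistent by state, whereas real multi-block
haplotypes discriminate sharply. Defaults: 3000 sites, coverage
(`2n / k`) set by the caller.

**Recombinant scenario.** `2n` haplotypes are drawn from a coalescent
with recombination (msprime behind a thin engine contract; a windowed
pure-R approximation is available offline) over 1 Mb with per-bp rates
`mu = 1e-8` and `r = 1e-7`, ancestral size `N0`, and paired sequentially.
Here haplotypes are *not* all distinct — recently related samples carry
identical marker haplotypes — so truth is counted on distinct sequences
and true sharing is sequence identity. The rate defaults were fixed by
requiring the generator to reproduce, simultaneously, the expected
segregating-site counts (`4 N0 mu L a_{2n-1}`) and the expected distinct
haplotype counts (Ewens with novelty rate `4 N0 (mu + r) L`) of the study
regimes this package targets; with them, instance statistics (SNPs,
edges, true counts, deletion loads) land where the method's published
operating range lies.

**Partial genotypes.** `mask_partial()` hides a uniform 70% of markers
(default `observed_fraction = 0.3`) of chosen individuals. Missing calls
are wildcards — the only reading under which partially observed genotypes
*gain* consistency edges, which is the failure mode the combined mode is
for. Masking therefore only ever adds edges.

Passing tests on these generators show that the estimator recovers
identity-by-descent structure and degrades gracefully under
identity-by-state noise and missingness. They do not show robustness to
genotyping *miscalls* (the edit mode exists for that, but no error model
is simulated by default), to multi-allelic or indel variation, or to real
LD structure, which block-independent genealogies only caricature.

## Numerical and design choices

* Missing genotype calls are wildcards in the consistency test; duplicate
  genotype call vectors collapse to one node before graph construction
  (the multiplicity is reported; two individuals with the same haplotype
  pair are one edge of the root graph). Individuals with no heterozygous
  site are set aside — each carries exactly one directly observable
  haplotype — and the distinct ones among them are added to the final
  estimate and reported separately.
* Deterministic tie-breaks throughout: forbidden occurrences are
  deduplicated by sorted vertex set and ordered lexicographically; the
  phasing loop seeds on the lexicographically first sharing edge and
  grows toward the lowest-labelled neighbor; ILP ties are broken by the
  solver, so deleted-edge sets are reported as *one* optimal solution,
  never the unique one.
* The estimate attached to a deletion solution is the color count of the
  assignment found at the deletion optimum; the separately exposed
  parsimony count is never silently substituted. Which of the two a
  study should report is a judgement call — they coincide on clean data
  and the parsimony count is the more conservative lower bound.
* Edit-mode insertion candidates are capped (`insert_cap = 2` conflicting
  sites by default) to keep the pair space near-linear; the full
  `V x V` candidate set is available via `all_pairs = TRUE`.
* Problem sizes used by the validation scripts — 50-genotype samples,
  ancestral sizes 500–1000, solver caps of 120–150 s per component — were
  chosen so a full validation run completes on a laptop-class single core
  while staying inside the method's published operating range. Clean and
  moderately noisy instances solve to proven optimality in seconds; the
  densest ones (ancestral size 500) return flagged incumbents at the cap,
  whose extra deletions can only raise the reported count.

## Known limitations

* The node-deletion mode enumerates all forbidden occurrences first; on
  dense graphs with many claws this list (not the ILP) dominates cost.
  The combined mode avoids enumeration entirely.
* GLPK is branch-and-cut without the engineering of commercial solvers;
  hard instances (hundreds of spurious edges) may return flagged
  incumbents at the time limit instead of proven optima.
* The phasing loop guarantees soundness of what it fixes, not global
  parsimony optimality of the final phasing, and leaves genuinely
  undetermined sites unphased.
* Pooled-sequencing consistency graphs are out of scope: the pool-level
  consistency predicate between conflated genotypes is not defined here.
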