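---
title: "Methods: species-tree-aware gene trees, homology and gene gain/loss for ncRNA families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: species-tree-aware gene trees, homology and gene gain/loss for ncRNA families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genetreekit)
```

## Overview

Short non-coding RNA genes (miRNAs, snoRNAs, snRNAs, ...) are hard to place
on gene trees: the sequences are short, poorly conserved at the nucleotide
level, and constrained by secondary structure rather than by codon content.
A practical remedy is to build *several* candidate trees per family — under
different RNA substitution models, and from genomic alignments that include
the flanking DNA — and then combine them into a single tree that is
consistent with the species phylogeny. `genetreekit` implements that
combination step and everything downstream of it:

1. LCA reconciliation of a gene tree with a species tree, with duplication
   and loss inference and duplication-loss-parsimony rooting;
2. the consensus merge of multiple candidate trees (`mmerge`), which prefers
   speciation splits, then splits implying fewer losses, then better
   bootstrap support;
3. duplication confidence scores (DCS) and dubious-duplication flagging;
4. orthologue/paralogue classification with a synteny-based QC;
5. K tree-score ranking of candidate trees against the merged tree;
6. a single-rate birth-death model of gene family sizes on an ultrametric
   species tree, with maximum-likelihood estimation of the gain/loss rate
   λ; and
7. simulators that generate every input the pipeline consumes, so the whole
   stack can be exercised and validated without any external data.

## Reconciliation model

Given a rooted gene tree with species-labelled leaves and a rooted species
tree, each leaf maps to its species and each internal node maps to the LCA
of its children's mappings. A node is a **duplication** when its mapping
equals the mapping of at least one child, otherwise a **speciation**.

**Multifurcating taxa.** Species trees may contain multifurcations —
either genuinely unresolved taxa or clades deliberately flattened with
`simplify_species_tree()` (the analysis flattens densely sampled clades such
as eutherian mammals so that annotation bias inside them does not masquerade
as duplication). Under the plain mapping-equality rule a flattened clade
would *increase* duplication calls: any node whose children together span
two or more clade members maps to the flattened node, and so do its
children. Since a multifurcation means "branching order unknown", any
laminar split of its members is compatible with some resolution. Nodes
mapped to a multifurcating taxon are therefore labelled duplications only
when two child subtrees **share a species**. On binary species trees this
rule is provably identical to mapping-equality, so nothing changes where
the species tree is resolved.

**Losses.** The losses on the gene-tree edge from `u` down to `v` are
`pathlen(m(u), m(v)) − 1`, plus one if `u` is a duplication mapped above
`v` (the second copy must have been lost on the way down), floored at zero;
`pathlen` counts species-tree edges. A multifurcation is a single level:
descending through it costs pathlen 1 and the uninvolved sibling lineages
are not counted as losses, consistent with the unresolved-order reading
above. The case of losses *inside* a flattened clade below a duplication
that sits above it is not resolved an any finer granularity — the flattened
clade has no internal structure to count against.

**Rooting.** `root_by_dl()` scores every edge rooting (2n−3 for a binary
tree) by total duplications + losses and keeps the minimum, using topology
only. Ties are broken deterministically: the rooting whose smaller root-side
has the lexicographically smallest sorted gene list wins. Determinism here
matters more than the particular choice — reruns must agree bit for bit.

**Duplication confidence.** For a duplication node,
`DCS = |S(left) ∩ S(right)| / |S(left) ∪ S(right)|` over the species sets of
the child subtrees. A species-specific duplication has DCS 1 by definition;
DCS 0 occurs only when gene tree and species tree disagree. Duplications
with DCS < 0.25 (configurable) are flagged `dubious` for reporting and for
the homology rescue below; reconciliation totals still count them as
duplications.

## The merge (`mmerge`)

The merge recursively bipartitions the gene set, starting from the full
family, and thus always returns a binary tree. At each recursion over gene
set G the **candidates** are only the bipartitions found in the input trees:
each input is restricted to G, and the root split of the restriction is a
candidate (every child-versus-rest split, when the restricted root is
multifurcating — this keeps the candidate set faithful to the inputs without
resolving their multifurcations arbitrarily). Candidates are ranked by:

1. speciation before duplication (against the species tree);
2. fewer losses on the two branches the split creates (only those two
   edges, not whole subtrees);
3. larger bootstrap, taking the maximum over the supporting input nodes
   (absent bootstrap counts 0);
4. deterministic lexicographic tie-break, as in rooting.

The inputs whose restriction induces the chosen split are recorded as the
branch's **supporters**; support summaries per input model
(`branch_support_summary()`, `model_overlap()`) are computed from these.
Branch lengths of the merged tree are the median lengths of matching clades
in the inputs and are flagged approximate — the reference pipeline
recomputes them from the alignment, which is outside this package's scope.
Input trees are expected pre-rooted by `root_by_dl()`; the merge does not
re-root them.

## Orthology and paralogy

For every gene pair the mediating node is their LCA in the merged,
reconciled tree. Same species + duplication ⇒ within-species paralogues;
different species + speciation ⇒ orthologues. Pairs that meet only through
a *dubious* duplication (DCS below the threshold) are **rescued** as
orthologues when at least one of the two genes has no speciation-mediated
partner in the other species — the dubious node is then its only route to a
counterpart there. A stricter symmetric alternative (requiring *both*
genes to lack partners) was considered and rejected: it refuses the
canonical missing-copy case — a duplicated gene whose sister copy was lost
in the other lineage — which is precisely the situation the rescue exists
for.
Orthologues (including rescued ones) are classified one-to-one /
one-to-many / many-to-many from the number of co-orthologues each gene has
in the partner species.

**Synteny QC.** An orthologous ncRNA pair is *intronic-supported* when both
genes sit inside protein-coding hosts that are themselves protein
orthologues of the same class, and *window-supported* when a same-class
protein orthologue pair lies within 5 kb (gap between 1-based inclusive
intervals; 0 when overlapping; strand-agnostic) of both ncRNAs. A gap of
exactly 5000 bp counts; 5001 does not.

## K tree score

Two trees on the same leaf set are compared on their unrooted branches,
paired by leaf bipartition (terminal branches included; a branch missing
from one tree pairs with length 0). The comparison tree is scaled by
`K = Σ b_ref·b_comp / Σ b_comp²` — the least-squares minimiser — and the
score is `sqrt(Σ (K·b_comp − b_ref)²)`. Identical trees give K = 1, score
0; a uniformly c-scaled copy gives K = 1/c, score 0. The score is left
unnormalized: it is used to *rank* each family's candidate trees against
the merged tree, and ranking is invariant under any monotone normalization.

## Birth-death gene gain and loss

Family sizes evolve by an equal-rate linear birth-death process: each gene
is duplicated or lost at rate λ per gene per million years. With
`α = λt/(1+λt)`, the transition probability along a branch of length `t`
is

```
P(c | s, t) = Σ_{j=0}^{min(s,c)} C(s,j) · C(s+c−j−1, s−1) · α^{s+c−2j} · (1−2α)^j
```

with absorbing zero (`P(c|0) = [c = 0]`). The parameterization requires
α < 1/2, i.e. λt < 1; the λ search bound is set so α < 0.45 on the longest
branch. Family likelihoods use the standard pruning recursion with
ancestral counts truncated at `n_max`, default `max(10, 4 × max observed
count)` — at that truncation, doubling `n_max` changes log-likelihoods by
less than 1e−8 on the benchmark profiles. The root prior is uniform over
`1..n_max` by default and configurable.

`estimate_lambda()` keeps only families whose positive-count species have
the species-tree root as LCA (families that must have existed in the common
ancestor), then maximises the summed log-likelihood by bounded 1-D search.
A fit is accepted only when the maximum is interior to the bounds;
otherwise the family with the lowest log-likelihood at the boundary λ is
excluded as an outlier and the search repeated, up to 20% of the input —
the exclusion order is a package choice, since "outlier" is not defined
more precisely by the reference procedure. The final report scores *all*
root-present families at the estimate. Most-probable ancestral counts use
the max-product analogue of the pruning recursion with ties broken toward
the smaller count; branches are labelled expanded/contracted/unchanged by
comparing child and parent counts.

`make_ultrametric()` turns node ages (millions of years) into integer
branch lengths (`parent age − child age`, rounded, floored at 1), matching
the integer-time convention of the gain/loss model.

## Synthetic data: what it emulates and what it does not

The simulators generate exactly the study conditions the tests assume:

* `simulate_gene_tree()` evolves gene lineages forward in time inside the
  species tree (duplication rate 0.05, loss rate 0.02 per lineage per unit
  branch length by default, on an 8-taxon unit-branch species tree —
  families of roughly 5–30 genes with a handful of duplications, the size
  regime of typical ncRNA families). Surviving duplications are logged as
  ground truth.
* `perturb_tree()` stands in for the up-to-17 independently inferred
  candidate trees: random NNI moves (default 1) plus log-normal branch
  noise (default sd 0.1), with bootstraps of 95 away from and 40 near the
  rearranged edges.
* `simulate_profiles()` draws family-size profiles by exact sampling from
  the birth-death kernel (default λ = 0.002 per gene per My, the magnitude
  reported for vertebrate ncRNA families).
* `simulate_synteny_fixture()` plants a known fraction of supported ncRNA
  orthologue pairs (intronic and near-protein) for the synteny QC.

One master seed drives independent per-generator substreams, so every
fixture is bit-reproducible and adding a generator does not shift existing
ones. The simulators do **not** emulate sequence evolution, alignment
error, annotation bias between genomes, or assembly artefacts; green tests
therefore demonstrate algorithmic correctness and recovery under the
modelled noise, not robustness to the full messiness of genome annotation.

## Numerical and testing choices

* Newick output prints branch lengths with 9 decimals (trailing zeros
  trimmed); the write/parse round trip is exact to 1e−9.
* NJ guide trees are built with `ape::nj` (negative branch estimates
  clamped to 0) and midpoint-rooted with `phangorn::midpoint` before
  top-down cutting into ≤ 400-gene clusters; quicktree's rooting is not
  specified by the reference pipeline, and midpoint is deterministic and
  balanced.
* The exhaustive reconciliation validation enumerates **all** rooted binary
  topologies with up to 6 leaves (1 068 trees) against a brute-force oracle
  and adds fixed-seed random samples at 7 and 8 leaves plus
  enumeration-verified rootings; the full 8-leaf sweep (135 135 topologies)
  adds no new structure at several hundred times the cost, and the chosen
  scale keeps the whole validation under two minutes.
* Benchmark sizes elsewhere: 50 simulated families for end-to-end homology
  recovery; 20 replicates × 500 families for λ recovery; 100 random
  6-leaf pairs for the K-score oracle.

## Known limitations

* One global λ; per-branch rates are out of scope.
* Between-species paralogues are not annotated; only within-species
  paralogues and the orthologue classes.
* Merged-tree branch lengths are medians of the inputs, not re-estimated.
* K-score comparison assumes identical leaf sets (partial overlap is not
  needed by the ranking use case and is unimplemented).
* External aligners and tree builders are represented by the synthetic
  provider; adapters to real tools are intentionally out of scope.
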