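---
title: "Inferring and dating gene duplication, loss, and domain fusion/fission"
author: "fuserec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring and dating gene duplication, loss, and domain fusion/fission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuserec)
```

## The problem

Many receptor kinase families contain the same catalytic module in two
architectures: a composite receptor protein (an extracellular sensing
domain fused to an intracellular kinase) and a free-standing cytoplasmic
kinase. The plant S-domain receptor-like kinases (SRLKs) and their
kinase-only relatives (SRLCKs) are the motivating example: both forms are
ubiquitous across land plants, which immediately raises the questions
*when* the composite architecture was assembled by gene fusion, whether it
was ever disassembled again by fission, and how the family expanded and
contracted along each plant lineage.

`fuserec` answers these questions for any two-state family. Its inputs are
a rooted binary gene tree (built upstream with any phylogenetics tool), a
rooted binary species tree, and a table assigning each gene to a species
and to one of two architecture states, `FUSED` or `SPLIT`. Branch lengths
are carried through but never used by inference: all dating is categorical,
onto species-tree branches ("in the common ancestor of land plants"),
which is the resolution the data support.

## The model

### Duplication–loss reconciliation

`reconcile()` maps every gene-tree node `v` to the species-tree node
`M(v)`, the most recent common ancestor of the species of `v`'s descendant
genes. An internal node is a **duplication** when `M(v)` equals the mapping
of one of its children, otherwise a **speciation**. For a gene edge
`(v, c)` whose endpoints map `d` species edges apart, the edge implies `d`
losses when `v` is a duplication and `d − 1` when `v` is a speciation; each
loss is placed on the branch into the off-path daughter of a traversed
species node — the branch on which the lineage is absent. This placement is
the only one consistent with the per-branch bookkeeping identity below. The
LCA mapping provably minimizes duplications and losses simultaneously; the
test suite verifies the minimum against exhaustive enumeration of all valid
reconciliation maps on hundreds of small random instances.

A duplication mapped to species node `s` is dated to the species branch
entering `s`; when `s` is the species root it is dated to the **stem**, a
virtual pre-root branch. Speciation nodes are dated to their species node
itself.

### Ancestral architectures

Given the reconciliation, `infer_states()` reconstructs the `FUSED`/`SPLIT`
state of every ancestral node. Every event class carries a cost
(`fuserec_costs()`; all default to 1, the equal-cost convention that avoids
prior bias about relative event frequencies). A state flip on an edge costs
`fusion` (SPLIT→FUSED) or `fission` (FUSED→SPLIT) *in addition to* the base
duplication/speciation cost of the node, so an event-bearing node costs 2
at the defaults.

The selection criterion is global: the ancestral state map of minimum total
cost. We implement it by exact two-state weighted parsimony (Sankoff
dynamic programming) — an upward pass accumulating per-node, per-state
minimal subtree costs with the asymmetric transition costs, and a downward
pass selecting states. Descriptions of this reconstruction in the
literature are often procedural (two leaf-to-root sweeps with a look-ahead
to the deeper branch); because the stated criterion is simply "lowest total
cost", the dynamic program attains it exactly and no heuristic ambiguity
needs to be resolved. Exactness is enforced in the tests by comparing
against brute-force enumeration of all `2^I` internal state vectors under
random positive costs.

Because the base costs are fixed by the reconciliation, state optimization
only ever trades fusions against fissions; the full sum is still reported
so the per-node accounting stays visible in output.

### Tie-breaking

Weighted parsimony can be indifferent between mirror-image solutions (one
fusion versus one fission). Ties are resolved deterministically, and every
rule is overridable:

* **root**: prefer `SPLIT` (`root_pref = "SPLIT"`). Rationale: the split
  kinase-only proteins are the ancestral component; composite receptors
  are assembled from them, and the basal lineages of the motivating family
  are split. `root_pref = "FUSED"` gives the mirror-image behaviour.
* **non-root tie**: inherit the parent's selected state
  (`child_tie = "parent"`), which never manufactures an extra boundary.
* **residual ties** resolve to `SPLIT` (unreachable with two states and
  parent inheritance, but the rule is total).

With these rules identical inputs give byte-identical event lists.

### Event calling and dating

A fusion is called on every edge going SPLIT→FUSED, attached to the child
node — the earliest ancestor showing the new architecture — and dated to
the species branch entering `M(child)` (the stem when `M(child)` is the
species root), exactly like a duplication. Events are sorted by
species-tree preorder, then gene node id.

### The per-branch ledger

`branch_ledger()` tabulates, per species branch, the gains (duplications
dated to it), losses, fusions and fissions, each split by architecture
class, plus the lineage count at the branch's child node: the number of
gene lineages crossing that speciation (`ancestor_count()`), or the extant
gene count at a terminal species. Two identities hold and are re-verified
as an internal audit on every call (violation is an error, never a silent
return):

* `count(s) = count(parent(s)) + gains − losses` on every branch;
* class-wise, the FUSED count additionally changes by `+fusions −
  fissions` (SPLIT symmetrically).

A lineage crossing a speciation is counted in its child-end state when the
crossing edge's child maps exactly to that node, else in its parent-end
state — the counting convention forced by dating state flips to the branch
into `M(child)`. Consequently the two moss composite genes of the
motivating family are booked as SPLIT lineages on branches above their
fusion event and FUSED below it.

One boundary convention: when the gene-tree root maps below the species
root, the family is carried as a single stem lineage through the earlier
speciations, and the ledger places one implied loss on each off-path
branch. These implied losses appear only in the ledger (they are not part
of `reconciliation$loss_count`, which must equal the standard
duplication-loss minimum) and vanish for any family observed in all
species.

`expansion_ratio()` computes genome-size-normalized family expansions,
`(count_a / size_a) / (count_ref / size_ref)`. Genome sizes are always
user-supplied configuration: no constants are bundled, and the ratio is
invariant under common rescaling of both sizes.

## The simulator

`simulate_family()` generates families with complete ground truth so every
inference layer can be validated end-to-end without external data. Along
each species branch every lineage evolves independently by a
continuous-time Markov process (Gillespie exponential waiting times, so
simultaneous events have probability zero): duplication copies the lineage
in place, loss terminates it, fusion flips SPLIT→FUSED, fission the
reverse. At each speciation every surviving lineage is copied into both
daughters. Fully extinct subtrees are pruned from the returned gene tree
but all their events remain in the truth log — which is exactly what an
inference method could at best attribute to losses. With
`n_root_lineages = k`, the k independent root lineages are joined into one
binary root by stem nodes, logged as `k − 1` stem duplications, so that
truth and reconciliation count the same objects. Everything is a
deterministic function of `seed`.

The simulator emulates the event grammar the parsimony model assumes —
lineage-autonomous duplication, loss, and state flips along a dated species
tree. It deliberately does **not** emulate several features of real data:
sequence evolution and hence gene-tree estimation error (input trees are
taken as correct), incomplete lineage sorting, horizontal transfer, gene
conversion, rate heterogeneity across lineages, or correlated
(burst) duplication. Passing recovery tests therefore demonstrates
correctness of the inference given a correct tree, not robustness to
phylogenetic error.

### Default study conditions

The dated five-species tree (`srlk_species_tree()`) uses literature ages in
units of 100 My: land plants 4.5, vascular plants 4.2, angiosperm crown
1.4, eudicot split 1.0 (so terminal branches of 1.0–4.5 and short internal
branches of 0.3–2.8). The demo preset (`sim_params_paperlike()`) uses
duplication 0.35, loss 0.12, fusion 0.08, fission 0.005 per lineage per
unit, three split root lineages — values chosen once so a typical draw has
a large fused clade, a persisting split stratum and rare fissions; it is a
demonstration preset, not a calibrated estimate. The recovery tests use the
low-rate regime in which all four classes run at 0.005, keeping the
expected number of events of any kind below 0.1 on every branch
(4 × 0.005 × 4.5 = 0.09 on the longest).

## Worked example

```{r}
fam <- srlk_coarse_family()   # coarse desk-scale family: 39 genes
fit <- fuserec(fam$gene_tree, fam$species_tree, fam$annotations)
fit
fit$events
```

The coarse family encodes the qualitative structure reported for the
SRLK/SRLCK kinase-domain tree — 17 basal split lineages, one fused clade
and one split clade containing a fused moss cherry — and the fit recovers
two fusions and no fission: a major fusion on the land-plant stem and a
minor fusion on the terminal moss branch.

```{r}
head(as.data.frame(fit$ledger), 4)
```

## Numerical and design choices

* **Polytomies are rejected, never resolved implicitly.** The model is
  defined on bifurcations; `resolve_polytomies()` offers deterministic
  left-ladderization for users who accept that convention.
* **Unrooted input is rejected** (a three-child root fails validation):
  both the mapping and the direction of state changes require a root.
* **Degenerate families.** A family with one surviving gene is represented
  as a single leaf under a unary root; the root is not an event. A
  simulation in which everything dies returns a flagged empty result, not
  an error.
* **Problem sizes in the test suite** were chosen to keep exhaustive
  oracles exact and fast: random instances up to 13 leaves (12 internal
  nodes, `2^12` state vectors) for the architecture oracle and up to 8
  leaves over 4 species for the reconciliation-map oracle, 200 instances
  each; ledger and recovery properties run on 500 simulated families.

## Known limitations

* **Parsimony under-determination.** Maximum parsimony reports a minimum
  history, not the true one. Beyond the familiar under-counting, the
  inferred event *spectrum* can differ from the truth: if two independent
  fusions strike the two basal sister lineages of a single-copy family,
  the unique lowest-cost explanation of the leaves is one ancestral fusion
  plus one fission — parsimony then over-calls fissions even though every
  true event was a fusion. At event probabilities of ~0.05–0.1 per branch
  such draws are rare but expected within a few hundred families; the
  recovery tests exhibit exactly this case. Conclusions about *absence* of
  fission should therefore be read as "no fission is needed", not "no
  fission occurred".
* **Dating resolution is a species branch.** Losses caused by extinct
  duplicates collapse onto the surviving edge's path; a fusion whose
  descendants survive in only one species is dated to that terminal
  branch even if it happened earlier.
* **Binary architecture alphabet.** Sub-architectures of the extracellular
  region are collapsed into `FUSED`; S-domain-only proteins are outside
  the kinase tree and outside this model.
* **No statistical uncertainty.** Equal costs encode indifference, not
  estimates; there are no branch supports, no rate model, and no
  probabilistic reconstruction.
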