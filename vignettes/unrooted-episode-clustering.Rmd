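---
title: "Locating multiple gene duplication episodes from unrooted gene trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating multiple gene duplication episodes from unrooted gene trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uecr)
```

## The problem

Large genomic duplications leave their traces scattered across many gene
families: each family's tree shows one or more *gene duplication* nodes, and
whole-genome or segmental events should place duplications from many families
at the *same* position of the species phylogeny. Episode clustering asks for
the smallest number of species-tree locations ("episodes") that can receive
all duplications of a collection of gene family trees, after each duplication
has been relocated within the limits that a biologically consistent scenario
allows.

The classical formulation takes rooted, binary gene trees. Most tree
inference software, however, emits *unrooted* gene trees, and rooting them
incorrectly distorts the reconciliation. This package solves episode
clustering directly for unrooted inputs: each gene tree is rooted on an edge
of its own *D-plateau* (the set of rooting edges minimizing the duplication
cost — rooting anywhere else would inflate the number of duplications), and
the rootings are chosen jointly so that the episode count is minimal.

## Model

### Reconciliation and costs

For a rooted gene tree $T$ and species tree $S$ with
$\mathcal{L}(T)\subseteq\mathcal{L}(S)$, the lca-mapping $M$ sends every leaf
to its species and every internal node to the least common ancestor of its
children's images. An internal node $g$ is a **duplication** when
$M(g)=M(a)$ for one of its children $a$, otherwise a **speciation**. The
duplication cost $D(T,S)$ counts duplications; the loss cost is
$L(T,S)=2D(T,S)+\sum_g(\lVert M(a),M(b)\rVert-2)$ over internal nodes $g$
with children $a,b$, where $\lVert x,y\rVert$ is the edge length of the path
joining $x$ and $y$ in $S$; and $DL = D + L$.

### All rootings at once

For an unrooted gene tree $G$, the rooting $G_e$ places a root on edge $e$.
Cutting $G$ at $e$ yields two subtrees with lca-images $m_v, m_w$; relative
to the top node $\top$ (the lca in $S$ of all species in $G$ — every rooting
maps its root there), an edge is **empty** ($m_v\neq\top\neq m_w$: the root
of $G_e$ is a speciation), **double** ($m_v=\top=m_w$), or **single**. Every
tree has either exactly one empty edge or at least one double edge, never
both. The three edges around an internal node form one of five star types
S1–S5, the workhorse classification behind all structural results. D-minimal
and DL-minimal edges each form a connected subtree (the D- and DL-plateau),
with the DL-plateau contained in the D-plateau. All of these facts are
re-verified empirically by the test suite on simulated trees.

### Valid mappings and episodes

A mapping $F$ from gene-tree nodes to species nodes is **valid** when (1) it
is time consistent ($a\preceq b$ implies $F(a)\preceq F(b)$), (2) it fixes
speciations ($F(a)=M(a)$), (3) it only raises duplications
($F(a)\succeq M(a)$), and (4) it keeps every duplication strictly below the
image of every speciation above it ($F(a)\prec M(b)$), so the number of
duplications never changes. Conditions (3) and (4) confine each duplication
to a vertical species-tree path: from $M(d)$ up to the child of $M(b)$
toward $M(d)$, where $b$ is the nearest speciation ancestor of $d$ (the
species root when there is none; the nearest ancestor gives the tightest cap,
which the tests assert). The episode count of a collection is the minimum
number of distinct species nodes receiving all duplication images over valid
mappings — equivalently, the minimum number of points stabbing all the
vertical paths.

`ec_greedy()` solves this by the classic exchange argument: repeatedly place
an episode at the deepest interval top (ties broken by species post-order)
and discard the paths it stabs. Each duplication is then assigned the deepest
selected location inside its path, which provably satisfies all four
conditions; the solver still re-checks them explicitly and fails loudly if
violated. `ec_brute()` — exhaustive assignment enumeration filtered by the
four conditions verbatim — certifies the greedy count on 200 random
instances in the test suite.

## Choosing rootings

For a single tree, the empty-edge rooting (when one exists) is always among
the optima, and when a double edge exists all plateau rootings tie; both
facts are checked exhaustively per tree by `single_uec()`'s tests. For
collections, the solution is induced per tree by either (U1) any D-minimal
edge, for trees with a double edge, or (U2) an edge of one of the at most
two S2 stars flanking the empty edge: any deeper plateau rooting is
episode-equivalent to one adjacent to the empty edge. `uec_exact()`
therefore compares two branches: the all-empty-edge rooting (no top-node
episode; only feasible when every tree has an empty edge), and the Cartesian
product of the per-tree candidate sets (top-node episode present).

### A subtle refinement, and why it is not the default

A tempting further refinement keeps a *single* adjacent edge per S2 star —
the one whose far endpoint shares the lca-image of the star center under the
empty rooting. With $k$ trees having two such stars inside their D-plateau,
the enumeration shrinks to $1+2^k$, and the package exposes this as
`uec_exact(refine = "u2prime")` together with the parameter `count_k()`.
However, during certification against the full plateau-rooting brute force
(`uec_brute()`), we found instances where this refinement misses the
optimum: when the subtree behind the image-tied edge carries **no
duplications**, rooting there frees nothing, while rooting on the *other*
star edge hangs the duplication-rich sibling subtree directly under the root
duplication chain, uncapping its duplications all the way to $\top$. In one
simulated 5-leaf example (three copies of one species and one each of two
others), the tied-edge rooting caps a duplication cherry strictly below
$\top$ while the discarded edge lets it join the top episode, saving one
location in the collection; about 5% of our random collections were
affected.

The default `refine = "star"` therefore enumerates the full
plateau-restricted star candidate set — the empty edge plus up to four
adjacent S2-star edges, at most five per tree. This is exhaustive over the
episode-equivalence classes of plateau rootings, and `uec_exact()`'s count
matches `uec_brute()` on all 150 random collections in the acceptance suite.
The price is a larger worst-case product; `uec_heuristic()` (solve the
unambiguous subcollection exactly to obtain a lower bound $c_0$, then extend
greedily, certifying optimality whenever the full collection reaches $c_0$)
is the practical tool for large inputs.

## The simulator

`random_species_tree()` grows uniform random binary species trees by
sequential random edge attachment. `simulate_gene_tree()` runs a
duplication–loss history down the species tree: on every species branch each
surviving gene lineage duplicates with probability `dup_prob` and each copy
dies with probability `loss_prob`; surviving lineages become gene leaves.
Defaults are `dup_prob = 0.3`, `loss_prob = 0.2` — event rates high enough
that simulated families routinely contain multiple duplications, empty and
double edges, and non-trivial plateaus, while trees stay small. All
randomness flows from one seed per call and the caller's RNG state is left
untouched.

What the generator emulates: topology-only duplication–loss evolution, with
at most one duplication per lineage per branch. What it does not emulate:
sequence-level inference error, horizontal transfer, incomplete lineage
sorting, or rate heterogeneity. Passing tests therefore certify the
combinatorial machinery on clean duplication–loss histories, not robustness
to misinferred gene trees.

Problem sizes used by the test and acceptance suites, chosen to exercise the
theory while keeping the exhaustive oracles exact: 300 simulated trees on
5–10-leaf species trees for the structural suites; 200 collections of 1–4
rooted trees on 5–8-leaf species trees for the episode-clustering oracle
(instances trimmed deterministically until they are within the oracle's
10-duplication limit); 150 collections of 2–4 unrooted trees for the
rooting-product oracle (regenerated deterministically until the full plateau
product is at most 400 combinations).

## Numerical and degenerate-input choices

* Rooted binary gene-tree inputs are silently unrooted; a single top-level
  trifurcation is accepted as already unrooted; any other polytomy is
  rejected (the theory assumes binary trees).
* Branch lengths and internal labels are parsed and ignored — every cost
  here is topology-only.
* The top node used for edge classification is the lca of the tree's own
  species set, not necessarily the species root; for spanning trees the two
  coincide, and for non-spanning trees this keeps edge classes well defined.
  The validity conditions, by contrast, reference the full species tree, so
  a top-most duplication of a non-spanning tree may still be raised above
  its tree's top node.
* Ties everywhere (equal-depth interval tops, multiple double edges,
  equally good candidates) are broken by canonical orders — species
  post-order index, gene-tree Newick reading order — so every result is
  deterministic.
* Three-leaf gene trees (one internal node, no internal edge) are fully
  supported; the star classification is evaluated at the unique internal
  node.

## A worked example

```{r example}
S <- parse_species_newick("((a,b),c);")
genes <- list(
  parse_gene_newick("((a,b),(a,c));"),   # empty edge, one S2 star in plateau
  parse_gene_newick("((a,c),(b,c));"))   # one double edge
res <- uec_exact(genes, S)
res
res$bipartitions
```

The first tree alone would keep its duplication below the root; the solver
re-roots it so that the duplication joins the second tree's unavoidable
top-node episode, giving a single episode for the pair.

## Limitations

* Exact solving is exponential in the number of trees with several
  candidates; use the heuristic (with its certificate) for large inputs.
* The minimum-episodes variant (bounding episodes per species branch) and
  duplication–transfer–loss models are out of scope.
* `ec_brute()` and `uec_brute()` are oracles for small instances only and
  refuse inputs beyond their limits rather than degrade silently.
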