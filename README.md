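# uecr — episode clustering of gene duplications for unrooted gene trees

Whole-genome and segmental duplications show up in gene family trees as many
individual gene duplication nodes. Given a collection of gene family trees
and a rooted binary species tree, *episode clustering* finds the smallest
set of species-tree locations ("duplication episodes") that can receive all
those duplications, after each duplication is relocated within the limits a
biologically consistent scenario allows. `uecr` solves the problem for the
inputs phylogenetic inference actually produces — **unrooted** gene trees —
by jointly choosing a rooting for every tree from its D-plateau (the edges
minimizing the duplication cost) and a valid mapping of its duplications.

The package is aimed at researchers in comparative genomics and molecular
evolution who want to locate multiple gene duplication episodes without
committing to arbitrary gene-tree rootings.

## The model in brief

For a rooted gene tree `T` and species tree `S`, the lca-mapping `M` sends
each node to the least common ancestor of its leaves' species; a node `g`
with child `a` is a *duplication* iff `M(g) = M(a)`. Costs:
`D(T,S) = #duplications`,
`L(T,S) = 2 D + Σ_g (‖M(a), M(b)‖ − 2)`, `DL = D + L`.

A mapping `F` of gene nodes to species nodes is *valid* when it is time
consistent, fixes speciations at `M`, only raises duplications, and keeps
every duplication strictly below the images of the speciations above it.
These conditions confine each duplication to a vertical species-tree path;
the minimal episode count is the minimum number of species nodes stabbing
all paths, solved greedily (deepest path-top first) and certified against an
exhaustive oracle.

For an unrooted tree, every edge is classified (*empty*, *single*,
*double*) by whether the two subtree images at its ends reach the top
species node, the D- and DL-plateaus are computed, and the solver enumerates
candidate rootings per tree: any D-minimal edge for trees with a double
edge; the empty edge plus the plateau edges of the at most two S2 stars
flanking it otherwise (at most five candidates per tree). An exact solver
(`uec_exact`), a published tighter refinement with a `1 + 2^k` enumeration
bound (`refine = "u2prime"`; see the vignette for why it is not the
default), a certified heuristic (`uec_heuristic`), and exhaustive oracles
(`ec_brute`, `uec_brute`) are all exposed.

## Worked example

```r
library(uecr)

S <- parse_species_newick("((a,b),c);")
genes <- list(
  parse_gene_newick("((a,b),(a,c));"),   # empty edge; one S2 star in its D-plateau
  parse_gene_newick("((a,c),(b,c));"))   # one double edge

res <- uec_exact(genes, S)
res
#> UEC (exact-star): 1 episode location(s); k = 0; 3 combination(s) explored; optimal
res$bipartitions
#> [1] "a|a,b,c" "a,c|b,c"
```

One episode suffices: the second tree forces a duplication mapped to the
species root, and the solver re-roots the first tree (on the plateau edge
whose bipartition is `a|a,b,c`, not its empty edge) so that its duplication
can be raised to join that same top-node episode. `k = 0` says no tree was
ambiguous (two S2 stars inside its plateau); 3 rooting combinations were
scored. `cmd_uec(genes, S)` returns the same result as a report with
episode locations as species clades (`"a,b,c"`) and the episode count as a
percentage of species-tree nodes (here 20%).

A command-line front-end wraps the same functions:

```sh
Rscript inst/scripts/uec.R uec --species species.nwk --genes genes.nwk --format json
Rscript inst/scripts/uec.R plateau --species species.nwk --genes genes.nwk --kind DL
Rscript inst/scripts/uec.R simulate --n-species 8 --n-trees 20 --dir sim/ --seed 1
```

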