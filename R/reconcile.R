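# Rooted reconciliation of a gene tree against the species tree: lca-mapping,
# duplication/speciation labels, and the duplication (D), loss (L) and
# duplication-loss (DL) costs.

#' Least common ancestor mapping
#'
#' Maps every node of a rooted gene tree `T` into the species tree `S`:
#' a leaf maps to the species leaf carrying its label; an internal node with
#' children `a`, `b` maps to `lca_S(M(a), M(b))`. The mapping is monotone:
#' if `a` is below `b` in `T`, then `M(a)` is below-or-equal `M(b)` in `S`.
#'
#' @param T a `rooted_gene_tree` whose leaf species all occur in `S`.
#' @param S a `species_tree`.
#' @return an integer vector `M` of species-node ids indexed by gene-tree node.
#' @examples
#' S <- parse_species_newick("((a,b),c);")
#' T <- root_at_edge(parse_gene_newick("((a,b),a);"), 3)
#' @export
lca_map <- function(T, S) {
  M <- rep(NA_integer_, T$n_nodes)
  leaves <- which(T$leaf)
  labs <- T$label[leaves]
  hit <- S$leaf_index[labs]
  if (anyNA(hit))
    stop(sprintf("gene-tree leaf label(s) not found in the species tree: %s",
                 paste(sort(unique(labs[is.na(hit)])), collapse = ", ")),
         call. = FALSE)
  M[leaves] <- hit
  for (v in T$postorder) {
    if (T$leaf[v]) next
    cs <- T$children[[v]]
    M[v] <- node_lca(S, M[cs[1]], M[cs[2]])
  }
  M
}

#' Classify gene-tree nodes as duplications or speciations
#'
#' An internal node `g` is a duplication iff `M(g) == M(a)` for one of its
#' children `a`; every other internal node is a speciation.
#'
#' @param T a `rooted_gene_tree`.
#' @param S a `species_tree`.
#' @param M the [lca_map()] of `T` against `S` (computed if missing).
#' @return a character vector (`"duplication"`/`"speciation"`, `NA` at leaves).
#' @export
classify_events <- function(T, S, M = lca_map(T, S)) {
  ev <- rep(NA_character_, T$n_nodes)
  for (v in which(!T$leaf)) {
    cs <- T$children[[v]]
    ev[v] <- if (M[v] == M[cs[1]] || M[v] == M[cs[2]]) "duplication" else "speciation"
  }
  ev
}

#' Duplication cost D(T, S)
#'
#' The number of duplication nodes of `T` under the lca reconciliation.
#'
#' @inheritParams classify_events
#' @return a non-negative integer.
#' @export
dup_cost <- function(T, S, M = lca_map(T, S)) {
  sum(classify_events(T, S, M) == "duplication", na.rm = TRUE)
}

#' Loss cost L(T, S)
#'
#' `L = 2 D + sum over internal g with children a,b of (||M(a), M(b)|| - 2)`,
#' where `||x, y||` is the number of edges on the path connecting `x` and `y`
#' in the species tree.
#'
#' @inheritParams classify_events
#' @return a non-negative integer.
#' @export
loss_cost <- function(T, S, M = lca_map(T, S)) {
  d <- dup_cost(T, S, M)
  extra <- 0L
  for (v in which(!T$leaf)) {
    cs <- T$children[[v]]
    extra <- extra + node_path_len(S, M[cs[1]], M[cs[2]]) - 2L
  }
  2L * d + extra
}

#' Duplication-loss cost DL(T, S) = D + L
#'
#' @inheritParams classify_events
#' @return a non-negative integer.
#' @export
dl_cost <- function(T, S, M = lca_map(T, S)) {
  dup_cost(T, S, M) + loss_cost(T, S, M)
}
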