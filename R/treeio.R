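#' Gene-to-species label mapping rule
#'
#' Gene-tree leaves carry gene identifiers that must resolve to species names
#' present in the species tree. The `identity` rule uses the leaf label as the
#' species name; the `prefix` rule takes everything before the first occurrence
#' of `sep` (so `"HSA_gene21"` with `sep = "_"` maps to species `"HSA"`).
#'
#' @param mode `"identity"` or `"prefix"`.
#' @param sep separator character for the prefix rule.
#' @return an object of class `label_map_rule`.
#' @examples
#' rule <- label_map_rule("prefix", "_")
#' @export
label_map_rule <- function(mode = c("identity", "prefix"), sep = "_") {
  mode <- match.arg(mode)
  if (mode == "prefix" && (!is.character(sep) || nchar(sep) < 1L))
    stop("prefix rule needs a non-empty separator", call. = FALSE)
  structure(list(mode = mode, sep = sep), class = "label_map_rule")
}

apply_label_rule <- function(labels, rule) {
  if (is.null(rule) || rule$mode == "identity") return(labels)
  vapply(strsplit(labels, rule$sep, fixed = TRUE),
         function(x) x[[1]], character(1))
}

phylo_to_rooted <- function(phy, class) {
  n_tip <- length(phy$tip.label)
  n <- n_tip + phy$Nnode
  parent <- rep(NA_integer_, n)
  children <- vector("list", n)
  for (i in seq_len(n)) children[[i]] <- integer(0)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]; c <- phy$edge[i, 2]
    parent[c] <- p
    children[[p]] <- c(children[[p]], c)
  }
  label <- rep(NA_character_, n)
  label[seq_len(n_tip)] <- phy$tip.label
  new_rooted_topology(parent, children, label, class)
}

parse_newick_one <- function(text) {
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop("malformed Newick string", call. = FALSE)
  phy
}

#' Parse a rooted binary species tree from Newick
#'
#' Branch lengths and internal node labels, if present, are parsed and
#' discarded: all costs in this package are topology-only.
#'
#' @param text a single Newick string.
#' @return a `species_tree`: a rooted binary tree whose leaves are uniquely
#'   labeled species, with parent/children maps and per-node depths
#'   (root depth 0).
#' @examples
#' S <- parse_species_newick("((a,b),c);")
#' @export
parse_species_newick <- function(text) {
  phy <- parse_newick_one(text)
  if (length(phy$tip.label) < 2L)
    stop("species tree must be non-trivial (at least 2 leaves)", call. = FALSE)
  S <- phylo_to_rooted(phy, "species_tree")
  labs <- S$label[S$leaf]
  if (anyDuplicated(labs))
    stop(sprintf("duplicate species leaf label(s): %s",
                 paste(unique(labs[duplicated(labs)]), collapse = ", ")),
         call. = FALSE)
  S$leaf_index <- stats::setNames(which(S$leaf), labs)
  S
}

#' Parse an unrooted gene tree from Newick
#'
#' Accepts either a rooted binary tree (at least 3 leaves), which is silently
#' unrooted by suppressing its degree-2 root, or a tree whose top node is a
#' trifurcation, taken as-is. Leaf labels are rewritten through `rule`;
#' whether each resulting label names a species is checked later, when the
#' tree is paired with a species tree.
#'
#' @param text a single Newick string.
#' @param rule a [label_map_rule()]; default identity.
#' @return an `unrooted_gene_tree`: nodes of degree 1 (leaves, labeled by
#'   species names, repeats allowed) or 3; every edge is a potential rooting.
#' @examples
#' G <- parse_gene_newick("((a,b),(a,c));")
#' @export
parse_gene_newick <- function(text, rule = label_map_rule()) {
  phy <- parse_newick_one(text)
  T <- phylo_to_rooted_gene(phy)
  T$label <- ifelse(T$leaf, apply_label_rule(T$label, rule), T$label)
  unroot_gene_tree(T)
}

# like phylo_to_rooted but tolerates a trifurcating top node
phylo_to_rooted_gene <- function(phy) {
  n_tip <- length(phy$tip.label)
  n <- n_tip + phy$Nnode
  parent <- rep(NA_integer_, n)
  children <- vector("list", n)
  for (i in seq_len(n)) children[[i]] <- integer(0)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]; c <- phy$edge[i, 2]
    parent[c] <- p
    children[[p]] <- c(children[[p]], c)
  }
  root <- which(is.na(parent))
  for (v in seq_len(n)) {
    k <- length(children[[v]])
    if (k == 0L) next
    if (v == root && k == 3L) next
    if (k != 2L)
      stop("gene tree must be binary (a single top-level trifurcation is allowed)",
           call. = FALSE)
  }
  label <- rep(NA_character_, n)
  label[seq_len(n_tip)] <- phy$tip.label
  depth <- integer(n); ord <- root
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (c in children[[v]]) { depth[c] <- depth[v] + 1L; stack <- c(stack, c); ord <- c(ord, c) }
  }
  structure(list(n_nodes = n, root = root, parent = parent, children = children,
                 label = label, leaf = lengths(children) == 0L, depth = depth,
                 postorder = rev(ord)),
            class = "rooted_gene_tree")
}

#' Unroot a rooted gene tree
#'
#' Suppresses a degree-2 root, merging its two incident edges; a trifurcating
#' top node is kept as an ordinary internal node.
#'
#' @param T a `rooted_gene_tree`.
#' @return an `unrooted_gene_tree`.
#' @export
unroot_gene_tree <- function(T) {
  n <- T$n_nodes
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  for (v in seq_len(n)) for (c in T$children[[v]]) {
    adj[[v]] <- c(adj[[v]], c); adj[[c]] <- c(adj[[c]], v)
  }
  kids <- T$children[[T$root]]
  if (length(kids) == 2L) {
    a <- kids[1]; b <- kids[2]
    adj[[a]] <- c(setdiff(adj[[a]], T$root), b)
    adj[[b]] <- c(setdiff(adj[[b]], T$root), a)
    keep <- setdiff(seq_len(n), T$root)
    remap <- integer(n); remap[keep] <- seq_along(keep)
    adj <- lapply(adj[keep], function(x) remap[x])
    label <- T$label[keep]
  } else {
    label <- T$label
  }
  if (sum(lengths(adj) == 1L) < 3L)
    stop("gene tree must have at least 3 leaves to be unrooted", call. = FALSE)
  new_unrooted_gene_tree(adj, label)
}

#' Root an unrooted gene tree on an edge
#'
#' Places a new degree-2 root subdividing edge `e`; all other adjacencies are
#' oriented away from the root. The returned tree has one more node than `G`
#' (the new root, id `G$n_nodes + 1`); all other node ids are preserved.
#'
#' @param G an `unrooted_gene_tree`.
#' @param e an edge id (row of `G$edges`) or a length-2 vector of node ids.
#' @return a `rooted_gene_tree`.
#' @examples
#' G <- parse_gene_newick("((a,b),(a,c));")
#' T <- root_at_edge(G, 1)
#' @export
root_at_edge <- function(G, e) {
  if (length(e) == 2L) e <- ug_edge_id(G, e[1], e[2])
  if (!(length(e) == 1L && e >= 1L && e <= nrow(G$edges)))
    stop("e is not an edge of G", call. = FALSE)
  v <- G$edges[e, 1]; w <- G$edges[e, 2]
  n <- G$n_nodes; root <- n + 1L
  parent <- rep(NA_integer_, root)
  children <- vector("list", root)
  for (i in seq_len(root)) children[[i]] <- integer(0)
  children[[root]] <- c(v, w)
  parent[v] <- root; parent[w] <- root
  # orient away from the root; do not cross the subdivided edge
  stack <- c(v, w)
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (y in G$adj[[x]]) {
      if (!is.na(parent[y]) || y == root) next
      if ((x == v && y == w) || (x == w && y == v)) next
      parent[y] <- x
      children[[x]] <- c(children[[x]], y)
      stack <- c(stack, y)
    }
  }
  label <- c(G$label, NA_character_)
  new_rooted_topology(parent, children, label, "rooted_gene_tree")
}

quote_newick_label <- function(x) {
  needs <- grepl("[ \t(),:;'\\[\\]]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Write a tree as a Newick string
#'
#' @param tree a `species_tree`, `rooted_gene_tree` or `unrooted_gene_tree`
#'   (the latter is written with a trifurcation at an internal node).
#' @return a Newick string ending in `;`. Round-trips through the
#'   corresponding parser preserve topology and labels.
#' @export
write_newick <- function(tree) {
  if (inherits(tree, "unrooted_gene_tree")) {
    center <- which(!tree$leaf)[1]
    if (is.na(center)) stop("cannot write a tree without internal nodes", call. = FALSE)
    sub <- function(v, from) {
      ws <- setdiff(tree$adj[[v]], from)
      if (length(ws) == 0L) return(quote_newick_label(tree$label[v]))
      paste0("(", paste(vapply(ws, sub, character(1), from = v), collapse = ","), ")")
    }
    ws <- tree$adj[[center]]
    return(paste0("(", paste(vapply(ws, sub, character(1), from = center),
                             collapse = ","), ");"))
  }
  if (is.null(tree$root) || tree$n_nodes < 2L)
    stop("cannot write an empty or degenerate tree", call. = FALSE)
  sub <- function(v) {
    cs <- tree$children[[v]]
    if (length(cs) == 0L) return(quote_newick_label(tree$label[v]))
    paste0("(", paste(vapply(cs, sub, character(1)), collapse = ","), ")")
  }
  paste0(sub(tree$root), ";")
}

#' Read a collection of gene trees
#'
#' One Newick per line; blank lines and lines starting with `#` are skipped.
#'
#' @param path file path.
#' @param rule a [label_map_rule()].
#' @return a list of `unrooted_gene_tree` objects.
#' @export
read_gene_trees <- function(path, rule = label_map_rule()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, parse_gene_newick, rule = rule)
}

#' @export
print.species_tree <- function(x, ...) {
  cat(sprintf("Species tree: %d leaves, %d nodes\n  %s\n",
              sum(x$leaf), x$n_nodes, write_newick(x)))
  invisible(x)
}

#' @export
print.rooted_gene_tree <- function(x, ...) {
  cat(sprintf("Rooted gene tree: %d leaves, %d nodes\n  %s\n",
              sum(x$leaf), x$n_nodes, write_newick(x)))
  invisible(x)
}

#' @export
print.unrooted_gene_tree <- function(x, ...) {
  cat(sprintf("Unrooted gene tree: %d leaves, %d edges\n  %s\n",
              sum(x$leaf), nrow(x$edges), write_newick(x)))
  invisible(x)
}
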