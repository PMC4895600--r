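# Internal rooted/unrooted topology plumbing shared by all modules.
# Nodes are integer ids 1..n; rooted trees store parent/children maps,
# unrooted trees store adjacency lists plus a canonical edge table.

new_rooted_topology <- function(parent, children, label, class) {
  n <- length(parent)
  root <- which(is.na(parent))
  if (length(root) != 1L)
    stop("rooted tree must have exactly one root", call. = FALSE)
  is_leaf <- lengths(children) == 0L
  for (v in which(!is_leaf)) {
    k <- length(children[[v]])
    if (k != 2L)
      stop(sprintf(
        "internal node with %d children (clade: %s); trees must be binary",
        k, paste(label[descendant_leaves(children, v)], collapse = ",")),
        call. = FALSE)
  }
  depth <- integer(n)
  ord <- integer(0)
  stack <- root
  while (length(stack)) {                       # preorder; depths top-down
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ord <- c(ord, v)
    for (c in children[[v]]) {
      depth[c] <- depth[v] + 1L
      stack <- c(stack, c)
    }
  }
  structure(list(
    n_nodes = n, root = root, parent = parent, children = children,
    label = label, leaf = is_leaf, depth = depth,
    postorder = rev(ord)
  ), class = class)
}

descendant_leaves <- function(children, v) {
  out <- integer(0); stack <- v
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (length(children[[x]]) == 0L) out <- c(out, x)
    else stack <- c(stack, children[[x]])
  }
  sort(out)
}

tree_leaves <- function(tree) which(tree$leaf)

# ancestor-or-equal: is a on the root path of d (d "below or equal" a)?
node_is_anc <- function(tree, a, d) {
  while (tree$depth[d] > tree$depth[a]) d <- tree$parent[d]
  d == a
}

node_lca <- function(tree, a, b) {
  while (tree$depth[a] > tree$depth[b]) a <- tree$parent[a]
  while (tree$depth[b] > tree$depth[a]) b <- tree$parent[b]
  while (a != b) { a <- tree$parent[a]; b <- tree$parent[b] }
  a
}

node_lca_set <- function(tree, ids) Reduce(function(a, b) node_lca(tree, a, b), ids)

# edge count of the path between a and b
node_path_len <- function(tree, a, b) {
  l <- node_lca(tree, a, b)
  tree$depth[a] + tree$depth[b] - 2L * tree$depth[l]
}

# nodes on the vertical path bottom..top (bottom must be below-or-equal top)
node_vertical_path <- function(tree, bottom, top) {
  out <- bottom
  while (bottom != top) { bottom <- tree$parent[bottom]; out <- c(out, bottom) }
  out
}

new_unrooted_gene_tree <- function(adj, label) {
  n <- length(adj)
  deg <- lengths(adj)
  if (any(!deg %in% c(1L, 3L)))
    stop(sprintf("unrooted gene tree has a node of degree %d; nodes must have degree 1 or 3",
                 deg[which(!deg %in% c(1L, 3L))[1]]), call. = FALSE)
  m <- sum(deg) / 2L
  if (m != n - 1L) stop("unrooted gene tree is not a tree (edge count mismatch)", call. = FALSE)
  # connectivity
  seen <- logical(n); stack <- 1L; seen[1L] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
  }
  if (!all(seen)) stop("unrooted gene tree is not connected", call. = FALSE)
  pairs <- do.call(rbind, lapply(seq_len(n), function(v) {
    ws <- adj[[v]][adj[[v]] > v]
    if (length(ws)) cbind(v, ws) else NULL
  }))
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  colnames(pairs) <- c("v", "w")
  structure(list(
    n_nodes = n, adj = adj, label = label, leaf = deg == 1L,
    edges = pairs
  ), class = "unrooted_gene_tree")
}

# canonical edge id of {v,w}
ug_edge_id <- function(G, v, w) {
  a <- min(v, w); b <- max(v, w)
  id <- which(G$edges[, 1] == a & G$edges[, 2] == b)
  if (length(id) != 1L) stop(sprintf("<%d,%d> is not an edge of the gene tree", v, w), call. = FALSE)
  id
}

# human-readable edge name: sorted leaf-label bipartition "x,y|z,w"
ug_edge_bipartition <- function(G, e) {
  v <- G$edges[e, 1]; w <- G$edges[e, 2]
  side <- ug_component(G, v, w)     # leaves on w's side
  lw <- sort(G$label[intersect(which(G$leaf), side)])
  lv <- sort(G$label[setdiff(which(G$leaf), side)])
  sides <- sort(c(paste(lv, collapse = ","), paste(lw, collapse = ",")))
  paste(sides, collapse = "|")
}

# nodes of the component containing w when edge {v,w} is removed
ug_component <- function(G, v, w) {
  seen <- logical(G$n_nodes); seen[w] <- TRUE; stack <- w
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (y in G$adj[[x]])
      if (!seen[y] && !(x == w && y == v)) { seen[y] <- TRUE; stack <- c(stack, y) }
  }
  which(seen)
}

# run expr with a private RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
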