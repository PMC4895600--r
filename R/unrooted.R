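# All-rootings analysis of an unrooted gene tree G against a species tree S.
# Rooting G on edge e gives the rooted tree G_e; its duplication (D) and
# duplication-loss (DL) costs vary with e, and the D-minimal (resp.
# DL-minimal) edges form a connected subtree of G, the D-plateau (DL-plateau).
# Edge classes (empty/single/double) and star types (S1..S5) drive both the
# plateau structure and the candidate rootings used by the episode solvers.

#' Top species node of a gene tree
#'
#' The species node every rooting of `G` maps its root to: the lca in `S` of
#' all species appearing in `G`. For gene trees spanning all species this is
#' the species-tree root.
#'
#' @param G an `unrooted_gene_tree`.
#' @param S a `species_tree`.
#' @return a species-node id.
#' @export
gene_tree_top <- function(G, S) {
  labs <- unique(G$label[G$leaf])
  hit <- S$leaf_index[labs]
  if (anyNA(hit))
    stop(sprintf("gene-tree leaf label(s) not found in the species tree: %s",
                 paste(sort(labs[is.na(hit)]), collapse = ", ")), call. = FALSE)
  node_lca_set(S, unname(hit))
}

#' Subtree lca-images for every directed edge
#'
#' For each ordered pair of adjacent nodes `(v, w)`, computes the lca-mapping
#' image of the subtree on the `w`-side when `G` is cut at the edge `{v, w}`.
#' These `2 |E|` images determine the lca-mapping of every rooting of `G` and
#' are computed in two sweeps (inward, then outward) over the tree.
#'
#' @inheritParams gene_tree_top
#' @return a list with `dmap` (an `n x n` integer matrix, `dmap[v, w]` = image
#'   of the component containing `w` after removing `{v, w}`; `NA` off the
#'   adjacency) and `top` (the [gene_tree_top()] node).
#' @export
directed_edge_maps <- function(G, S) {
  top <- gene_tree_top(G, S)
  n <- G$n_nodes
  leaf_img <- rep(NA_integer_, n)
  leaf_img[G$leaf] <- S$leaf_index[G$label[G$leaf]]
  dmap <- matrix(NA_integer_, n, n)
  r <- which(!G$leaf)[1]
  # orientation away from r
  parent <- rep(NA_integer_, n); parent[r] <- 0L
  ord <- integer(0); stack <- r
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    ord <- c(ord, v)
    for (w in G$adj[[v]]) if (is.na(parent[w])) { parent[w] <- v; stack <- c(stack, w) }
  }
  # inward sweep: dmap[parent, u] = image of u's subtree
  for (u in rev(ord)) {
    if (u == r) next
    p <- parent[u]
    dmap[p, u] <- if (G$leaf[u]) leaf_img[u] else {
      cs <- setdiff(G$adj[[u]], p)
      node_lca(S, dmap[u, cs[1]], dmap[u, cs[2]])
    }
  }
  # outward sweep (preorder, so dmap[p, parent[p]] is already filled)
  for (u in ord) {
    if (u == r) next
    p <- parent[u]
    others <- setdiff(G$adj[[p]], u)
    imgs <- dmap[p, others]
    dmap[u, p] <- if (length(imgs) == 1L) imgs else node_lca_set(S, imgs)
  }
  list(dmap = dmap, top = top)
}

#' Classify the edges of an unrooted gene tree
#'
#' An edge `{v, w}` is *empty* if both side-images differ from the top node
#' (the root of the rooting on it is a speciation), *double* if both equal the
#' top, and *single* otherwise. For a single edge the *incoming* endpoint is
#' the one whose side does not reach the top.
#'
#' @inheritParams gene_tree_top
#' @param maps precomputed [directed_edge_maps()].
#' @return a data frame with one row per edge: `edge`, `v`, `w`, `mv`, `mw`
#'   (side images), `class`, `incoming`.
#' @export
classify_edges <- function(G, S, maps = directed_edge_maps(G, S)) {
  top <- maps$top; dmap <- maps$dmap
  m <- nrow(G$edges)
  out <- data.frame(edge = seq_len(m), v = G$edges[, 1], w = G$edges[, 2],
                    mv = NA_integer_, mw = NA_integer_,
                    class = NA_character_, incoming = NA_integer_)
  for (e in seq_len(m)) {
    v <- out$v[e]; w <- out$w[e]
    mv <- dmap[w, v]; mw <- dmap[v, w]     # image of v-side, w-side
    out$mv[e] <- mv; out$mw[e] <- mw
    out$class[e] <- if (mv != top && mw != top) "empty"
      else if (mv == top && mw == top) "double" else "single"
    if (out$class[e] == "single") out$incoming[e] <- if (mv != top) v else w
  }
  out
}

#' Classify the stars of an unrooted gene tree
#'
#' The star at an internal node `v` consists of its three incident edges.
#' Relative to `v` each edge is empty, double, `v`-outgoing (the `v`-side
#' image equals the top node) or `v`-incoming. The five feasible types are
#' S1 (1 incoming + 2 outgoing), S2 (2 outgoing + 1 empty),
#' S3 (2 outgoing + 1 double), S4 (3 double), S5 (1 outgoing + 2 double);
#' any other combination cannot occur and raises an error.
#'
#' @inheritParams classify_edges
#' @param edges precomputed [classify_edges()] table.
#' @return a data frame with one row per internal node: `node`, `type`.
#' @export
classify_stars <- function(G, S, edges = classify_edges(G, S)) {
  internal <- which(!G$leaf)
  type <- character(length(internal))
  for (i in seq_along(internal)) {
    v <- internal[i]
    rows <- edges[edges$v == v | edges$w == v, ]
    role <- character(3)
    for (j in seq_len(3)) {
      cls <- rows$class[j]
      role[j] <- if (cls %in% c("empty", "double")) cls
        else if (rows$incoming[j] == v) "incoming" else "outgoing"
    }
    cnt <- table(factor(role, levels = c("incoming", "outgoing", "empty", "double")))
    type[i] <-
      if (cnt[["incoming"]] == 1 && cnt[["outgoing"]] == 2) "S1"
      else if (cnt[["outgoing"]] == 2 && cnt[["empty"]] == 1) "S2"
      else if (cnt[["outgoing"]] == 2 && cnt[["double"]] == 1) "S3"
      else if (cnt[["double"]] == 3) "S4"
      else if (cnt[["outgoing"]] == 1 && cnt[["double"]] == 2) "S5"
      else stop(sprintf(
        "impossible star at node %d (%s): edge classification is inconsistent",
        v, paste(role, collapse = "+")), call. = FALSE)
  }
  data.frame(node = internal, type = type)
}

#' Rooting cost of every edge
#'
#' For each edge `e` of `G`, the duplication (or duplication-loss) cost of the
#' rooting `G_e` against `S`, computed from the directed-edge images without
#' constructing the rootings. Equals `dup_cost(root_at_edge(G, e), S)`
#' (resp. [dl_cost()]) for every edge.
#'
#' @inheritParams classify_edges
#' @param kind `"D"` (duplication) or `"DL"` (duplication-loss).
#' @return an integer vector of costs indexed by edge id.
#' @export
rooting_cost_profile <- function(G, S, kind = c("D", "DL"),
                                 maps = directed_edge_maps(G, S)) {
  kind <- match.arg(kind)
  dmap <- maps$dmap
  m <- nrow(G$edges)
  costs <- integer(m)
  internal <- which(!G$leaf)
  for (e in seq_len(m)) {
    v <- G$edges[e, 1]; w <- G$edges[e, 2]
    # next hop toward the rooting edge, for every node
    toward <- rep(NA_integer_, G$n_nodes)
    toward[v] <- w; toward[w] <- v
    stack <- c(v, w)
    while (length(stack)) {
      x <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (y in G$adj[[x]]) {
        if (!is.na(toward[y])) next
        if ((x == v && y == w) || (x == w && y == v)) next
        toward[y] <- x; stack <- c(stack, y)
      }
    }
    D <- 0L; extra <- 0L
    for (u in internal) {
      p <- toward[u]
      mu <- dmap[p, u]
      cs <- setdiff(G$adj[[u]], p)
      m1 <- dmap[u, cs[1]]; m2 <- dmap[u, cs[2]]
      if (mu == m1 || mu == m2) D <- D + 1L
      if (kind == "DL") extra <- extra + node_path_len(S, m1, m2) - 2L
    }
    m1 <- dmap[w, v]; m2 <- dmap[v, w]          # root's two child images
    mr <- node_lca(S, m1, m2)
    if (mr == m1 || mr == m2) D <- D + 1L
    if (kind == "DL") extra <- extra + node_path_len(S, m1, m2) - 2L
    costs[e] <- if (kind == "D") D else 3L * D + extra    # DL = D + (2D + extra)
  }
  costs
}

#' Minimal-cost rooting edges (the plateau)
#'
#' The set of edges whose rootings achieve the minimal duplication
#' (`kind = "D"`) or duplication-loss (`kind = "DL"`) cost. The set always
#' induces a connected subtree of `G`, and the DL-plateau is a subgraph of the
#' D-plateau; both facts are verified and an internal error is raised if they
#' fail.
#'
#' @inheritParams rooting_cost_profile
#' @return an object of class `plateau`: a list with `kind`, `cost` (the
#'   minimum), `edges` (edge ids) and `profile` (the full cost vector).
#' @export
plateau <- function(G, S, kind = c("D", "DL"), maps = directed_edge_maps(G, S)) {
  kind <- match.arg(kind)
  prof <- rooting_cost_profile(G, S, kind, maps)
  edges <- which(prof == min(prof))
  if (!plateau_edges_connected(G, edges))
    stop("plateau edges do not induce a connected subtree (internal error)", call. = FALSE)
  if (kind == "DL") {
    dprof <- rooting_cost_profile(G, S, "D", maps)
    if (!all(edges %in% which(dprof == min(dprof))))
      stop("DL-plateau is not a subgraph of the D-plateau (internal error)", call. = FALSE)
  }
  structure(list(kind = kind, cost = min(prof), edges = edges, profile = prof),
            class = "plateau")
}

plateau_edges_connected <- function(G, edges) {
  if (length(edges) <= 1L) return(TRUE)
  nodes <- unique(as.vector(G$edges[edges, , drop = FALSE]))
  adj <- lapply(seq_len(G$n_nodes), function(i) integer(0))
  for (e in edges) {
    v <- G$edges[e, 1]; w <- G$edges[e, 2]
    adj[[v]] <- c(adj[[v]], w); adj[[w]] <- c(adj[[w]], v)
  }
  seen <- logical(G$n_nodes); seen[nodes[1]] <- TRUE; stack <- nodes[1]
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (y in adj[[x]]) if (!seen[y]) { seen[y] <- TRUE; stack <- c(stack, y) }
  }
  all(seen[nodes])
}

#' @export
print.plateau <- function(x, ...) {
  cat(sprintf("%s-plateau: cost %d, %d edge(s): %s\n",
              x$kind, x$cost, length(x$edges), paste(x$edges, collapse = ", ")))
  invisible(x)
}

#' Find an empty or double edge
#'
#' Every unrooted gene tree has either exactly one empty edge or at least one
#' double edge, never both. Returns the empty edge when it exists, otherwise
#' the first double edge in canonical edge order. The returned edge is always
#' D-minimal.
#'
#' @inheritParams classify_edges
#' @return an edge id.
#' @export
find_opt_edge <- function(G, S, maps = directed_edge_maps(G, S)) {
  cls <- classify_edges(G, S, maps)
  empty <- cls$edge[cls$class == "empty"]
  if (length(empty) > 1L)
    stop("more than one empty edge (internal error)", call. = FALSE)
  if (length(empty) == 1L) return(empty)
  dbl <- cls$edge[cls$class == "double"]
  if (length(dbl) == 0L)
    stop("no empty and no double edge (internal error)", call. = FALSE)
  dbl[1]
}
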