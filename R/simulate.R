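# Fixture generation: random species trees, duplication-loss gene trees
# simulated along them, and small hand-built gene trees exercising every
# edge-class/star/plateau situation the solvers distinguish.

#' Simulation configuration
#'
#' @param dup_prob per-branch probability that a surviving gene lineage
#'   duplicates (default 0.3).
#' @param loss_prob per-branch probability that a gene lineage is lost
#'   (default 0.2).
#' @param min_leaves minimum surviving gene-tree leaves (default 3, the
#'   smallest unrootable tree).
#' @param max_retries attempts before giving up (default 1000).
#' @return a `sim_config` list.
#' @export
sim_config <- function(dup_prob = 0.3, loss_prob = 0.2, min_leaves = 3L,
                       max_retries = 1000L) {
  stopifnot(dup_prob >= 0, dup_prob <= 1, loss_prob >= 0, loss_prob <= 1,
            min_leaves >= 3L)
  structure(list(dup_prob = dup_prob, loss_prob = loss_prob,
                 min_leaves = as.integer(min_leaves),
                 max_retries = as.integer(max_retries)),
            class = "sim_config")
}

#' Random rooted binary species tree
#'
#' Grows a tree over leaves `s1..sn` by sequential random edge attachment:
#' each new leaf subdivides a uniformly chosen edge (including a virtual edge
#' above the root). Deterministic per seed; the caller's RNG state is left
#' untouched.
#'
#' @param n leaf count (at least 3).
#' @param seed integer seed.
#' @return a `species_tree` with `2n - 1` nodes.
#' @export
random_species_tree <- function(n, seed) {
  stopifnot(n >= 3)
  with_seed(seed, {
    # edges named by their child node; attaching to child c subdivides the
    # edge (parent(c), c); 0 denotes the virtual edge above the current root
    parent <- rep(NA_integer_, 2L * n - 1L)
    children <- vector("list", 2L * n - 1L)
    for (i in seq_len(2L * n - 1L)) children[[i]] <- integer(0)
    root <- 1L                      # start from the single leaf s1
    next_int <- n + 1L
    for (i in 2:n) {
      opts <- c(0L, which(!is.na(parent)))
      pick <- opts[sample.int(length(opts), 1L)]
      newl <- i                     # leaf id
      newi <- next_int; next_int <- next_int + 1L
      if (pick == 0L) {             # new root above the old root
        children[[newi]] <- c(root, newl)
        parent[root] <- newi; parent[newl] <- newi
        root <- newi
      } else {                      # subdivide edge (parent(pick), pick)
        p <- parent[pick]
        children[[p]][children[[p]] == pick] <- newi
        children[[newi]] <- c(pick, newl)
        parent[newi] <- p; parent[pick] <- newi; parent[newl] <- newi
      }
    }
    label <- rep(NA_character_, 2L * n - 1L)
    label[seq_len(n)] <- paste0("s", seq_len(n))
    S <- new_rooted_topology(parent, children, label, "species_tree")
    S$leaf_index <- stats::setNames(which(S$leaf), S$label[S$leaf])
    S
  })
}

#' Simulate a duplication-loss gene tree along a species tree
#'
#' Walks `S` from the root. On each species branch every incoming gene
#' lineage duplicates with probability `dup_prob` (both copies continue down
#' the branch) and each copy is then lost with probability `loss_prob`.
#' Lineages surviving to a species leaf become gene leaves labeled by that
#' species. Lost subtrees are pruned and unary nodes suppressed; the run is
#' retried until at least `min_leaves` leaves survive.
#'
#' @param S a `species_tree`.
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return a list with `rooted` (the true `rooted_gene_tree`), `unrooted`
#'   (its unrooted version), `n_dup_events` (duplications drawn on surviving
#'   history paths), `n_loss_events`.
#' @export
simulate_gene_tree <- function(S, cfg = sim_config(), seed = 1L) {
  with_seed(seed, {
    for (try in seq_len(cfg$max_retries)) {
      res <- sim_once(S, cfg)
      if (!is.null(res) && sum(res$rooted$leaf) >= cfg$min_leaves) return(res)
    }
    stop("simulation failed to reach the minimum leaf count; lower loss_prob",
         call. = FALSE)
  })
}

# one DL history; returns NULL when everything dies
sim_once <- function(S, cfg) {
  # event-tree nodes grown in a flat list: type spec/dup/leaf, children ids
  type <- character(0); kids <- list(); lab <- character(0)
  new_node <- function(t, l = NA_character_) {
    type[[length(type) + 1L]] <<- t
    kids[[length(kids) + 1L]] <<- integer(0)
    lab[[length(lab) + 1L]] <<- l
    length(type)
  }
  n_dup <- 0L; n_loss <- 0L
  # descend: lineage entering species node sp; returns event-tree node id or NA
  descend <- function(sp) {
    if (S$leaf[sp]) return(new_node("leaf", S$label[sp]))
    cs <- S$children[[sp]]
    a <- branch(cs[1]); b <- branch(cs[2])
    if (is.na(a) && is.na(b)) return(NA_integer_)
    if (is.na(a)) return(b)
    if (is.na(b)) return(a)
    v <- new_node("spec"); kids[[v]] <<- c(a, b)
    v
  }
  # lineage traversing the branch above species node sp
  branch <- function(sp) {
    if (stats::runif(1) < cfg$dup_prob) {
      n_dup <<- n_dup + 1L
      a <- if (stats::runif(1) < cfg$loss_prob) { n_loss <<- n_loss + 1L; NA_integer_ } else descend(sp)
      b <- if (stats::runif(1) < cfg$loss_prob) { n_loss <<- n_loss + 1L; NA_integer_ } else descend(sp)
      if (is.na(a) && is.na(b)) return(NA_integer_)
      if (is.na(a)) return(b)
      if (is.na(b)) return(a)
      v <- new_node("dup"); kids[[v]] <<- c(a, b)
      return(v)
    }
    if (stats::runif(1) < cfg$loss_prob) { n_loss <<- n_loss + 1L; return(NA_integer_) }
    descend(sp)
  }
  top <- branch(S$root)   # the root lineage may itself duplicate or die
  if (is.na(top)) return(NULL)
  if (length(kids[[top]]) == 0L) return(NULL)     # single surviving leaf
  # build rooted gene tree from the event tree (already pruned/suppressed)
  n <- length(type)
  parent <- rep(NA_integer_, n)
  for (v in seq_len(n)) for (c in kids[[v]]) parent[c] <- v
  keep <- rep(FALSE, n); stack <- top; keep[top] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (c in kids[[v]]) { keep[c] <- TRUE; stack <- c(stack, c) }
  }
  ids <- which(keep)
  remap <- integer(n); remap[ids] <- seq_along(ids)
  parent2 <- rep(NA_integer_, length(ids))
  children2 <- vector("list", length(ids))
  for (i in seq_along(ids)) children2[[i]] <- remap[kids[[ids[i]]]]
  for (i in seq_along(ids)) {
    p <- parent[ids[i]]
    parent2[i] <- if (is.na(p) || !keep[p]) NA_integer_ else remap[p]
  }
  parent2[remap[top]] <- NA_integer_
  T <- new_rooted_topology(parent2, children2, lab[ids], "rooted_gene_tree")
  if (sum(T$leaf) < 3L) return(list(rooted = T, unrooted = NULL,
                                    n_dup_events = n_dup, n_loss_events = n_loss))
  list(rooted = T, unrooted = unroot_gene_tree(T),
       n_dup_events = n_dup, n_loss_events = n_loss)
}

#' Curated gene-tree / species-tree fixtures
#'
#' Small hand-built inputs covering the solver-relevant situations:
#' \describe{
#'   \item{empty_star}{3-leaf star over `a,b,c`; its single empty edge is the
#'     whole D-plateau.}
#'   \item{double_edge}{unrooted `((a,c),(b,c))`; one double (internal) edge,
#'     D-plateau of size 1.}
#'   \item{one_s2}{unrooted `((a,b),(a,c))`; empty edge with one S2 star in
#'     the plateau, a single refined candidate.}
#'   \item{two_s2}{unrooted `((a,a),(c,c))`; empty edge flanked by two S2
#'     stars, both inside the D-plateau: two refined candidates (ambiguous,
#'     contributes to k).}
#' }
#' All use the species tree `((a,b),c)`. Expected annotations (edge classes,
#' plateau, candidate counts, single-tree episode counts) are attached for
#' use as test oracles.
#'
#' @return a named list of fixtures, each with `G`, `S` and `expect`.
#' @export
fixture_suite <- function() {
  S <- parse_species_newick("((a,b),c);")
  fx <- list()
  fx$empty_star <- list(
    G = parse_gene_newick("((a,b),c);"), S = S,
    expect = list(n_edges = 3L, empty = "a,b|c", plateau_cost = 0L,
                  plateau_size = 1L, n_branch_b = 0L, ambiguous = FALSE,
                  single_uec = 0L))
  fx$double_edge <- list(
    G = parse_gene_newick("((a,c),(b,c));"), S = S,
    expect = list(n_edges = 5L, empty = NULL, plateau_cost = 1L,
                  plateau_size = 1L, n_branch_b = 1L, ambiguous = FALSE,
                  single_uec = 1L))
  fx$one_s2 <- list(
    G = parse_gene_newick("((a,b),(a,c));"), S = S,
    expect = list(n_edges = 5L, empty = "a,a,b|c", plateau_cost = 1L,
                  plateau_size = 3L, n_branch_b = 1L, ambiguous = FALSE,
                  single_uec = 1L))
  fx$two_s2 <- list(
    G = parse_gene_newick("((a,a),(c,c));"), S = S,
    expect = list(n_edges = 5L, empty = "a,a|c,c", plateau_cost = 2L,
                  plateau_size = 5L, n_branch_b = 2L, ambiguous = TRUE,
                  single_uec = 2L))
  fx
}
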