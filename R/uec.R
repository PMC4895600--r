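# Unrooted episode clustering (UEC): choose a D-plateau rooting for every
# unrooted gene tree so that the rooted episode clustering of the chosen
# rootings is minimal.
#
# Candidate rootings per tree:
#  - double-edge case: every plateau rooting ties, one canonical D-minimal
#    candidate is kept;
#  - empty-edge case: any deeper plateau rooting is episode-equivalent to a
#    rooting adjacent to the empty edge, so the candidates are the empty edge
#    itself plus the plateau edges of the (at most two) S2 stars flanking it
#    (at most 5 in total).
# A further refinement ("u2prime") keeps a single adjacent edge per S2 star,
# the one whose far endpoint shares the lca-image of the star center under
# the empty rooting; it yields the 1 + 2^k enumeration bound (k = number of
# trees with two S2 stars inside the D-plateau) but can miss the optimum when
# the tied-side subtree carries no duplications, so the full star set is the
# default. See the methods vignette for the analysis.

#' Candidate rooting edges of one gene tree
#'
#' @param G an `unrooted_gene_tree`.
#' @param S a `species_tree`.
#' @return a `candidate_set`: a list with
#'   `case` (`"double-edge"` or `"empty-edge"`),
#'   `empty_edge` (edge id or `NA`),
#'   `star_candidates` (D-plateau edges adjacent to the empty edge at S2-star
#'   centers; at most 4),
#'   `enum_candidates` (the set enumerated by [uec_exact()] under the default
#'   refinement: the empty edge plus `star_candidates`, or the single
#'   canonical double-edge candidate),
#'   `branch_b` (the single-edge-per-star refinement: at most 2, non-adjacent,
#'   each D-minimal, adjacent to the empty edge with tied lca-image under the
#'   empty rooting),
#'   `theorem5` (the empty edge plus all edges of the flanking S2 stars, or
#'   the canonical double-edge candidate; never more than 5),
#'   `ambiguous` (`TRUE` iff `branch_b` has two edges, i.e. two S2 stars lie
#'   inside the D-plateau; such trees are counted by the parameter `k`),
#'   `plateau` (the D-plateau object).
#' @export
candidate_rootings <- function(G, S) {
  maps <- directed_edge_maps(G, S)
  cls <- classify_edges(G, S, maps)
  pl <- plateau(G, S, "D", maps)
  empty <- cls$edge[cls$class == "empty"]
  if (length(empty) == 0L) {
    e <- find_opt_edge(G, S, maps)
    return(structure(list(case = "double-edge", empty_edge = NA_integer_,
                          star_candidates = integer(0), enum_candidates = e,
                          branch_b = e, theorem5 = e,
                          ambiguous = FALSE, plateau = pl),
                     class = "candidate_set"))
  }
  e_star <- empty[1]
  v <- G$edges[e_star, 1]; w <- G$edges[e_star, 2]
  G_star <- root_at_edge(G, e_star)
  M_star <- lca_map(G_star, S)
  th5 <- e_star
  star_cand <- integer(0)
  u2prime <- integer(0)
  for (u in c(v, w)) {
    if (G$leaf[u]) next                       # S2 stars sit at internal endpoints
    others <- setdiff(G$adj[[u]], c(v, w))
    eids <- vapply(others, function(x) ug_edge_id(G, u, x), integer(1))
    th5 <- c(th5, eids)
    in_pl <- eids[eids %in% pl$edges]
    star_cand <- c(star_cand, in_pl)
    tied <- eids[vapply(others, function(x) M_star[x] == M_star[u], logical(1))]
    tied <- intersect(tied, in_pl)
    if (length(tied)) u2prime <- c(u2prime, sort(tied)[1])  # one per S2 star
  }
  structure(list(case = "empty-edge", empty_edge = e_star,
                 star_candidates = sort(star_cand),
                 enum_candidates = sort(unique(c(e_star, star_cand))),
                 branch_b = sort(u2prime), theorem5 = sort(unique(th5)),
                 ambiguous = length(u2prime) == 2L, plateau = pl),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("Candidate rootings (%s case): enumerated = {%s}; per-star refined = {%s}%s\n",
              x$case, paste(x$enum_candidates, collapse = ", "),
              paste(x$branch_b, collapse = ", "),
              if (x$ambiguous) " [ambiguous]" else ""))
  invisible(x)
}

#' Number of ambiguous gene trees (the parameter k)
#'
#' Counts the input gene trees with two S2 stars whose candidate edges lie in
#' the D-plateau (two single-edge-per-star refined candidates); the
#' `"u2prime"` exact solver explores at most `1 + 2^k` rooting combinations.
#'
#' @param collection a list of `unrooted_gene_tree` objects.
#' @param S a `species_tree`.
#' @param candidates optional precomputed list of [candidate_rootings()].
#' @return a non-negative integer.
#' @export
count_k <- function(collection, S,
                    candidates = lapply(collection, candidate_rootings, S = S)) {
  sum(vapply(candidates, `[[`, logical(1), "ambiguous"))
}

root_combination <- function(collection, edges) {
  lapply(seq_along(collection), function(i) root_at_edge(collection[[i]], edges[i]))
}

uec_result <- function(edges, solution, method, optimal, k, explored, collection) {
  structure(list(rooting_edges = edges, solution = solution,
                 count = solution$count, method = method, optimal = optimal,
                 k = k, explored = explored,
                 bipartitions = vapply(seq_along(collection), function(i)
                   ug_edge_bipartition(collection[[i]], edges[i]), character(1))),
            class = "uec_result")
}

#' @export
print.uec_result <- function(x, ...) {
  cat(sprintf("UEC (%s): %d episode location(s); k = %d; %d combination(s) explored%s\n",
              x$method, x$count, x$k, x$explored,
              if (x$optimal) "; optimal" else "; optimality not certified"))
  invisible(x)
}

#' Exact unrooted episode clustering
#'
#' Two branches are compared. If every gene tree has an empty edge, the
#' clustering without a top-node episode is evaluated by rooting every tree
#' on its empty edge. For clusterings with a top-node episode, the Cartesian
#' product of the per-tree candidate sets is enumerated and each combination
#' is scored with [ec_greedy()]; the best of both branches is returned with
#' its witnessing rootings.
#'
#' With `refine = "star"` (default) the enumerated candidate sets are the
#' plateau-restricted star sets (`enum_candidates`, at most 5 per tree),
#' which is exhaustive over the episode-equivalence classes of plateau
#' rootings. With `refine = "u2prime"` the single-edge-per-star sets
#' (`branch_b`, at most 2; empty-edge fallback when a tree has none) are
#' enumerated, bounding the work by `1 + 2^k` at the price of missing the
#' optimum on some inputs (see the vignette).
#'
#' @inheritParams count_k
#' @param max_enum refusal cap on the enumeration size (default `2^20`).
#' @param refine `"star"` or `"u2prime"`.
#' @return a `uec_result` with `rooting_edges` (one edge id per tree), the
#'   `episode_solution`, `count`, `k`, `explored` (combinations scored),
#'   `optimal` (`TRUE` for `refine = "star"`), and leaf-set `bipartitions`
#'   naming the chosen edges.
#' @examples
#' S <- parse_species_newick("((a,b),c);")
#' gs <- list(parse_gene_newick("((a,c),(b,c));"))
#' uec_exact(gs, S)
#' @export
uec_exact <- function(collection, S, max_enum = 2^20,
                      candidates = lapply(collection, candidate_rootings, S = S),
                      refine = c("star", "u2prime")) {
  refine <- match.arg(refine)
  k <- count_k(collection, S, candidates)
  choice_lists <- lapply(candidates, function(cs) {
    if (refine == "star") cs$enum_candidates
    else if (length(cs$branch_b)) cs$branch_b else cs$empty_edge
  })
  n_comb <- prod(lengths(choice_lists))
  if (n_comb > max_enum)
    stop(sprintf("enumeration size %.0f exceeds max_enum = %.0f; consider uec_heuristic()",
                 n_comb, max_enum), call. = FALSE)
  best_edges <- NULL; best_sol <- NULL; explored <- 0L; branch_a <- NULL
  # branch without a top-node episode: feasible only if all trees have empty edges
  if (all(vapply(candidates, function(cs) cs$case == "empty-edge", logical(1)))) {
    branch_a <- vapply(candidates, `[[`, integer(1), "empty_edge")
    best_edges <- branch_a
    best_sol <- ec_greedy(root_combination(collection, branch_a), S)
    explored <- explored + 1L
  }
  # branch with a top-node episode: enumerate candidate combinations
  grid <- expand.grid(rev(choice_lists), KEEP.OUT.ATTRS = FALSE)
  grid <- as.matrix(grid)[, rev(seq_along(choice_lists)), drop = FALSE]
  for (r in seq_len(nrow(grid))) {
    edges <- as.integer(grid[r, ])
    if (!is.null(branch_a) && length(edges) && all(edges == branch_a)) next
    sol <- ec_greedy(root_combination(collection, edges), S)
    explored <- explored + 1L
    if (is.null(best_sol) || sol$count < best_sol$count) {
      best_sol <- sol; best_edges <- edges
    }
  }
  uec_result(best_edges, best_sol, paste0("exact-", refine),
             refine == "star", k, explored, collection)
}

#' Heuristic unrooted episode clustering
#'
#' Solves the subcollection of unambiguous trees exactly (cost `c0`, a lower
#' bound for the full input), then extends tree by tree: each ambiguous tree
#' tries its candidates and keeps one minimizing the clustering built so far.
#' If the full collection reaches `c0` the result is provably optimal;
#' otherwise the best cost found is returned with `optimal = FALSE` (fall
#' back to [uec_exact()] for a certificate).
#'
#' @inheritParams uec_exact
#' @return a `uec_result` with `method = "heuristic"`.
#' @export
uec_heuristic <- function(collection, S, max_enum = 2^20,
                          candidates = lapply(collection, candidate_rootings, S = S)) {
  k <- count_k(collection, S, candidates)
  amb <- which(vapply(candidates, `[[`, logical(1), "ambiguous"))
  uniq <- setdiff(seq_along(collection), amb)
  edges <- rep(NA_integer_, length(collection))
  explored <- 0L
  if (length(uniq)) {
    sub <- uec_exact(collection[uniq], S, max_enum, candidates[uniq])
    edges[uniq] <- sub$rooting_edges
    c0 <- sub$count
    explored <- sub$explored
  } else {
    c0 <- 0L
  }
  rooted <- vector("list", length(collection))
  for (i in uniq) rooted[[i]] <- root_at_edge(collection[[i]], edges[i])
  for (i in amb) {
    opts <- candidates[[i]]$enum_candidates
    scores <- vapply(opts, function(e) {
      trial <- c(Filter(Negate(is.null), rooted), list(root_at_edge(collection[[i]], e)))
      ec_greedy(trial, S)$count
    }, integer(1))
    explored <- explored + length(opts)
    pick <- opts[which.min(scores)]
    edges[i] <- pick
    rooted[[i]] <- root_at_edge(collection[[i]], pick)
  }
  sol <- ec_greedy(rooted, S)
  uec_result(edges, sol, "heuristic", sol$count == c0, k, explored, collection)
}

#' Exhaustive UEC oracle over all D-plateau rootings
#'
#' Scores the full Cartesian product of D-plateau rootings of every tree.
#' Exponential in the plateau sizes; intended as a small-instance certificate
#' for the candidate-based solvers.
#'
#' @inheritParams count_k
#' @param max_comb refusal cap on the product size.
#' @return a `uec_result` with `method = "brute"`.
#' @export
uec_brute <- function(collection, S, max_comb = 1e5) {
  plats <- lapply(collection, function(G) plateau(G, S, "D")$edges)
  n_comb <- prod(lengths(plats))
  if (n_comb > max_comb)
    stop("uec_brute: plateau-rooting product too large", call. = FALSE)
  # cache intervals per (tree, plateau edge): pooled stabbing is then cheap
  recon <- lapply(seq_along(collection), function(i)
    lapply(plats[[i]], function(e) {
      T <- root_at_edge(collection[[i]], e)
      M <- lca_map(T, S)
      events <- classify_events(T, S, M)
      dup_intervals(T, S, M, events)
    }))
  grid <- expand.grid(lapply(plats, seq_along), KEEP.OUT.ATTRS = FALSE)
  best_count <- Inf; best_edges <- NULL
  for (r in seq_len(nrow(grid))) {
    iv <- do.call(rbind, lapply(seq_along(collection),
                                function(i) recon[[i]][[grid[r, i]]]))
    cnt <- if (nrow(iv)) length(stab_intervals(S, iv$bottom, iv$top)) else 0L
    if (cnt < best_count) {
      best_count <- cnt
      best_edges <- vapply(seq_along(collection),
                           function(i) plats[[i]][grid[r, i]], integer(1))
    }
  }
  sol <- ec_greedy(root_combination(collection, best_edges), S)
  uec_result(best_edges, sol, "brute", TRUE, count_k(collection, S),
             as.integer(n_comb), collection)
}

#' Single-tree unrooted episode clustering
#'
#' The minimal episode count over all D-plateau rootings of one gene tree,
#' with the set of edges achieving it. When the tree has a double edge every
#' plateau rooting ties; when it has an empty edge the empty rooting is
#' always among the optima.
#'
#' @inheritParams candidate_rootings
#' @return a list with `count` and `edges` (optimal edge ids).
#' @export
single_uec <- function(G, S) {
  pl <- plateau(G, S, "D")
  counts <- vapply(pl$edges, function(e)
    ec_greedy(list(root_at_edge(G, e)), S)$count, integer(1))
  list(count = min(counts), edges = pl$edges[counts == min(counts)])
}
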