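# Rooted episode clustering (EC). Duplications may be relocated upward in the
# species tree through a *valid mapping* F, constrained by four conditions:
#   (1) F(a) below-or-equal F(b) whenever a is below b   (time consistency)
#   (2) F(a) = M(a) for every speciation a               (fixed speciations)
#   (3) F(a) above-or-equal M(a) for every duplication a (duplications raised)
#   (4) F(a) strictly below M(b) for every speciation b above a
#                                                (fixed number of duplications)
# Conditions (3)+(4) confine each duplication to a vertical species-tree path
# (its interval); EC is the minimum number of species nodes stabbing all
# intervals, solved by a deepest-top greedy certified against an exhaustive
# oracle.

#' Allowed species-tree interval of every duplication
#'
#' For each duplication `d`, the vertical path of species nodes where a valid
#' mapping may place it: from `bottom = M(d)` up to `top`, the child of
#' `M(b)` on the path toward `M(d)` for `d`'s nearest speciation ancestor `b`
#' (the species-tree root when `d` has no speciation ancestor).
#'
#' @param T a `rooted_gene_tree`.
#' @param S a `species_tree`.
#' @param M the [lca_map()]; computed if missing.
#' @param events the [classify_events()] labels; computed if missing.
#' @return a data frame with one row per duplication: `node`, `bottom`, `top`.
#' @export
dup_intervals <- function(T, S, M = lca_map(T, S),
                          events = classify_events(T, S, M)) {
  dups <- which(!is.na(events) & events == "duplication")
  bottom <- top <- integer(length(dups))
  for (i in seq_along(dups)) {
    d <- dups[i]
    bottom[i] <- M[d]
    b <- T$parent[d]
    while (!is.na(b) && events[b] != "speciation") b <- T$parent[b]
    if (is.na(b)) {
      top[i] <- S$root
    } else {
      if (M[b] == M[d])
        stop("speciation ancestor maps onto the duplication (internal error)", call. = FALSE)
      # ancestor of M(d) whose parent is M(b)
      x <- M[d]
      while (S$parent[x] != M[b]) x <- S$parent[x]
      top[i] <- x
    }
  }
  data.frame(node = dups, bottom = bottom, top = top)
}

#' Check a mapping against the four validity conditions
#'
#' Verbatim implementation of the conditions above; independent of the greedy
#' solver and used to certify every returned solution.
#'
#' @inheritParams dup_intervals
#' @param F integer vector of species-node ids indexed by gene-tree node.
#' @return `TRUE`, or a character scalar naming the violated condition.
#' @export
check_valid_mapping <- function(T, S, F, M = lca_map(T, S),
                                events = classify_events(T, S, M)) {
  internal <- which(!T$leaf)
  for (a in seq_len(T$n_nodes)) {
    b <- T$parent[a]
    if (is.na(b)) next
    # walk the whole ancestor chain of a
    while (!is.na(b)) {
      if (!node_is_anc(S, F[b], F[a]))
        return("time consistency: F(a) must be below-or-equal F(b) for a below b")
      if (!is.na(events[b]) && events[b] == "speciation") {
        if (!(node_is_anc(S, M[b], F[a]) && F[a] != M[b]))
          return("fixed number of gene duplications: F(a) must be strictly below M(b)")
      }
      b <- T$parent[b]
    }
  }
  for (a in internal) {
    if (events[a] == "speciation" && F[a] != M[a])
      return("fixed speciations: F(a) must equal M(a) for speciations")
    if (events[a] == "duplication" && !node_is_anc(S, F[a], M[a]))
      return("duplication can be raised: F(a) must be above-or-equal M(a)")
  }
  TRUE
}

# minimum stabbing of vertical species-tree paths: pick the interval with the
# deepest top (ties by postorder index), stab at its top, drop stabbed paths
stab_intervals <- function(S, bottom, top) {
  locations <- integer(0)
  active <- seq_along(bottom)
  while (length(active)) {
    depths <- S$depth[top[active]]
    cand <- active[depths == max(depths)]
    pick <- top[cand][which.min(match(top[cand], S$postorder))]
    locations <- c(locations, pick)
    keep <- vapply(active, function(i)
      !(node_is_anc(S, pick, bottom[i]) && node_is_anc(S, top[i], pick)),
      logical(1))
    active <- active[keep]
  }
  sort(locations)
}

build_solution <- function(trees, S, recon, locations) {
  mappings <- vector("list", length(trees))
  placements <- NULL
  for (i in seq_along(trees)) {
    T <- trees[[i]]; M <- recon[[i]]$M; events <- recon[[i]]$events
    F <- M
    iv <- recon[[i]]$intervals
    if (nrow(iv)) {
      for (j in seq_len(nrow(iv))) {
        inside <- locations[vapply(locations, function(s)
          node_is_anc(S, s, iv$bottom[j]) && node_is_anc(S, iv$top[j], s),
          logical(1))]
        if (!length(inside))
          stop("an interval is not stabbed by the selected locations (internal error)",
               call. = FALSE)
        F[iv$node[j]] <- inside[which.max(S$depth[inside])]
      }
      placements <- rbind(placements, data.frame(
        tree = i, node = iv$node, bottom = iv$bottom, top = iv$top,
        location = F[iv$node]))
    }
    ok <- check_valid_mapping(T, S, F, M, events)
    if (!isTRUE(ok))
      stop(sprintf("solver produced an invalid mapping (%s)", ok), call. = FALSE)
    mappings[[i]] <- F
  }
  used <- sort(unique(if (is.null(placements)) integer(0) else placements$location))
  structure(list(locations = used, count = length(used),
                 mappings = mappings, placements = placements),
            class = "episode_solution")
}

#' @export
print.episode_solution <- function(x, ...) {
  cat(sprintf("Episode clustering: %d episode location(s)\n", x$count))
  if (x$count) cat("  species nodes:", paste(x$locations, collapse = ", "), "\n")
  invisible(x)
}

reconcile_all <- function(trees, S) {
  lapply(trees, function(T) {
    M <- lca_map(T, S)
    events <- classify_events(T, S, M)
    list(M = M, events = events, intervals = dup_intervals(T, S, M, events))
  })
}

#' Minimal duplication episodes for rooted gene trees (greedy)
#'
#' Pools the duplication intervals of all trees and stabs them with the fewest
#' species nodes: repeatedly place an episode at the deepest interval top and
#' drop all intervals containing it. Each duplication is then assigned the
#' deepest selected location inside its interval and the resulting mappings
#' are re-checked against the four validity conditions. The count is minimal
#' (exchange argument on vertical paths; certified against [ec_brute()]).
#'
#' @param trees a list of `rooted_gene_tree` objects (or a single tree).
#' @param S a `species_tree`.
#' @return an `episode_solution`: `locations` (species-node ids), `count`,
#'   per-tree `mappings`, and a `placements` table.
#' @examples
#' S <- parse_species_newick("((a,b),c);")
#' G <- parse_gene_newick("((a,b),a);")
#' T <- root_at_edge(G, find_opt_edge(G, S))
#' ec_greedy(list(T), S)
#' @export
ec_greedy <- function(trees, S) {
  if (inherits(trees, "rooted_gene_tree")) trees <- list(trees)
  recon <- reconcile_all(trees, S)
  iv <- do.call(rbind, lapply(recon, `[[`, "intervals"))
  locations <- if (is.null(iv) || nrow(iv) == 0L) integer(0)
    else stab_intervals(S, iv$bottom, iv$top)
  build_solution(trees, S, recon, locations)
}

#' Exhaustive episode-clustering oracle
#'
#' Enumerates every assignment of each duplication to a node of its interval,
#' filters the assignments by the four validity conditions, and returns one
#' minimizing the number of distinct locations. Exponential; refuses inputs
#' with more than `limit` duplications.
#'
#' @inheritParams ec_greedy
#' @param limit maximum total number of duplications (default 10).
#' @return an `episode_solution`.
#' @export
ec_brute <- function(trees, S, limit = 10L) {
  if (inherits(trees, "rooted_gene_tree")) trees <- list(trees)
  recon <- reconcile_all(trees, S)
  iv <- do.call(rbind, lapply(seq_along(recon), function(i) {
    x <- recon[[i]]$intervals
    if (nrow(x)) cbind(tree = i, x) else NULL
  }))
  if (is.null(iv) || nrow(iv) == 0L)
    return(build_solution(trees, S, recon, integer(0)))
  if (nrow(iv) > limit)
    stop(sprintf("ec_brute: %d duplications exceed the limit of %d", nrow(iv), limit),
         call. = FALSE)
  paths <- lapply(seq_len(nrow(iv)), function(j)
    node_vertical_path(S, iv$bottom[j], iv$top[j]))
  if (prod(lengths(paths)) > 2e6)
    stop("ec_brute: assignment space too large", call. = FALSE)
  grid <- as.matrix(expand.grid(paths, KEEP.OUT.ATTRS = FALSE))
  best <- NULL; best_n <- Inf
  for (r in seq_len(nrow(grid))) {
    assign_ <- grid[r, ]
    ok <- TRUE
    for (i in unique(iv$tree)) {
      sel <- iv$tree == i
      F <- recon[[i]]$M
      F[iv$node[sel]] <- assign_[sel]
      if (!isTRUE(check_valid_mapping(trees[[i]], S, F,
                                      recon[[i]]$M, recon[[i]]$events))) {
        ok <- FALSE; break
      }
    }
    if (!ok) next
    n_loc <- length(unique(assign_))
    if (n_loc < best_n) { best_n <- n_loc; best <- assign_ }
  }
  if (is.null(best)) stop("no valid assignment found (internal error)", call. = FALSE)
  build_solution(trees, S, recon, sort(unique(best)))
}

#' Episodes as a percentage of species-tree nodes
#'
#' `100 * count / (2 * leaves(S) - 1)`: the fraction of species-tree nodes
#' that carry a duplication episode.
#'
#' @param count episode count.
#' @param S a `species_tree`.
#' @return a percentage.
#' @examples
#' ec_percent_locations(17, parse_species_newick(
#'   "((((((a,b),c),d),e),(f,g)),(h,i));"))  # 100 for a 9-leaf tree
#' @export
ec_percent_locations <- function(count, S) {
  stopifnot(count >= 0)
  100 * count / (2L * sum(S$leaf) - 1L)
}
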