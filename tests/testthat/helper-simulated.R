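# Shared simulated test inputs, generated once per test run and cached.

.suite_cache <- new.env(parent = emptyenv())

# a rooted gene tree straight from Newick (no unrooting)
mk_rooted <- function(nwk, rule = label_map_rule()) {
  phy <- ape::read.tree(text = nwk)
  T <- uecr:::phylo_to_rooted_gene(phy)
  T$label <- ifelse(T$leaf, uecr:::apply_label_rule(T$label, rule), T$label)
  T
}

# sorted leaf-label bipartitions of all edges: an isomorphism fingerprint
ug_fingerprint <- function(G) {
  sort(vapply(seq_len(nrow(G$edges)),
              function(e) uecr:::ug_edge_bipartition(G, e), character(1)))
}

# leaf-label clade sets of a rooted tree: a topology fingerprint
rt_fingerprint <- function(T) {
  sort(vapply(seq_len(T$n_nodes), function(v)
    paste(sort(T$label[uecr:::descendant_leaves(T$children, v)]), collapse = ","),
    character(1)))
}

# the study suite: 300 duplication-loss gene trees over 5-10 leaf species
# trees (per-branch duplication 0.3, loss 0.2), seeds 0-299
simulated_suite <- function(n = 300L) {
  key <- paste0("suite", n)
  if (is.null(.suite_cache[[key]])) {
    .suite_cache[[key]] <- lapply(seq_len(n) - 1L, function(i) {
      S <- random_species_tree(5L + (i %% 6L), seed = i)
      sim <- simulate_gene_tree(S, sim_config(0.3, 0.2), seed = i)
      list(S = S, G = sim$unrooted, rooted = sim$rooted,
           n_dup_events = sim$n_dup_events)
    })
  }
  .suite_cache[[key]]
}

# small rooted collections for the episode-clustering oracle: 1-4 trees over
# 5-8 leaf species trees (duplication 0.2, loss 0.1); collections are
# truncated from the back until the exhaustive oracle's limits are met
ec_instances <- function(n = 200L) {
  key <- paste0("ec", n)
  if (is.null(.suite_cache[[key]])) {
    .suite_cache[[key]] <- lapply(seq_len(n) - 1L, function(i) {
      S <- random_species_tree(5L + (i %% 4L), seed = 10000L + i)
      trees <- lapply(seq_len(1L + (i %% 4L)), function(j)
        simulate_gene_tree(S, sim_config(0.2, 0.1), seed = 10000L + i * 7L + j)$rooted)
      within_limits <- function(trees) {
        iv <- do.call(rbind, lapply(trees, function(T) dup_intervals(T, S)))
        n_dup <- if (is.null(iv)) 0L else nrow(iv)
        sz <- if (n_dup == 0L) 1 else
          prod(vapply(seq_len(n_dup), function(j)
            length(uecr:::node_vertical_path(S, iv$bottom[j], iv$top[j])), numeric(1)))
        n_dup <= 10L && sz <= 2e4
      }
      off <- 0L
      while (!within_limits(trees)) {
        if (length(trees) > 1L) trees <- trees[-length(trees)]
        else {
          off <- off + 1L
          trees <- list(simulate_gene_tree(S, sim_config(0.2, 0.1),
                                           seed = 10000L + i * 7L + 100L + off)$rooted)
        }
      }
      list(S = S, trees = trees)
    })
  }
  .suite_cache[[key]]
}

# small unrooted collections for the UEC oracle: 2-4 trees over 5-8 leaf
# species trees (duplication 0.25, loss 0.15); regenerated with a shifted
# seed until the full plateau-rooting product is within the oracle's reach
uec_collections <- function(n = 150L) {
  key <- paste0("uec", n)
  if (is.null(.suite_cache[[key]])) {
    .suite_cache[[key]] <- lapply(seq_len(n) - 1L, function(i) {
      base <- 20000L + i * 101L
      repeat {
        S <- random_species_tree(5L + (i %% 4L), seed = base)
        gs <- lapply(seq_len(2L + (i %% 3L)), function(j)
          simulate_gene_tree(S, sim_config(0.25, 0.15), seed = base + j)$unrooted)
        sz <- prod(vapply(gs, function(G) length(plateau(G, S, "D")$edges), integer(1)))
        if (sz <= 400) break
        base <- base + 1L
      }
      list(S = S, trees = gs)
    })
  }
  .suite_cache[[key]]
}
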