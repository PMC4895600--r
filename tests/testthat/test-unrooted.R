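S3 <- parse_species_newick("((a,b),c);")

edge_by_labels <- function(G, lab_v, lab_w = NULL) {
  # edge id whose leaf endpoints carry the given labels (lab_w NULL: any side)
  hits <- which(apply(G$edges, 1, function(r) {
    l <- G$label[r]
    if (is.null(lab_w)) any(l == lab_v, na.rm = TRUE)
    else all(c(lab_v, lab_w) %in% l)
  }))
  hits[1]
}

test_that("directed edge images equal the subtree lca images", {
  G <- parse_gene_newick("((a,b),c);")
  maps <- directed_edge_maps(G, S3)
  ctr <- which(!G$leaf)
  c_leaf <- which(G$label == "c")
  ab <- uecr:::node_lca(S3, S3$leaf_index[["a"]], S3$leaf_index[["b"]])
  expect_equal(maps$dmap[ctr, c_leaf], unname(S3$leaf_index[["c"]]))
  expect_equal(maps$dmap[c_leaf, ctr], ab)

  S4 <- parse_species_newick("((a,b),(c,d));")
  G4 <- parse_gene_newick("((a,b),(c,d));")
  m4 <- directed_edge_maps(G4, S4)
  v <- which(!G4$leaf)[1]; w <- which(!G4$leaf)[2]
  imgs <- sort(c(m4$dmap[v, w], m4$dmap[w, v]))
  ab4 <- uecr:::node_lca(S4, S4$leaf_index[["a"]], S4$leaf_index[["b"]])
  cd4 <- uecr:::node_lca(S4, S4$leaf_index[["c"]], S4$leaf_index[["d"]])
  expect_setequal(imgs, sort(c(ab4, cd4)))

  # any leaf edge: the image toward the leaf is that species leaf
  for (lf in which(G4$leaf)) {
    nb <- G4$adj[[lf]]
    expect_equal(m4$dmap[nb, lf], unname(S4$leaf_index[[G4$label[lf]]]))
  }
})

test_that("edge classes match the empty/single/double definitions on fixtures", {
  G <- parse_gene_newick("((a,b),c);")
  cls <- classify_edges(G, S3)
  expect_equal(cls$class[edge_by_labels(G, "c")], "empty")
  expect_equal(sum(cls$class == "empty"), 1L)

  G2 <- parse_gene_newick("((a,c),(b,c));")
  cls2 <- classify_edges(G2, S3)
  internal2 <- which(apply(G2$edges, 1, function(r) all(!G2$leaf[r])))
  expect_equal(cls2$class[internal2], "double")
  expect_true(all(cls2$class[-internal2] == "single"))

  S4 <- parse_species_newick("((a,b),(c,d));")
  G4 <- parse_gene_newick("((a,b),(c,d));")
  cls4 <- classify_edges(G4, S4)
  a_edge <- edge_by_labels(G4, "a")
  expect_equal(cls4$class[a_edge], "single")
  expect_equal(cls4$incoming[a_edge], which(G4$label == "a"))
})

test_that("star types follow the five feasible edge-role combinations", {
  G <- parse_gene_newick("((a,b),c);")
  expect_equal(classify_stars(G, S3)$type, "S2")

  G2 <- parse_gene_newick("((a,c),(b,c));")
  expect_equal(sort(classify_stars(G2, S3)$type), c("S3", "S3"))

  G3 <- parse_gene_newick("((a,b),(a,c));")   # S2 star at the empty edge
  st <- classify_stars(G3, S3)
  expect_setequal(st$type, c("S1", "S2"))
})

test_that("per-edge rooting costs match fixtures and the plateau is their argmin", {
  G <- parse_gene_newick("((a,b),c);")
  prof <- rooting_cost_profile(G, S3, "D")
  expect_equal(prof[edge_by_labels(G, "c")], 0L)
  expect_equal(sort(prof), c(0L, 1L, 1L))
  pl <- plateau(G, S3, "D")
  expect_equal(pl$cost, 0L)
  expect_equal(pl$edges, edge_by_labels(G, "c"))

  G2 <- parse_gene_newick("((a,c),(b,c));")
  prof2 <- rooting_cost_profile(G2, S3, "D")
  internal2 <- which(apply(G2$edges, 1, function(r) all(!G2$leaf[r])))
  expect_equal(prof2[internal2], 1L)
  expect_true(all(prof2[-internal2] == 2L))
  plD <- plateau(G2, S3, "D"); plDL <- plateau(G2, S3, "DL")
  expect_equal(plD$edges, internal2)
  expect_equal(plDL$edges, internal2)   # single-double-edge case: plateaus equal

  G3 <- parse_gene_newick("((a,b),(a,c));")
  pl3 <- plateau(G3, S3, "D")
  expect_equal(pl3$cost, 1L)
  expect_equal(length(pl3$edges), 3L)
  # min over the profile equals the cost of any plateau edge
  expect_equal(min(pl3$profile), pl3$cost)
})

test_that("cost profiles agree with naive re-rooting on simulated trees", {
  suite <- simulated_suite(300)[1:30]
  for (x in suite) {
    maps <- directed_edge_maps(x$G, x$S)
    for (kind in c("D", "DL")) {
      prof <- rooting_cost_profile(x$G, x$S, kind, maps)
      naive <- vapply(seq_len(nrow(x$G$edges)), function(e) {
        T <- root_at_edge(x$G, e)
        if (kind == "D") dup_cost(T, x$S) else dl_cost(T, x$S)
      }, integer(1))
      expect_equal(prof, naive)
    }
  }
})

test_that("an empty or double edge always exists and is what the search returns", {
  G <- parse_gene_newick("((a,b),c);")
  expect_equal(find_opt_edge(G, S3), edge_by_labels(G, "c"))
  G2 <- parse_gene_newick("((a,c),(b,c));")
  expect_equal(find_opt_edge(G2, S3),
               which(apply(G2$edges, 1, function(r) all(!G2$leaf[r]))))
  suite <- simulated_suite(300)[1:40]
  for (x in suite) {
    cls <- classify_edges(x$G, x$S)
    e <- find_opt_edge(x$G, x$S)
    expect_true(cls$class[e] %in% c("empty", "double"))
    if (cls$class[e] == "empty")
      expect_equal(sum(cls$class == "empty"), 1L)
  }
})
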