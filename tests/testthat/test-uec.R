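S3 <- parse_species_newick("((a,b),c);")

test_that("candidate rooting sets match the fixture annotations", {
  fx <- fixture_suite()
  for (nm in names(fx)) {
    f <- fx[[nm]]
    cs <- candidate_rootings(f$G, f$S)
    expect_equal(length(cs$branch_b), f$expect$n_branch_b, info = nm)
    expect_equal(cs$ambiguous, f$expect$ambiguous, info = nm)
    expect_lte(length(cs$theorem5), 5L)
    pl <- plateau(f$G, f$S, "D")
    expect_equal(pl$cost, f$expect$plateau_cost, info = nm)
    expect_equal(length(pl$edges), f$expect$plateau_size, info = nm)
    if (!is.null(f$expect$empty)) {
      expect_equal(cs$case, "empty-edge")
      expect_equal(uecr:::ug_edge_bipartition(f$G, cs$empty_edge), f$expect$empty)
    } else {
      expect_equal(cs$case, "double-edge")
    }
    # every enumerated candidate is D-minimal
    expect_true(all(cs$enum_candidates %in% pl$edges))
  }
})

test_that("the ambiguity parameter counts trees with two refined candidates", {
  fx <- fixture_suite()
  gs <- lapply(fx, `[[`, "G")
  expect_equal(count_k(gs, S3), 1L)
  expect_equal(count_k(rep(list(fx$two_s2$G), 3), S3), 3L)
  expect_equal(count_k(list(), S3), 0L)
})

test_that("single-tree solutions return the minimal count and all optimal edges", {
  fx <- fixture_suite()
  for (nm in names(fx)) {
    f <- fx[[nm]]
    su <- single_uec(f$G, f$S)
    expect_equal(su$count, f$expect$single_uec, info = nm)
    # exhaustive check over the plateau
    pl <- plateau(f$G, f$S, "D")
    counts <- vapply(pl$edges, function(e)
      ec_brute(list(root_at_edge(f$G, e)), f$S)$count, integer(1))
    expect_equal(su$count, min(counts))
    expect_setequal(su$edges, pl$edges[counts == min(counts)])
  }
  # the empty-edge rooting is always among the single-tree optima
  su <- single_uec(fx$one_s2$G, S3)
  cs <- candidate_rootings(fx$one_s2$G, S3)
  expect_true(cs$empty_edge %in% su$edges)
  expect_equal(length(su$edges), 3L)   # all plateau rootings tie here
})

test_that("exact solver reproduces the worked collection examples", {
  fx <- fixture_suite()
  expect_equal(uec_exact(list(fx$empty_star$G), S3)$count, 0L)
  expect_equal(uec_exact(list(fx$double_edge$G), S3)$count, 1L)
  pair <- uec_exact(list(fx$one_s2$G, fx$double_edge$G), S3)
  expect_equal(pair$count, 1L)   # one_s2 rerooted so its duplication joins the top episode
  expect_true(all(vapply(seq_along(pair$rooting_edges), function(i)
    pair$rooting_edges[i] %in% plateau(list(fx$one_s2$G, fx$double_edge$G)[[i]], S3, "D")$edges,
    logical(1))))
  expect_error(uec_exact(list(fx$two_s2$G), S3, max_enum = 1), "max_enum")
})

test_that("exact solver equals the full plateau-rooting brute force", {
  colls <- uec_collections(150)[1:50]
  for (cl in colls) {
    ex <- uec_exact(cl$trees, cl$S)
    br <- uec_brute(cl$trees, cl$S, max_comb = 1e5)
    expect_equal(ex$count, br$count)
    expect_true(ex$optimal)
  }
})

test_that("collections of double-edge trees are rooting-invariant", {
  # every plateau rooting combination yields the same episode count
  colls <- uec_collections(150)[1:60]
  checked <- 0L
  for (cl in colls) {
    dbl <- vapply(cl$trees, function(G)
      candidate_rootings(G, cl$S)$case == "double-edge", logical(1))
    if (!all(dbl) || length(cl$trees) < 2L) next
    plats <- lapply(cl$trees, function(G) plateau(G, cl$S, "D")$edges)
    if (prod(lengths(plats)) > 200) next
    grid <- expand.grid(plats, KEEP.OUT.ATTRS = FALSE)
    counts <- apply(grid, 1, function(edges)
      ec_greedy(lapply(seq_along(cl$trees), function(i)
        root_at_edge(cl$trees[[i]], edges[i])), cl$S)$count)
    expect_equal(length(unique(counts)), 1L)
    checked <- checked + 1L
  }
  expect_gte(checked, 1L)
})

test_that("empty-edge rootings are never beaten within a single tree", {
  suite <- simulated_suite(300)[1:40]
  for (x in suite) {
    cs <- candidate_rootings(x$G, x$S)
    if (cs$case != "empty-edge") next
    su <- single_uec(x$G, x$S)
    expect_true(cs$empty_edge %in% su$edges)
  }
})

test_that("the published one-candidate-per-star refinement bounds its enumeration by 1 + 2^k", {
  colls <- uec_collections(150)[1:60]
  for (cl in colls) {
    u2 <- uec_exact(cl$trees, cl$S, refine = "u2prime")
    expect_lte(u2$explored, 1L + 2L^u2$k)
    ex <- uec_exact(cl$trees, cl$S)
    expect_gte(u2$count, ex$count)   # may miss the optimum, never beat it
  }
})

test_that("heuristic certifies optimality exactly when it reaches the lower bound", {
  fx <- fixture_suite()
  # no ambiguity: identical to the exact solver
  gs0 <- list(fx$one_s2$G, fx$double_edge$G)
  h0 <- uec_heuristic(gs0, S3)
  expect_true(h0$optimal)
  expect_equal(h0$count, uec_exact(gs0, S3)$count)
  # an ambiguous tree whose extension cannot reach the subcollection bound
  gs1 <- list(fx$one_s2$G, fx$double_edge$G, fx$two_s2$G)
  h1 <- uec_heuristic(gs1, S3)
  e1 <- uec_exact(gs1, S3)
  expect_false(h1$optimal)
  expect_gte(h1$count, e1$count)
  # heuristic never beats the exact solver on random collections
  colls <- uec_collections(150)[61:100]
  for (cl in colls) {
    h <- uec_heuristic(cl$trees, cl$S)
    ex <- uec_exact(cl$trees, cl$S)
    expect_gte(h$count, ex$count)
    if (h$optimal) expect_equal(h$count, ex$count)
    expect_true(all(vapply(seq_along(cl$trees), function(i)
      h$rooting_edges[i] %in% plateau(cl$trees[[i]], cl$S, "D")$edges, logical(1))))
  }
})
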