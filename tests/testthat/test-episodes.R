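S3 <- parse_species_newick("((a,b),c);")
ab3 <- uecr:::node_lca(S3, S3$leaf_index[["a"]], S3$leaf_index[["b"]])

test_that("duplication intervals follow the nearest-speciation cap", {
  T <- mk_rooted("((a,b),a);")
  iv <- dup_intervals(T, S3)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$bottom, ab3)
  expect_equal(iv$top, S3$root)        # no speciation ancestor: root cap

  T2 <- mk_rooted("(((a,a),b),c);")
  iv2 <- dup_intervals(T2, S3)
  expect_equal(iv2$bottom, unname(S3$leaf_index[["a"]]))
  expect_equal(iv2$top, unname(S3$leaf_index[["a"]]))  # capped strictly below ab

  T3 <- mk_rooted("((a,c),a);")
  iv3 <- dup_intervals(T3, S3)
  expect_equal(iv3$bottom, S3$root)
  expect_equal(iv3$top, S3$root)
})

test_that("nearest-speciation caps are the tightest among all speciation ancestors", {
  suite <- simulated_suite(300)[1:40]
  for (x in suite) {
    T <- x$rooted; S <- x$S
    M <- lca_map(T, S)
    events <- classify_events(T, S, M)
    iv <- dup_intervals(T, S, M, events)
    if (!nrow(iv)) next
    for (j in seq_len(nrow(iv))) {
      d <- iv$node[j]
      b <- T$parent[d]
      while (!is.na(b)) {
        if (events[b] == "speciation") {
          # the interval top must lie strictly below every speciation ancestor
          expect_true(uecr:::node_is_anc(S, M[b], iv$top[j]) && M[b] != iv$top[j])
        }
        b <- T$parent[b]
      }
    }
  }
})

test_that("greedy episode clustering matches the exhaustive oracle on fixtures", {
  T <- mk_rooted("((a,b),a);")
  T4 <- mk_rooted("(((a,a),b),c);")
  T5 <- mk_rooted("((a,c),a);")

  s1 <- ec_greedy(list(T), S3)
  expect_equal(s1$count, 1L)
  expect_equal(ec_brute(list(T), S3)$count, 1L)

  s2 <- ec_greedy(list(T, T5), S3)
  expect_equal(s2$count, 1L)
  expect_equal(s2$locations, S3$root)  # raised to the top node
  expect_equal(ec_brute(list(T, T5), S3)$count, 1L)

  s3 <- ec_greedy(list(T, T4), S3)
  expect_equal(s3$count, 2L)           # disjoint intervals
  expect_equal(ec_brute(list(T, T4), S3)$count, 2L)

  expect_equal(ec_greedy(list(mk_rooted("(a,b);")), S3)$count, 0L)
  expect_equal(ec_brute(list(mk_rooted("(a,b);")), S3)$count, 0L)
  expect_error(ec_brute(rep(list(T4), 11), S3), "limit")
})

test_that("greedy episode counts equal the oracle on random small instances", {
  insts <- ec_instances(200)[1:80]
  for (inst in insts) {
    g <- ec_greedy(inst$trees, inst$S)
    b <- ec_brute(inst$trees, inst$S, limit = 10L)
    expect_equal(g$count, b$count)
  }
})

test_that("solutions satisfy the validity conditions and combinatorial bounds", {
  insts <- ec_instances(200)[81:140]
  for (inst in insts) {
    sol <- ec_greedy(inst$trees, inst$S)
    n_dup <- 0L
    for (i in seq_along(inst$trees)) {
      T <- inst$trees[[i]]
      M <- lca_map(T, inst$S)
      ev <- classify_events(T, inst$S, M)
      n_dup <- n_dup + sum(ev == "duplication", na.rm = TRUE)
      expect_true(isTRUE(check_valid_mapping(T, inst$S, sol$mappings[[i]], M, ev)))
    }
    if (n_dup > 0L) expect_gte(sol$count, 1L)
    expect_lte(sol$count, n_dup)
    expect_lte(sol$count, 2L * sum(inst$S$leaf) - 1L)
  }
})

test_that("adding a gene tree never decreases the episode count", {
  insts <- ec_instances(200)[141:200]
  for (inst in insts) {
    if (length(inst$trees) < 2L) next
    counts <- vapply(seq_along(inst$trees), function(m)
      ec_greedy(inst$trees[seq_len(m)], inst$S)$count, integer(1))
    expect_true(all(diff(counts) >= 0L))
  }
})

test_that("episode percentages are computed per species-tree node", {
  S16 <- parse_species_newick(
    "(((((((((((((((a,b),c),d),e),f),g),h),i),j),k),l),m),n),o),p);")
  expect_equal(round(ec_percent_locations(4, S16), 1), 12.9)
  S9 <- parse_species_newick("((((((((a,b),c),d),e),f),g),h),i);")
  expect_equal(ec_percent_locations(17, S9), 100)
  expect_equal(ec_percent_locations(0, S3), 0)
})
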