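test_that("leaf tables enumerate valid selection/furthest-vertex entries", {
  # bag {source, sink}, no edge between them: single forced entry
  g0 <- toy_graph(2, list())
  t0 <- leaf_entries(c(1, 2), g0)
  expect_equal(nrow(t0$entries), 1)
  expect_equal(t0$entries$sel, "11")
  expect_equal(t0$entries$L, 1)
  expect_equal(t0$entries$len, 0)
  # bag {source, v, sink} with edge source -> v only
  g1 <- toy_graph(3, list(c(1, 2)))
  t1 <- leaf_entries(c(1, 2, 3), g1)
  expect_equal(nrow(t1$entries), 2)
  sel1 <- t1$entries[t1$entries$sel == "111", ]
  expect_equal(sel1$len, 1)
  expect_equal(sel1$L, 2)
  sel0 <- t1$entries[t1$entries$sel == "101", ]
  expect_equal(sel0$len, 0)
  expect_equal(sel0$L, 1)
})

test_that("a selected complement pair never yields an entry", {
  # source - v1 - v2 - sink with a complement edge {v1, v2}
  g <- toy_graph(4, list(c(1, 2), c(2, 3), c(3, 4)), complements = list(c(2, 3)))
  tb <- leaf_entries(c(1, 2, 3, 4), g)
  both <- substr(tb$entries$sel, 2, 3) == "11"
  expect_false(any(both))
})

test_that("identity transition preserves the table", {
  g <- ga_graph()
  bag <- 1:4
  tb <- leaf_entries(bag, g)
  tb2 <- transition(tb, bag, bag, g)
  o1 <- order(tb$entries$sel)
  o2 <- order(tb2$entries$sel)
  expect_equal(tb$entries$sel[o1], tb2$entries$sel[o2])
  expect_equal(tb$entries$len[o1], tb2$entries$len[o2])
})

test_that("induced_length counts edges among selected vertices", {
  g <- toy_graph(4, list(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(induced_length(g, c(1, 2, 3)), 2)
  expect_equal(induced_length(g, c(1, 3)), 0)
  g2 <- toy_graph(5, list(c(1, 2), c(3, 4)))
  expect_equal(induced_length(g2, c(1, 2, 3, 4)), 2)
})

test_that("worked examples solve to the expected partial paths", {
  # two-residue graph: length 2, tie broken toward the smaller first peak
  g <- ga_graph()
  p <- solve_lapp(g)
  expect_equal(p$total_length, 2)
  expect_length(p$segments, 1)
  expect_equal(g$vertices$mass[p$segments[[1]][2]], 57.02146,
               tolerance = 1e-6)
  # single-peak GG spectrum (peak at M/2 gets no complement loop)
  g2 <- build_graph(spectrum(57.02146, 1, 114.04292), TAB, tol = 0.001)
  p2 <- solve_lapp(g2)
  expect_equal(p2$total_length, 2)
  expect_length(p2$segments, 1)
  # deleting the middle of a unique chain leaves two segments
  seqs <- c("G", "A", "S", "V", "K")
  pm <- cumsum(residue_mass(seqs, TAB))
  M <- pm[length(pm)]
  peaks <- pm[-length(pm)]
  peaks <- peaks[-2]  # drop b2; keep a b-only ladder (no y peaks)
  g3 <- build_graph(spectrum(peaks, 1, M), TAB, tol = 0.001)
  p3 <- solve_lapp(g3)
  expect_equal(p3$total_length, 3)
  expect_length(p3$segments, 2)
  expect_true(isTRUE(validate_antisym_path(p3, g3)))
})

test_that("conflicting source and sink arms keep the longer one", {
  # source->v1->v2 and v3->sink, complement {v2, v3}: keep the 2-edge arm
  g <- toy_graph(5, list(c(1, 2), c(2, 3), c(4, 5)),
                 complements = list(c(3, 4)))
  p <- solve_lapp(g)
  bf <- brute_force_lapp(g)
  expect_equal(p$total_length, 2)
  expect_equal(bf$total_length, 2)
})

test_that("edgeless graphs give a zero-length two-segment anchor", {
  g <- toy_graph(4, list())
  p <- solve_lapp(g)
  expect_equal(p$total_length, 0)
  expect_equal(length(p$segments), 2)
  expect_true(isTRUE(validate_antisym_path(p, g)))
})

test_that("DP equals the brute-force oracle on random mixed graphs", {
  set.seed(71)
  for (i in 1:60) {
    g <- random_mixed_graph()
    bf <- brute_force_lapp(g)
    p <- solve_lapp(g)
    expect_equal(p$total_length, bf$total_length)
    expect_true(isTRUE(validate_antisym_path(p, g)))
  }
})

test_that("the optimum is identical across valid decompositions", {
  set.seed(72)
  for (i in 1:20) {
    g <- random_mixed_graph(max_peaks = 8)
    ref <- solve_lapp(g)$total_length
    for (r in 1:3) {
      pd <- random_decomposition(g)
      expect_true(isTRUE(validate_decomposition(pd, g)))
      expect_equal(solve_lapp(g, pd)$total_length, ref)
    }
    expect_equal(solve_lapp(g, decompose(g, strategy = "mass"))$total_length,
                 ref)
  }
})

test_that("without complement edges the single-path optimum matches a
           topological longest-path DP", {
  set.seed(73)
  for (i in 1:20) {
    g <- random_mixed_graph()
    g$complements <- g$complements[0, , drop = FALSE]
    p <- solve_lapp(g)
    topo <- pdnovo:::longest_path_dag(g)
    expect_gte(p$total_length, max(0, topo))
    if (length(p$segments) == 1 && is.finite(topo)) {
      expect_equal(p$total_length, topo)
    }
  }
})

test_that("DP tables respect the (selection, furthest-vertex) size bound", {
  set.seed(74)
  for (i in 1:10) {
    g <- random_mixed_graph()
    p <- solve_lapp(g, keep_tables = TRUE)
    sw <- attr(p, "tables")
    pbag <- pmax(sw$bag_sizes, 2)
    expect_true(all(sw$entry_counts <= 2^(pbag - 2) * (pbag + 1)))
  }
})

test_that("table dumps are written for debugging", {
  g <- ga_graph()
  p <- solve_lapp(g, keep_tables = TRUE)
  f <- withr::local_tempfile(fileext = ".txt")
  write_dp_tables(p, f)
  expect_gt(length(readLines(f)), 0)
  expect_error(write_dp_tables(solve_lapp(g), f), "keep_tables")
})
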