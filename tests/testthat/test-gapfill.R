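# exhaustive enumeration of residue multisets (with optional single
# modified residue) summing to delta -- the oracle for subset_fill
enumerate_fills <- function(delta, tol, max_residues, with_mods = FALSE) {
  items <- TAB$residues
  labels <- names(items)
  nmod <- integer(length(items))
  if (with_mods) {
    mm <- MODS$mods
    items <- c(items, TAB$residues[mm$target] + mm$delta)
    labels <- c(labels, paste0(mm$target, "+", mm$label))
    nmod <- c(nmod, rep(1L, nrow(mm)))
  }
  out <- list()
  rec <- function(start, left, rem, acc, used) {
    if (abs(rem) <= tol && length(acc)) {
      out[[length(out) + 1L]] <<- sort(labels[acc])
    }
    if (left == 0L) return(invisible())
    for (i in seq(start, length(items))) {
      if (items[i] > rem + tol) next
      if (used + nmod[i] > 1L) next
      rec(i, left - 1L, rem - items[i], c(acc, i), used + nmod[i])
    }
  }
  rec(1L, max_residues, delta, integer(), 0L)
  unique(out)
}

test_that("worked gap fills behave as documented", {
  expect_equal(subset_fill(57.02146, TAB, MODS, tol = 0.01)$candidates[[1]],
               "G")
  f <- subset_fill(114.04293, TAB, MODS, tol = 0.01)
  expect_equal(f$status, "exact")
  expect_equal(f$candidates[[1]], "N")          # fewer residues first
  expect_true(list(c("G", "G")) %in% lapply(f$candidates, sort))
  # oxidized methionine only reachable through the modified pass
  f2 <- subset_fill(147.03540, TAB, MODS, tol = 0.01)
  expect_equal(f2$status, "modified")
  expect_equal(f2$candidates[[1]], "M+ox")
  # below the minimum residue mass: unresolved
  f3 <- subset_fill(30.0, TAB, MODS, tol = 0.01)
  expect_equal(f3$status, "unresolved")
  expect_length(f3$candidates, 0)
})

test_that("subset_fill agrees with exhaustive enumeration on random deltas", {
  set.seed(41)
  for (i in 1:40) {
    k <- sample(1:3, 1)
    delta <- sum(sample(TAB$residues, k, replace = TRUE)) +
      runif(1, -0.02, 0.02)
    tol <- 0.02
    maxr <- max(1L, ceiling(delta / TAB$min_residue_mass))
    got <- subset_fill(delta, TAB, MODS, tol = tol, max_candidates = 1000L)
    want <- enumerate_fills(delta, tol, maxr, with_mods = FALSE)
    if (length(want)) {
      expect_equal(got$status, "exact")
      expect_setequal(vapply(lapply(got$candidates, sort), paste, "",
                             collapse = "+"),
                      vapply(want, paste, "", collapse = "+"))
    } else {
      expect_true(got$status != "exact")
    }
  }
})

test_that("modified fills appear only when no unmodified fill exists", {
  set.seed(42)
  n_mod_hits <- 0L
  for (i in 1:25) {
    # one modified residue (a mod on its own target) plus extra residues:
    # resolvable only in the modified pass unless a plain multiset
    # coincides
    row <- sample(nrow(MODS$mods), 1)
    delta <- residue_mass(MODS$mods$target[row], TAB) +
      MODS$mods$delta[row] +
      sum(sample(TAB$residues, sample(0:1, 1), replace = TRUE))
    got <- subset_fill(delta, TAB, MODS, tol = 0.005, max_candidates = 500L)
    expect_true(got$status %in% c("exact", "modified"))
    maxr <- max(1L, ceiling(delta / TAB$min_residue_mass))
    plain <- enumerate_fills(delta, 0.005, maxr, with_mods = FALSE)
    if (length(plain)) {
      expect_equal(got$status, "exact")
      expect_true(all(got$n_mods == 0))
    } else {
      expect_equal(got$status, "modified")
      expect_true(all(got$n_mods >= 1))
      n_mod_hits <- n_mod_hits + 1L
    }
  }
  expect_gt(n_mod_hits, 0)
})

test_that("candidates are ranked by size, modifications, then error", {
  f <- subset_fill(114.04293, TAB, MODS, tol = 0.02, max_candidates = 50L)
  sizes <- lengths(f$candidates)
  expect_true(all(diff(sizes) >= 0 | diff(f$n_mods) >= 0 |
                    diff(f$errors) >= -1e-12))
  expect_true(all(sizes[1] <= sizes))
})

test_that("find_gaps orders the boundaries of consecutive segments", {
  seqs <- c("G", "A", "S", "V", "K")
  pm <- cumsum(residue_mass(seqs, TAB))
  M <- pm[length(pm)]
  g <- build_graph(spectrum(pm[-length(pm)][-2], 1, M), TAB, tol = 0.001)
  p <- solve_lapp(g)
  gaps <- find_gaps(p, g)
  expect_equal(nrow(gaps), length(p$segments) - 1)
  if (nrow(gaps)) {
    expect_true(all(gaps$delta > 0))
    expect_equal(gaps$delta,
                 g$vertices$mass[gaps$right] - g$vertices$mass[gaps$left])
  }
  # single segment: no gaps
  expect_equal(nrow(find_gaps(solve_lapp(ga_graph()), ga_graph())), 0)
})

test_that("assemble emits mass-conserving results with bracketed gaps", {
  seqs <- c("G", "A", "S", "V", "K")
  pm <- cumsum(residue_mass(seqs, TAB))
  M <- pm[length(pm)]
  g <- build_graph(spectrum(pm[-length(pm)][-2], 1, M), TAB, tol = 0.001)
  p <- solve_lapp(g)
  gaps <- find_gaps(p, g)
  fills <- lapply(gaps$delta, subset_fill, table = TAB, mods = MODS,
                  tol = 0.01)
  res <- assemble(p, fills, g, TAB)
  expect_s3_class(res, "sequencing_result")
  expect_equal(sum(res$end - res$start), M, tolerance = 0.01 * nrow(res))
  expect_true(any(res$kind == "gap"))
  expect_true(grepl("\\[", attr(res, "string")))
  rec <- result_record(res)
  expect_equal(rec$sequence, attr(res, "string"))
  expect_length(rec$elements, nrow(res))
})

test_that("unresolved gaps are reported as explicit mass deltas", {
  # two one-edge segments separated by a 100 Da hole that no residue
  # multiset explains at this tolerance
  g <- toy_graph(4, list(c(1, 2), c(3, 4)))
  p <- solve_lapp(g)
  expect_length(p$segments, 2)
  gaps <- find_gaps(p, g)
  expect_equal(gaps$delta, 100)
  fills <- lapply(gaps$delta, subset_fill, table = TAB, mods = MODS,
                  tol = 0.001)
  expect_equal(fills[[1]]$status, "unresolved")
  res <- assemble(p, fills, g, TAB)
  expect_true(any(res$status == "unresolved"))
  expect_true(any(grepl("Δ100.000", res$call, fixed = TRUE)))
})
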