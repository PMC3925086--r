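test_that("random peptides respect length bounds and tryptic termini", {
  cfg <- sim_config(40, seed = 9)
  set.seed(cfg$seed)
  peps <- random_peptides(cfg, TAB)
  lens <- lengths(lapply(peps, `[[`, "sequence"))
  expect_true(all(lens >= 5 & lens <= 24))
  last <- vapply(peps, function(p) p$sequence[length(p$sequence)], "")
  expect_true(all(last %in% c("K", "R")))
  expect_length(random_peptides(sim_config(0, seed = 1)), 0)
})

test_that("simulation is reproducible under a fixed seed", {
  cfg <- sim_config(8, seed = 33, ns_ratio = 0.5, dropout = 0.1,
                    ptm_prob = 0.5)
  a <- simulate_spectra(cfg)
  b <- simulate_spectra(cfg)
  expect_identical(vapply(a$peptides, format, ""),
                   vapply(b$peptides, format, ""))
  expect_identical(lapply(a$spectra, function(s) s$peaks$mass),
                   lapply(b$spectra, function(s) s$peaks$mass))
})

test_that("ideal spectra hold every prefix mass and its complement", {
  p <- peptide("GASVK")
  s <- ideal_spectrum(p, TAB)
  pm <- cumsum(residue_mass(p$sequence, TAB))
  M <- pm[length(pm)]
  expect_equal(s$total_mass, M)
  expect_lte(nrow(s$peaks), 2 * (length(p$sequence) - 1))
  for (b in pm[-length(pm)]) {
    expect_true(any(abs(s$peaks$mass - b) < 1e-6))
    expect_true(any(abs(s$peaks$mass - (M - b)) < 1e-6))
  }
  for (m in s$peaks$mass) {
    expect_true(any(abs(s$peaks$mass - (M - m)) < 1e-6))
  }
})

test_that("grouped noise hits the requested count with residue spacings", {
  cfg <- sim_config(1, seed = 10, ns_ratio = 1.0)
  p <- peptide("GASVKLMER")
  s <- ideal_spectrum(p, TAB)
  set.seed(77)
  noisy <- add_noise(s, cfg, TAB)
  expect_equal(nrow(noisy$peaks), 2 * nrow(s$peaks))
  # ratio 0 leaves the spectrum untouched
  cfg0 <- sim_config(1, seed = 10, ns_ratio = 0)
  expect_identical(add_noise(s, cfg0, TAB)$peaks$mass, s$peaks$mass)
  # within a freshly generated group, consecutive spacings are residues
  set.seed(78)
  M <- 2000
  empty <- spectrum(1000, 1, M)
  cfg1 <- sim_config(1, seed = 1, ns_ratio = 3, noise_steps_min = 3L,
                     noise_steps_max = 3L)
  grp <- add_noise(empty, cfg1, TAB)
  extra <- setdiff(round(grp$peaks$mass, 6), round(1000, 6))
  extra <- sort(extra)
  diffs <- diff(extra)
  near_residue <- vapply(diffs, function(d) {
    length(is_residue_mass(d, TAB, tol = 1e-6)) > 0 || d > 200
  }, logical(1))
  expect_true(all(near_residue))
})

test_that("dropout thins real peaks and PTMs shift downstream masses", {
  p <- peptide("GASMK")
  s <- ideal_spectrum(p, TAB)
  cfg <- sim_config(1, seed = 1, dropout = 1)
  set.seed(5)
  expect_equal(nrow(drop_peaks(s, cfg)$peaks), 0)
  cfg0 <- sim_config(1, seed = 1, dropout = 0)
  expect_identical(drop_peaks(s, cfg0)$peaks$mass, s$peaks$mass)
  # a forced oxidation on M shifts all prefix masses past position 4
  cfgp <- sim_config(1, seed = 1, ptm_prob = 1)
  set.seed(6)
  pm <- apply_ptm(p, cfgp, MODS)
  expect_true(any(!is.na(pm$mods)))
  sm <- ideal_spectrum(pm, TAB, MODS)
  expect_equal(sm$total_mass, s$total_mass + 15.99491, tolerance = 1e-6)
})

test_that("accuracy scores positional calls, ambiguities and reversals", {
  p <- peptide("GAK")
  s <- ideal_spectrum(p, TAB)
  res <- sequence_spectrum(s, TAB, MODS, tol = 0.001,
                           complement_augment = FALSE)
  expect_equal(accuracy(res, p, TAB, MODS), 100)
  # the same result scored against the reversed truth is also perfect
  prev <- peptide(rev(p$sequence))
  expect_equal(accuracy(res, prev, TAB, MODS), 100)
  # a wrong peptide of the same mass scores below 100
  pw <- peptide("ATR")  # different composition
  expect_lt(accuracy(res, pw, TAB, MODS), 100)
})

test_that("mass-identical substitutions count as correct", {
  # truth GGK: the single-peak spectrum reads as [N] + K or similar
  p <- peptide("NK")
  s <- ideal_spectrum(p, TAB)
  res <- sequence_spectrum(s, TAB, MODS, tol = 0.001,
                           complement_augment = FALSE)
  # N vs G+G: scoring a GGK truth with an N call still credits both Gs
  pg <- peptide("GGK")
  expect_equal(accuracy(res, pg, TAB, MODS), 100 * 3 / 3)
})

test_that("noiseless pipeline sequences nearly all spectra perfectly", {
  b <- evaluate_batch(sim_config(60, seed = 14))
  expect_true(all(b$ok))
  expect_gte(mean(b$accuracy), 98.6)
  expect_gte(mean(b$accuracy == 100), 0.9)
  expect_gte(mean(b$n_segments == 1), 0.9)
})

test_that("benchmark summaries cover the requested noise levels", {
  out <- benchmark_sweep(4, seed = 3, ns_levels = c(0, 0.5))
  expect_equal(out$ns, c(0, 0.5))
  expect_true(all(out$n == 4))
  expect_true(all(out$mean_accuracy >= 0 & out$mean_accuracy <= 100))
  expect_true(all(abs(out$pw_lt5 + out$pw_eq5 + out$pw_gt5 - 100) < 1e-6))
})
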