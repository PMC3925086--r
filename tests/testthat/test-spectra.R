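write_test_mgf <- function(path, blocks) {
  lines <- character()
  for (b in blocks) {
    lines <- c(lines, "BEGIN IONS", b$headers,
               sprintf("%.5f %.2f", b$mz, b$intensity), "END IONS")
  }
  writeLines(lines, path)
  path
}

test_that("MGF parsing preserves peaks and computes the neutral mass", {
  f <- withr::local_tempfile(fileext = ".mgf")
  write_test_mgf(f, list(list(
    headers = c("TITLE=spec1", "PEPMASS=500.0", "CHARGE=2+"),
    mz = c(100.1, 200.2, 300.3), intensity = c(10, 20, 5))))
  sp <- read_mgf(f)
  expect_length(sp, 1)
  expect_equal(nrow(sp[[1]]$peaks), 3)
  # neutral peptide mass 2*500 - 2*proton; abstract M subtracts one water
  expect_equal(sp[[1]]$total_mass + pdnovo:::WATER_MASS,
               2 * 500.0 - 2 * pdnovo:::PROTON_MASS, tolerance = 1e-9)
  expect_equal(sp[[1]]$metadata$title, "spec1")
})

test_that("MGF blocks without PEPMASS are skipped; empty file gives none", {
  f <- withr::local_tempfile(fileext = ".mgf")
  write_test_mgf(f, list(
    list(headers = "TITLE=broken", mz = 100, intensity = 1),
    list(headers = c("TITLE=good", "PEPMASS=400", "CHARGE=1+"),
         mz = c(150, 250), intensity = c(1, 1))))
  expect_warning(sp <- read_mgf(f), "PEPMASS")
  expect_length(sp, 1)
  expect_equal(sp[[1]]$metadata$title, "good")
  f2 <- withr::local_tempfile(fileext = ".mgf")
  writeLines(character(), f2)
  expect_length(read_mgf(f2), 0)
})

test_that("peak lists round-trip and reject malformed lines", {
  f <- withr::local_tempfile(fileext = ".tsv")
  s <- abstract_spectrum(c(57.02146, 71.03711), 128.05857)
  write_peaklist(s, f)
  s2 <- read_peaklist(f, 128.05857)
  expect_equal(s2$peaks$mass, s$peaks$mass, tolerance = 1e-5)
  expect_false(is.unsorted(s2$peaks$mass))
  writeLines(c("57.0 1.0", "oops 2.0"), f)
  expect_error(read_peaklist(f, 128.05857), "line 2")
})

test_that("preprocess filters weak peaks and closes complements", {
  M <- 500
  s <- spectrum(c(100, 150, 380), c(100, 5, 50), M)
  out <- preprocess(s, tol = 0.3)
  # intensity 5 < 0.1 * 100 removed; complements of 100 and 380 created
  expect_false(any(abs(out$peaks$mass - 150) < 0.3))
  expect_true(any(abs(out$peaks$mass - 400) < 0.3))
  expect_true(any(abs(out$peaks$mass - 120) < 0.3))
  for (m in out$peaks$mass) {
    expect_true(any(abs(out$peaks$mass - (M - m)) <= 0.3))
  }
  expect_true(any(out$peaks$synthetic))
  # idempotence
  out2 <- preprocess(out, tol = 0.3)
  expect_equal(out2$peaks$mass, out$peaks$mass, tolerance = 1e-9)
})

test_that("preprocess removes isotope peaks below a stronger peak", {
  s <- spectrum(c(200, 201.00335, 300), c(100, 40, 80), 500)
  out <- preprocess(s, tol = 0.1)
  expect_false(any(abs(out$peaks$mass - 201.00335) < 0.05))
  # equal-intensity twin peaks are not isotope-filtered
  s2 <- spectrum(c(200, 201.00335), c(50, 50), 500)
  out2 <- preprocess(s2, tol = 0.1)
  expect_true(any(abs(out2$peaks$mass - 201.00335) < 0.05))
})

test_that("calibrate_ions maps b and y hypotheses into (0, M)", {
  # b1 ion of Gly observed at 58.02874 -> abstract 57.02146
  M <- 128.05857
  raw <- structure(list(
    peaks = data.frame(mass = 58.02874, intensity = 1, synthetic = FALSE),
    total_mass = M, metadata = list()), class = "spectrum")
  cal <- calibrate_ions(raw, merge_tol = 0.01)
  expect_true(any(abs(cal$peaks$mass - 57.02146) < 1e-4))
  # y1 ion of the C-terminal residue maps to M - residue mass
  yobs <- 57.02146 + pdnovo:::WATER_MASS + pdnovo:::PROTON_MASS
  raw$peaks$mass <- yobs
  cal2 <- calibrate_ions(raw, merge_tol = 0.01)
  expect_true(any(abs(cal2$peaks$mass - (M - 57.02146)) < 1e-4))
  # candidates outside (0, M) are dropped
  raw$peaks$mass <- M + 50
  cal3 <- calibrate_ions(raw, merge_tol = 0.01)
  expect_true(all(cal3$peaks$mass > 0 & cal3$peaks$mass < M))
})

test_that("spectra written as MGF read back with the same total mass", {
  p <- peptide("GASK")
  s <- ideal_spectrum(p, TAB)
  s$metadata$title <- "t"
  f <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(list(s), f)
  back <- read_mgf(f)
  expect_equal(back[[1]]$total_mass, s$total_mass, tolerance = 1e-6)
  expect_equal(nrow(back[[1]]$peaks), nrow(s$peaks))
})
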