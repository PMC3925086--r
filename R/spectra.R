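## Spectrum I/O and preprocessing.
##
## A spectrum holds peaks in abstract coordinates: each peak mass is a
## residue prefix-sum candidate in (0, M) where M is the peptide's residue
## total. MGF input is observed singly charged ion m/z and is bridged into
## the abstract system by calibrate_ions().

#' Spectrum constructor
#'
#' @param mass numeric vector of peak masses (abstract coordinates, Da).
#' @param intensity numeric vector of intensities (>= 0); recycled if scalar.
#' @param total_mass total residue mass M of the peptide (Da).
#' @param synthetic logical vector flagging peaks created by complement
#'   augmentation rather than observed.
#' @param metadata list of per-spectrum metadata (title, charge, pepmass...).
#' @param merge_tol peaks closer than this are merged (max intensity kept).
#' @return object of class \code{spectrum}: list with a \code{peaks} data
#'   frame (mass, intensity, synthetic; sorted, deduplicated), numeric
#'   \code{total_mass} and \code{metadata}.
#' @export
spectrum <- function(mass, intensity = 1, total_mass,
                     synthetic = FALSE, metadata = list(),
                     merge_tol = 1e-6) {
  stopifnot(is.numeric(mass), total_mass > 0)
  intensity <- rep_len(intensity, length(mass))
  synthetic <- rep_len(synthetic, length(mass))
  keep <- mass > 0 & mass < total_mass
  mass <- mass[keep]; intensity <- intensity[keep]; synthetic <- synthetic[keep]
  o <- order(mass, -intensity)
  mass <- mass[o]; intensity <- intensity[o]; synthetic <- synthetic[o]
  if (length(mass) > 1L) {
    grp <- cumsum(c(TRUE, diff(mass) > merge_tol))
    first <- !duplicated(grp)
    # keep max intensity within each merge group (sorted -intensity above)
    mass <- mass[first]; intensity <- intensity[first]
    synthetic <- synthetic[first]
  }
  structure(
    list(peaks = data.frame(mass = mass, intensity = intensity,
                            synthetic = synthetic),
         total_mass = total_mass, metadata = metadata),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat("<spectrum> ", nrow(x$peaks), " peaks, M = ",
      format(x$total_mass), " Da", sep = "")
  if (!is.null(x$metadata$title)) cat(" [", x$metadata$title, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Read spectra from a Mascot Generic Format (MGF) file
#'
#' Parses BEGIN IONS / END IONS blocks with PEPMASS, CHARGE and TITLE
#' headers. The neutral peptide mass is computed as
#' \code{pepmass * z - z * proton} and the abstract total mass as the neutral
#' mass minus one water. Peak m/z values are stored as read; use
#' \code{\link{calibrate_ions}} to map them into abstract coordinates.
#'
#' @param path path to an MGF file.
#' @param default_charge charge assumed when a block has no CHARGE line.
#' @return list of raw \code{spectrum} objects (possibly empty). Blocks
#'   without PEPMASS are skipped with a warning.
#' @export
read_mgf <- function(path, default_charge = 1L) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (length(starts) != length(ends)) stop("unbalanced BEGIN/END IONS in ", path)
  out <- list()
  for (b in seq_along(starts)) {
    block <- lines[seq(starts[b] + 1L, ends[b] - 1L)]
    hdr <- grep("=", block, fixed = TRUE, value = TRUE)
    ion_lines <- grep("^[0-9]", trimws(block), value = TRUE)
    kv <- strsplit(hdr, "=", fixed = TRUE)
    keys <- toupper(vapply(kv, `[`, "", 1L))
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
    if (!"PEPMASS" %in% keys) {
      warning("MGF block ", b, " has no PEPMASS; skipped")
      next
    }
    pepmass <- as.numeric(strsplit(trimws(vals[match("PEPMASS", keys)]),
                                   "[[:space:]]+")[[1]][1])
    z <- default_charge
    if ("CHARGE" %in% keys) {
      z <- as.integer(gsub("[^0-9]", "", vals[match("CHARGE", keys)]))
      if (is.na(z) || z < 1L) z <- default_charge
    }
    title <- if ("TITLE" %in% keys) vals[match("TITLE", keys)] else NA_character_
    neutral <- pepmass * z - z * PROTON_MASS
    m_abstract <- neutral - WATER_MASS
    pk <- do.call(rbind, lapply(strsplit(ion_lines, "[[:space:]]+"),
                                function(x) as.numeric(x[1:2])))
    if (is.null(pk)) pk <- matrix(numeric(), ncol = 2)
    pk[is.na(pk[, 2]), 2] <- 1
    sp <- structure(
      list(peaks = data.frame(mass = pk[, 1], intensity = pk[, 2],
                              synthetic = rep(FALSE, nrow(pk))),
           total_mass = m_abstract,
           metadata = list(title = title, charge = z, pepmass = pepmass,
                           calibrated = FALSE)),
      class = "spectrum")
    o <- order(sp$peaks$mass)
    sp$peaks <- sp$peaks[o, , drop = FALSE]
    rownames(sp$peaks) <- NULL
    out[[length(out) + 1L]] <- sp
  }
  out
}

#' Write spectra to an MGF file
#'
#' Abstract-coordinate spectra are written as singly charged b ions
#' (m/z = mass + proton) with PEPMASS = (M + water + proton) / 1.
#'
#' @param spectra list of \code{spectrum} objects in abstract coordinates.
#' @param path output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    title <- s$metadata$title
    if (is.null(title) || is.na(title)) title <- paste0("spectrum_", i)
    pepmass <- s$total_mass + WATER_MASS + PROTON_MASS
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", title),
                 paste0("PEPMASS=", format(pepmass, digits = 12)),
                 "CHARGE=1+"), con)
    mz <- s$peaks$mass + PROTON_MASS
    writeLines(sprintf("%.5f %.4f", mz, s$peaks$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read a two-column peak list already in abstract coordinates
#'
#' @param path whitespace- or tab-separated text with columns mass and
#'   intensity; lines starting with '#' are ignored.
#' @param total_mass abstract total mass M (Da).
#' @return a \code{spectrum}.
#' @export
read_peaklist <- function(path, total_mass) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]; lineno <- which(keep)
  if (!length(lines)) {
    return(spectrum(numeric(), numeric(), total_mass))
  }
  parts <- strsplit(lines, "[[:space:]]+")
  mass <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  inten <- suppressWarnings(as.numeric(vapply(parts, function(x) {
    if (length(x) >= 2L) x[2L] else "1"
  }, "")))
  bad <- which(is.na(mass) | is.na(inten))
  if (length(bad)) {
    stop("non-numeric peak entry at line ", lineno[bad[1]], " of ", path)
  }
  spectrum(mass, inten, total_mass)
}

#' Write a spectrum as a two-column peak list
#' @param s a \code{spectrum}.
#' @param path output path. A header comment records the total mass.
#' @export
write_peaklist <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# total_mass %.5f", s$total_mass), con)
  writeLines(sprintf("%.5f\t%.4f", s$peaks$mass, s$peaks$intensity), con)
  invisible(path)
}

#' Map observed ion m/z values into abstract coordinates
#'
#' Each observed peak at m/z \code{m} (assumed singly charged) produces two
#' candidate abstract masses: \code{m - proton} under the b-ion hypothesis
#' and \code{M - (m - proton - water)} under the y-ion hypothesis. Candidates
#' outside (0, M) are dropped and near-duplicates merged keeping the larger
#' intensity.
#'
#' @param s raw \code{spectrum} (as from \code{\link{read_mgf}}).
#' @param merge_tol merge tolerance in Da.
#' @return calibrated \code{spectrum} in abstract coordinates.
#' @export
calibrate_ions <- function(s, merge_tol = 0.3) {
  M <- s$total_mass
  b_cand <- s$peaks$mass - PROTON_MASS
  y_cand <- M - (s$peaks$mass - PROTON_MASS - WATER_MASS)
  mass <- c(b_cand, y_cand)
  inten <- rep(s$peaks$intensity, 2L)
  md <- s$metadata
  md$calibrated <- TRUE
  spectrum(mass, inten, M, synthetic = FALSE, metadata = md,
           merge_tol = merge_tol)
}

#' Preprocess a spectrum
#'
#' Three steps: (1) drop peaks with intensity below
#' \code{min_intensity_frac} of the maximum intensity; (2) drop isotope
#' peaks, i.e. any peak sitting 1.00335 Da (within \code{tol}) above a peak
#' of strictly greater intensity; (3) complement augmentation: for every
#' surviving peak at mass m without a partner within \code{tol} of M - m, add
#' a synthetic peak at M - m carrying the same intensity. The result is
#' complement-closed and the operation is idempotent.
#'
#' @param s a \code{spectrum} in abstract coordinates.
#' @param min_intensity_frac intensity threshold as a fraction of the max.
#' @param tol mass tolerance (Da) for isotope spacing and complement pairing.
#' @param merge_tol tolerance below which peaks are merged; defaults to
#'   \code{tol}.
#' @param isotope_spacing C13-C12 mass difference (Da).
#' @param add_complements create synthetic complementary ions (step 3).
#'   The default TRUE matches the preprocessing used for experimental
#'   spectra; simulated benchmark spectra are complement-complete for
#'   their signal peaks by construction and are processed without it, so
#'   that the injected noise/signal ratio is the ratio seen by the graph.
#' @return preprocessed \code{spectrum}.
#' @export
preprocess <- function(s, min_intensity_frac = 0.1, tol = 0.3,
                       merge_tol = tol, isotope_spacing = 1.00335,
                       add_complements = TRUE) {
  pk <- s$peaks
  M <- s$total_mass
  if (nrow(pk)) {
    pk <- pk[pk$intensity >= min_intensity_frac * max(pk$intensity), ,
             drop = FALSE]
  }
  if (nrow(pk) > 1L) {
    drop <- logical(nrow(pk))
    for (i in seq_len(nrow(pk))) {
      gap <- pk$mass[i] - pk$mass
      iso <- which(abs(gap - isotope_spacing) <= tol &
                     pk$intensity > pk$intensity[i])
      if (length(iso)) drop[i] <- TRUE
    }
    pk <- pk[!drop, , drop = FALSE]
  }
  if (nrow(pk) && add_complements) {
    need <- vapply(seq_len(nrow(pk)), function(i) {
      comp <- M - pk$mass[i]
      !any(abs(pk$mass - comp) <= tol)
    }, logical(1))
    if (any(need)) {
      pk <- rbind(pk, data.frame(mass = M - pk$mass[need],
                                 intensity = pk$intensity[need],
                                 synthetic = TRUE))
    }
  }
  spectrum(pk$mass, pk$intensity, M, synthetic = pk$synthetic,
           metadata = s$metadata, merge_tol = merge_tol)
}
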