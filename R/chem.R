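## Residue and modification mass bookkeeping.
##
## All sequencing code works in an "abstract" mass coordinate system: the
## source sits at mass 0, the sink at mass M = sum of residue masses, and
## complementary fragment peaks sum exactly to M. Conversion from observed
## singly charged ion m/z values lives in spectra.R.

#' Monoisotopic mass constants (Da)
#'
#' Proton and water monoisotopic masses used when converting observed ion
#' m/z values to the abstract residue-sum coordinate system.
#' @keywords internal
#' @name mass-constants
NULL

PROTON_MASS <- 1.00727646688
WATER_MASS <- 18.0105646863

.default_residues <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' Residue mass table
#'
#' Builds the table of monoisotopic residue masses used throughout the
#' sequencer. The default contains the 20 standard amino acids; isoleucine
#' and leucine share a residue mass and are reported as the joint call
#' \code{"L/I"} by downstream code.
#'
#' Two near-coincidences of the standard table are recorded in the
#' \code{coincidences} attribute: Gly+Gly differs from Asn by 1e-5 Da and
#' Gly+Ala from Gln by 1e-5 Da. Within any realistic tolerance these are
#' indistinguishable by mass alone.
#'
#' @param residues named numeric vector of residue masses (Da). Names are
#'   one-letter codes.
#' @return an object of class \code{residue_table} with elements
#'   \code{residues} (named numeric) and \code{min_residue_mass}.
#' @examples
#' tab <- residue_table()
#' tab$min_residue_mass  # 57.02146, glycine
#' @export
residue_table <- function(residues = .default_residues) {
  if (is.null(names(residues)) || any(!nzchar(names(residues)))) {
    stop("residue masses must be named with one-letter codes")
  }
  if (any(residues <= 0)) stop("residue masses must be strictly positive")
  structure(
    list(
      residues = residues,
      min_residue_mass = min(residues),
      coincidences = list(c("N", "G", "G"), c("Q", "G", "A"))
    ),
    class = "residue_table"
  )
}

#' @export
print.residue_table <- function(x, ...) {
  cat("<residue_table> ", length(x$residues), " residues, min mass ",
      format(x$min_residue_mass), " Da\n", sep = "")
  invisible(x)
}

.default_mods <- data.frame(
  target = c("M", "S", "T", "Y", "N", "Q"),
  delta = c(15.99491, 79.96633, 79.96633, 79.96633, 0.98402, 0.98402),
  label = c("ox", "ph:S", "ph:T", "ph:Y", "deam:N", "deam:Q"),
  stringsAsFactors = FALSE
)

#' Modification table
#'
#' Table of residue-specific mass shifts considered when a mass gap cannot be
#' explained by unmodified residues alone. Defaults: methionine oxidation
#' (+15.99491), phosphorylation of S/T/Y (+79.96633) and deamidation of N/Q
#' (+0.98402).
#'
#' @param mods data frame with columns \code{target} (residue code),
#'   \code{delta} (Da, nonzero) and \code{label} (unique identifier).
#' @return object of class \code{mod_table}.
#' @export
mod_table <- function(mods = .default_mods) {
  stopifnot(is.data.frame(mods),
            all(c("target", "delta", "label") %in% names(mods)))
  if (any(mods$delta == 0)) stop("modification deltas must be nonzero")
  if (anyDuplicated(mods$label)) stop("modification labels must be unique")
  structure(list(mods = mods), class = "mod_table")
}

#' @export
print.mod_table <- function(x, ...) {
  cat("<mod_table> ", nrow(x$mods), " modifications\n", sep = "")
  invisible(x)
}

#' Peptide constructor
#'
#' @param sequence character vector of one-letter residue codes, or a single
#'   string that is split into codes.
#' @param mods optional character vector of modification labels, one per
#'   position (NA where unmodified).
#' @param table residue table used to validate the codes.
#' @return object of class \code{peptide}: list with \code{sequence} and
#'   \code{mods}.
#' @export
peptide <- function(sequence, mods = NULL, table = residue_table()) {
  if (length(sequence) == 1L && nchar(sequence) > 1L) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  if (length(sequence) < 1L) stop("peptide must contain at least one residue")
  unknown <- setdiff(sequence, names(table$residues))
  if (length(unknown)) {
    stop("unknown residue code(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(mods)) mods <- rep(NA_character_, length(sequence))
  if (length(mods) != length(sequence)) {
    stop("mods must have one entry per residue position")
  }
  structure(list(sequence = sequence, mods = mods), class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  s <- x$sequence
  marked <- ifelse(is.na(x$mods), s, paste0(s, "*"))
  cat("<peptide> ", paste(marked, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' @export
format.peptide <- function(x, ...) paste(x$sequence, collapse = "")

#' Look up a residue mass
#'
#' @param code one-letter residue code.
#' @param table residue table.
#' @return monoisotopic residue mass in Da.
#' @export
residue_mass <- function(code, table = residue_table()) {
  m <- table$residues[code]
  if (anyNA(m)) {
    stop("unknown residue code(s): ",
         paste(code[is.na(m)], collapse = ", "))
  }
  unname(m)
}

#' Residue-sum mass of a peptide
#'
#' Sum of residue masses plus any modification deltas; this is the abstract
#' total mass M of the peptide (the neutral peptide mass minus one water).
#'
#' @param p a \code{peptide}.
#' @param table residue table.
#' @param mods modification table used to resolve modification labels.
#' @return mass in Da.
#' @export
peptide_residue_sum <- function(p, table = residue_table(),
                                mods = mod_table()) {
  stopifnot(inherits(p, "peptide"))
  total <- sum(residue_mass(p$sequence, table))
  lab <- p$mods[!is.na(p$mods)]
  if (length(lab)) {
    idx <- match(lab, mods$mods$label)
    if (anyNA(idx)) {
      stop("unknown modification label(s): ",
           paste(lab[is.na(idx)], collapse = ", "))
    }
    total <- total + sum(mods$mods$delta[idx])
  }
  total
}

#' Per-position masses of a peptide
#'
#' Residue mass at each position including any modification delta.
#' @inheritParams peptide_residue_sum
#' @return numeric vector, one mass per residue position.
#' @keywords internal
peptide_position_masses <- function(p, table = residue_table(),
                                    mods = mod_table()) {
  m <- residue_mass(p$sequence, table)
  has <- !is.na(p$mods)
  if (any(has)) {
    idx <- match(p$mods[has], mods$mods$label)
    if (anyNA(idx)) stop("unknown modification label")
    m[has] <- m[has] + mods$mods$delta[idx]
  }
  m
}

#' Residues matching a mass difference
#'
#' All residue codes whose mass lies within \code{tol} of \code{delta}; the
#' empty character vector when none match. A directed spectrum-graph edge is
#' created exactly when this set is nonempty for the peak mass difference.
#'
#' @param delta mass difference in Da.
#' @param table residue table.
#' @param tol nonnegative tolerance in Da.
#' @return character vector of residue codes, ordered by |mass - delta|.
#' @export
is_residue_mass <- function(delta, table = residue_table(), tol = 0.02) {
  stopifnot(tol >= 0)
  err <- abs(table$residues - delta)
  hit <- which(err <= tol)
  names(table$residues)[hit[order(err[hit], names(table$residues)[hit])]]
}

#' Detect sum coincidences in a residue table
#'
#' Enumerates multisets of two or more residues whose summed mass lies within
#' \code{tol} of a single residue mass. For the standard table at 0.01 Da the
#' only hits are the recorded Asn = Gly+Gly and Gln = Gly+Ala coincidences;
#' the sequencing model otherwise relies on no residue equalling a sum of
#' others (this underpins the rule that every directed edge between selected
#' vertices belongs to the path).
#'
#' @param table residue table.
#' @param tol tolerance in Da.
#' @param max_terms largest multiset size to consider.
#' @return data frame with columns \code{residue} and \code{sum_of}.
#' @export
residue_sum_coincidences <- function(table = residue_table(), tol = 0.01,
                                     max_terms = 3L) {
  res <- table$residues
  # collapse duplicate masses (I/L) to one representative for sums
  codes <- names(res)
  out <- list()
  # enumerate multisets of size 2..max_terms by recursion over sorted codes
  enum <- function(start, left, acc_mass, acc_codes) {
    if (length(acc_codes) >= 2L) {
      tgt <- setdiff(codes, acc_codes)
      hit <- tgt[abs(res[tgt] - acc_mass) <= tol]
      for (h in hit) {
        out[[length(out) + 1L]] <<- data.frame(
          residue = h, sum_of = paste(sort(acc_codes), collapse = "+"),
          stringsAsFactors = FALSE)
      }
    }
    if (left == 0L) return(invisible())
    for (i in seq(start, length(codes))) {
      if (acc_mass + res[codes[i]] > max(res) + tol) next
      enum(i, left - 1L, acc_mass + res[codes[i]],
           c(acc_codes, codes[i]))
    }
  }
  enum(1L, max_terms, 0, character())
  if (!length(out)) {
    return(data.frame(residue = character(), sum_of = character(),
                      stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, out))
}

#' Load residue and modification tables from a YAML config
#'
#' The file may contain a \code{residues} mapping (code: mass) and a
#' \code{modifications} list of records with \code{target}, \code{delta},
#' \code{label}. Missing sections fall back to the built-in defaults.
#'
#' @param path path to a YAML file.
#' @return list with elements \code{table} and \code{mods}.
#' @export
load_mass_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  tab <- if (!is.null(cfg$residues)) {
    residue_table(unlist(cfg$residues))
  } else {
    residue_table()
  }
  mods <- if (!is.null(cfg$modifications)) {
    md <- do.call(rbind, lapply(cfg$modifications, function(m) {
      data.frame(target = m$target, delta = as.numeric(m$delta),
                 label = m$label, stringsAsFactors = FALSE)
    }))
    mod_table(md)
  } else {
    mod_table()
  }
  list(table = tab, mods = mods)
}
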