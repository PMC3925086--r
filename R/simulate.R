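## Spectrum simulator and evaluation.
##
## Emulates the benchmark protocol: random tryptic-like peptides (uniform
## residues, C-terminal K/R, lengths 5-24), ideal spectra containing every
## prefix mass and its complement, grouped noise peaks whose within-group
## spacings are residue masses, optional peak dropout and a single PTM.
## The noise/signal ratio N/S is the number of injected noise peaks divided
## by the number of real peaks.

#' Simulation configuration
#'
#' @param n_peptides number of peptides to simulate.
#' @param seed random seed (mandatory; all randomness flows from it).
#' @param min_length,max_length peptide length bounds (inclusive).
#' @param ns_ratio noise/signal ratio (>= 0).
#' @param noise_steps_min,noise_steps_max residue-mass steps per noise group
#'   (a group of k steps contributes k+1 peaks).
#' @param dropout independent probability that a real peak is removed.
#' @param ptm_prob probability that a peptide carries one modified residue.
#' @param tol mass tolerance used throughout the simulated pipeline.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_peptides, seed, min_length = 5L, max_length = 24L,
                       ns_ratio = 0, noise_steps_min = 1L,
                       noise_steps_max = 3L, dropout = 0, ptm_prob = 0,
                       tol = 0.001) {
  stopifnot(n_peptides >= 0, min_length >= 1, max_length >= min_length,
            ns_ratio >= 0, dropout >= 0, dropout <= 1,
            ptm_prob >= 0, ptm_prob <= 1, tol > 0)
  if (missing(seed) || is.null(seed)) stop("sim_config requires a seed")
  structure(as.list(environment()), class = "sim_config")
}

#' Random tryptic-like peptides
#'
#' Lengths uniform within the configured bounds, residues uniform over the
#' table, last residue K or R (tryptic emulation). Uses the current RNG
#' state; drive through \code{\link{simulate_spectra}} for seeded runs.
#'
#' @param cfg a \code{sim_config}.
#' @param table residue table.
#' @return list of \code{peptide} objects.
#' @export
random_peptides <- function(cfg, table = residue_table()) {
  codes <- names(table$residues)
  term <- intersect(c("K", "R"), codes)
  if (!length(term)) term <- codes
  lapply(seq_len(cfg$n_peptides), function(i) {
    len <- sample(cfg$min_length:cfg$max_length, 1L)
    seqs <- c(sample(codes, len - 1L, replace = TRUE),
              sample(term, 1L))
    peptide(seqs, table = table)
  })
}

#' Ideal spectrum of a peptide
#'
#' Peaks at every proper prefix residue sum and at its complement M - prefix
#' (the two fragment ladders), unit intensities, abstract coordinates.
#'
#' @param p a \code{peptide}.
#' @param table residue table.
#' @param mods modification table (for modified positions).
#' @return a \code{spectrum} with at most 2(n-1) peaks.
#' @export
ideal_spectrum <- function(p, table = residue_table(), mods = mod_table()) {
  pm <- peptide_position_masses(p, table, mods)
  M <- sum(pm)
  n <- length(pm)
  if (n == 1L) return(spectrum(numeric(), numeric(), M))
  prefix <- cumsum(pm)[-n]
  spectrum(c(prefix, M - prefix), 1, M, merge_tol = 1e-6)
}

#' Add grouped noise peaks
#'
#' Injects \code{round(ns_ratio * n_real)} noise peaks. Peaks are created
#' in groups: each group starts at a uniform random mass in (0, M) and
#' extends upward by 1-3 random residue-mass steps (clipped to the open
#' interval), so within-group spacings look like residue gaps, as in
#' realistic contaminating fragment series.
#'
#' @param s a \code{spectrum}.
#' @param cfg a \code{sim_config} (fields ns_ratio, noise_steps_*).
#' @param table residue table for the step masses.
#' @return spectrum with noise peaks merged in.
#' @export
add_noise <- function(s, cfg, table = residue_table()) {
  n_real <- nrow(s$peaks)
  target <- round(cfg$ns_ratio * n_real)
  if (target <= 0L) return(s)
  M <- s$total_mass
  res <- unname(table$residues)
  noise <- numeric(0)
  while (length(noise) < target) {
    start <- stats::runif(1, 0, M)
    k <- sample(cfg$noise_steps_min:cfg$noise_steps_max, 1L)
    grp <- start + c(0, cumsum(sample(res, k, replace = TRUE)))
    grp <- grp[grp > 0 & grp < M]
    noise <- c(noise, grp)
  }
  noise <- noise[seq_len(target)]
  spectrum(c(s$peaks$mass, noise),
           c(s$peaks$intensity, rep(1, length(noise))),
           M, synthetic = c(s$peaks$synthetic, rep(FALSE, length(noise))),
           metadata = s$metadata, merge_tol = 1e-6)
}

#' Random peak dropout
#'
#' Removes each real peak independently with probability \code{cfg$dropout},
#' emulating missing fragmentation.
#'
#' @param s a \code{spectrum}.
#' @param cfg a \code{sim_config}.
#' @return thinned spectrum.
#' @export
drop_peaks <- function(s, cfg) {
  if (cfg$dropout <= 0 || !nrow(s$peaks)) return(s)
  keep <- stats::runif(nrow(s$peaks)) >= cfg$dropout
  spectrum(s$peaks$mass[keep], s$peaks$intensity[keep], s$total_mass,
           synthetic = s$peaks$synthetic[keep], metadata = s$metadata,
           merge_tol = 1e-6)
}

#' Apply one random modification to a peptide
#'
#' With probability \code{cfg$ptm_prob}, one modifiable position (a residue
#' listed as a target in the modification table) is modified; prefix masses
#' downstream of it shift by the modification delta.
#'
#' @param p a \code{peptide}.
#' @param cfg a \code{sim_config}.
#' @param mods modification table.
#' @return possibly modified \code{peptide}.
#' @export
apply_ptm <- function(p, cfg, mods = mod_table()) {
  if (cfg$ptm_prob <= 0 || stats::runif(1) >= cfg$ptm_prob) return(p)
  elig <- which(p$sequence %in% mods$mods$target & is.na(p$mods))
  if (!length(elig)) return(p)
  pos <- if (length(elig) == 1L) elig else sample(elig, 1L)
  cand <- which(mods$mods$target == p$sequence[pos])
  lab <- mods$mods$label[if (length(cand) == 1L) cand else sample(cand, 1L)]
  p$mods[pos] <- lab
  p
}

#' Simulate a seeded batch of spectra
#'
#' Generates peptides and their (possibly modified, noisy, thinned) spectra
#' reproducibly from \code{cfg$seed}.
#'
#' @param cfg a \code{sim_config}.
#' @param table residue table.
#' @param mods modification table.
#' @return list with \code{peptides} and \code{spectra} (parallel lists).
#' @export
simulate_spectra <- function(cfg, table = residue_table(),
                             mods = mod_table()) {
  set.seed(cfg$seed)
  peps <- random_peptides(cfg, table)
  peps <- lapply(peps, apply_ptm, cfg = cfg, mods = mods)
  spectra <- lapply(peps, function(p) {
    s <- ideal_spectrum(p, table, mods)
    s <- drop_peaks(s, cfg)
    add_noise(s, cfg, table)
  })
  list(peptides = peps, spectra = spectra)
}

## --- sequencing pipeline --------------------------------------------------

#' Sequence one spectrum end to end
#'
#' preprocess -> extended spectrum graph -> path decomposition -> longest
#' antisymmetric partial path -> subset-sum gap filling.
#'
#' @param s a \code{spectrum} in abstract coordinates.
#' @param table residue table.
#' @param mods modification table for gap filling.
#' @param tol mass tolerance (Da).
#' @param strategy decomposition strategy.
#' @param preprocessed set TRUE when \code{s} has already been preprocessed.
#' @param complement_augment create synthetic complementary ions during
#'   preprocessing (see \code{\link{preprocess}}); the simulated benchmark
#'   turns this off because simulated spectra are complement-complete by
#'   construction.
#' @return a \code{sequencing_result}; attributes \code{width} (achieved
#'   decomposition width before source/sink augmentation), \code{path} (the
#'   \code{antisym_path}) and \code{graph}.
#' @export
sequence_spectrum <- function(s, table = residue_table(),
                              mods = mod_table(), tol = 0.3,
                              strategy = "greedy", preprocessed = FALSE,
                              complement_augment = TRUE) {
  if (!preprocessed) {
    s <- preprocess(s, tol = tol, add_complements = complement_augment)
  }
  g <- build_graph(s, table, tol = tol)
  # achieved width of the plain decomposition (the descriptive statistic);
  # the solver builds its own span-aware decomposition internally
  width <- decompose(g, strategy = strategy)$width
  p <- solve_lapp(g)
  gaps <- find_gaps(p, g)
  fills <- lapply(gaps$delta, subset_fill, table = table, mods = mods,
                  tol = tol)
  res <- assemble(p, fills, g, table)
  attr(res, "width") <- width
  attr(res, "path") <- p
  attr(res, "graph") <- g
  res
}

## --- accuracy -------------------------------------------------------------

# masses of predicted codes; "X+label" means residue X plus that mod delta
codes_to_masses <- function(codes, table, mods) {
  vapply(codes, function(cd) {
    if (grepl("+", cd, fixed = TRUE)) {
      parts <- strsplit(cd, "+", fixed = TRUE)[[1]]
      residue_mass(parts[1], table) +
        mods$mods$delta[match(paste(parts[-1], collapse = "+"),
                              mods$mods$label)]
    } else {
      residue_mass(cd, table)
    }
  }, numeric(1))
}

# greedy multiset matching credit between predicted and truth masses;
# single-vs-pair substitutions cover the N=G+G / Q=G+A coincidences
multiset_credit <- function(pred, truth, tol) {
  used_p <- logical(length(pred)); used_t <- logical(length(truth))
  credit <- 0L
  for (i in seq_along(truth)) {
    j <- which(!used_p & abs(pred - truth[i]) <= tol)
    if (length(j)) {
      used_p[j[1]] <- TRUE; used_t[i] <- TRUE
      credit <- credit + 1L
    }
  }
  # predicted single explaining two truth residues
  for (j in which(!used_p)) {
    ti <- which(!used_t)
    if (length(ti) >= 2L) {
      prs <- utils::combn(ti, 2L)
      hit <- which(abs(pred[j] - colSums(matrix(truth[prs], nrow = 2))) <=
                     2 * tol)
      if (length(hit)) {
        pair <- prs[, hit[1]]
        used_t[pair] <- TRUE; used_p[j] <- TRUE
        credit <- credit + 2L
      }
    }
  }
  # two predicted residues explaining one truth residue
  pj <- which(!used_p)
  if (length(pj) >= 2L) {
    prs <- utils::combn(pj, 2L)
    for (i in which(!used_t)) {
      if (is.null(dim(prs))) break
      sums <- colSums(matrix(pred[prs], nrow = 2))
      hit <- which(abs(sums - truth[i]) <= 2 * tol &
                     !used_p[prs[1, ]] & !used_p[prs[2, ]])
      if (length(hit)) {
        used_p[prs[, hit[1]]] <- TRUE; used_t[i] <- TRUE
        credit <- credit + 1L
      }
    }
  }
  credit
}

score_orientation <- function(res, bounds, pos_mass, table, mods, tol) {
  n <- length(pos_mass)
  matched <- 0L
  for (i in seq_len(nrow(res))) {
    x <- res$start[i]; y <- res$end[i]
    if (res$status[i] == "unresolved") next
    # truth positions fully inside the element's mass interval
    span <- which(bounds[-length(bounds)] >= x - tol &
                    bounds[-1] <= y + tol)
    if (!length(span)) next
    if (res$kind[i] == "edge") {
      # alternative single-residue labels: best credit among them (the
      # single-vs-pair rule inside multiset_credit covers N over G+G)
      pred_each <- codes_to_masses(res$codes[[i]], table, mods)
      matched <- matched +
        max(vapply(pred_each, function(pm) {
          multiset_credit(pm, pos_mass[span], tol)
        }, integer(1)))
    } else {
      pred <- codes_to_masses(res$codes[[i]], table, mods)
      matched <- matched + multiset_credit(pred, pos_mass[span], tol)
    }
  }
  min(matched, n)
}

#' Per-residue sequencing accuracy
#'
#' Percentage of the true residues correctly determined: edge calls match
#' positionally (their mass interval must align with the true prefix-mass
#' boundaries; mass-identical ambiguities such as L/I count as correct) and
#' bracketed gap fills match as multisets against the true residues their
#' interval spans (mass-identical substitutions such as N vs G+G count as
#' correct). The better of the as-read orientation and its reversal is
#' reported, since the two fragment ladders are co-optimal readings of one
#' spectrum.
#'
#' @param res a \code{sequencing_result}.
#' @param truth the true \code{peptide}.
#' @param table residue table.
#' @param mods modification table.
#' @param tol mass tolerance (Da).
#' @return accuracy in percent (0-100).
#' @export
accuracy <- function(res, truth, table = residue_table(),
                     mods = mod_table(), tol = 0.02) {
  pos_mass <- peptide_position_masses(truth, table, mods)
  M <- sum(pos_mass)
  bounds <- c(0, cumsum(pos_mass))
  fwd <- score_orientation(res, bounds, pos_mass, table, mods, tol)
  # reversal: reflect element intervals through M and reverse the order
  rev_res <- res[rev(seq_len(nrow(res))), , drop = FALSE]
  start <- M - rev_res$end; end <- M - rev_res$start
  rev_res$start <- start; rev_res$end <- end
  bwd <- score_orientation(rev_res, bounds, pos_mass, table, mods, tol)
  100 * max(fwd, bwd) / length(pos_mass)
}

## --- benchmarking ---------------------------------------------------------

#' Run the simulation benchmark at one noise level
#'
#' Simulates \code{cfg$n_peptides} spectra, sequences each and scores it.
#'
#' @param cfg a \code{sim_config}.
#' @param table residue table.
#' @param mods modification table.
#' @param strategy decomposition strategy.
#' @return data frame with one row per spectrum: \code{length},
#'   \code{n_peaks}, \code{width}, \code{n_segments}, \code{accuracy},
#'   \code{seconds}, \code{ok}.
#' @export
evaluate_batch <- function(cfg, table = residue_table(),
                           mods = mod_table(), strategy = "greedy") {
  sim <- simulate_spectra(cfg, table, mods)
  rows <- lapply(seq_along(sim$spectra), function(i) {
    s <- sim$spectra[[i]]
    t0 <- proc.time()[3]
    out <- tryCatch({
      res <- sequence_spectrum(s, table, mods, tol = cfg$tol,
                               strategy = strategy,
                               complement_augment = FALSE)
      acc <- accuracy(res, sim$peptides[[i]], table, mods,
                      tol = max(cfg$tol, 0.01))
      list(width = attr(res, "width"),
           nseg = length(attr(res, "path")$segments),
           acc = acc, ok = TRUE)
    }, error = function(e) {
      list(width = NA_integer_, nseg = NA_integer_, acc = 0, ok = FALSE)
    })
    data.frame(length = length(sim$peptides[[i]]$sequence),
               n_peaks = nrow(s$peaks), width = out$width,
               n_segments = out$nseg, accuracy = out$acc,
               seconds = proc.time()[3] - t0, ok = out$ok)
  })
  do.call(rbind, rows)
}

#' Noise-sweep benchmark summary
#'
#' Reruns the simulation benchmark across noise/signal levels and
#' summarizes accuracy, width distribution and runtime per level.
#'
#' @param n_peptides spectra per level.
#' @param seed base seed; level k uses seed + k - 1.
#' @param ns_levels noise/signal ratios.
#' @param ... further arguments to \code{\link{sim_config}}.
#' @param table residue table.
#' @param mods modification table.
#' @return data frame with one row per level: \code{ns}, \code{mean_accuracy}
#'   (percent), \code{pw_lt5}, \code{pw_eq5}, \code{pw_gt5} (percent of
#'   graphs), \code{mean_seconds}, \code{n}.
#' @export
benchmark_sweep <- function(n_peptides, seed,
                            ns_levels = c(0, 0.2, 0.5, 0.8, 1.0), ...,
                            table = residue_table(), mods = mod_table()) {
  rows <- lapply(seq_along(ns_levels), function(k) {
    cfg <- sim_config(n_peptides, seed = seed + k - 1L,
                      ns_ratio = ns_levels[k], ...)
    b <- evaluate_batch(cfg, table, mods)
    data.frame(ns = ns_levels[k],
               mean_accuracy = mean(b$accuracy),
               pw_lt5 = 100 * mean(b$width < 5, na.rm = TRUE),
               pw_eq5 = 100 * mean(b$width == 5, na.rm = TRUE),
               pw_gt5 = 100 * mean(b$width > 5, na.rm = TRUE),
               mean_seconds = mean(b$seconds), n = nrow(b))
  })
  do.call(rbind, rows)
}

#' Width distribution of noiseless simulated spectrum graphs
#'
#' Builds the extended spectrum graphs of a seeded batch and reports the
#' achieved decomposition width of each (before source/sink augmentation).
#'
#' @param cfg a \code{sim_config}.
#' @param table residue table.
#' @param strategy decomposition strategy.
#' @return integer vector of widths, one per spectrum.
#' @export
width_distribution <- function(cfg, table = residue_table(),
                               strategy = "greedy") {
  sim <- simulate_spectra(cfg, table)
  vapply(sim$spectra, function(s) {
    s2 <- preprocess(s, tol = cfg$tol, add_complements = FALSE)
    g <- build_graph(s2, table, tol = cfg$tol)
    decompose(g, strategy = strategy)$width
  }, integer(1))
}
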