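# Shared fixtures: all built in code at test time.

TAB <- residue_table()
MODS <- mod_table()

# spectrum in abstract coordinates from explicit peak masses
abstract_spectrum <- function(masses, M, intensity = 1) {
  spectrum(masses, intensity, total_mass = M)
}

# extended spectrum graph of a peptide's ideal spectrum
peptide_graph <- function(seq, tol = 0.001) {
  p <- peptide(seq, table = TAB)
  s <- ideal_spectrum(p, TAB, MODS)
  build_graph(s, TAB, tol = tol)
}

# the worked two-residue graph: peaks G and A, M = G+A
ga_graph <- function() peptide_graph("GA")

# random mixed graph: residue-structured and uniform peak masses plus
# extra random complement pairs (not necessarily summing to M)
random_mixed_graph <- function(max_peaks = 9) {
  M <- runif(1, 400, 900)
  start <- runif(1, 30, M / 2)
  chain <- cumsum(c(start, sample(TAB$residues, 3, replace = TRUE)))
  masses <- unique(round(c(chain[chain < M - 30],
                           runif(sample(3:max_peaks, 1), 30, M - 30)), 3))
  masses <- masses[masses > 0 & masses < M]
  if (length(masses) > max_peaks) masses <- sample(masses, max_peaks)
  g <- build_graph(spectrum(masses, 1, M), TAB, tol = 0.02)
  pk <- which(g$vertices$kind == "peak")
  if (length(pk) >= 2) {
    extra <- matrix(sample(pk, 2 * sample(1:3, 1), replace = TRUE), ncol = 2)
    extra <- extra[extra[, 1] != extra[, 2], , drop = FALSE]
    if (nrow(extra)) {
      g$complements <- unique(rbind(
        g$complements,
        data.frame(v1 = pmin(extra[, 1], extra[, 2]),
                   v2 = pmax(extra[, 1], extra[, 2]))))
    }
  }
  g
}

# a valid (random-order) path decomposition of g
random_decomposition <- function(g) {
  n <- nrow(g$vertices)
  pdnovo:::pd_from_order(sample(n), pdnovo:::mixed_adjacency(g), n)
}

# plain graph (no residue semantics) wrapped as a spectrum_graph so the
# decomposition utilities can be exercised on textbook examples
toy_graph <- function(n, edges, complements = NULL) {
  # place vertices on an arbitrary ascending mass scale
  vertices <- data.frame(id = seq_len(n), mass = seq_len(n) * 100,
                         kind = c("source", rep("peak", max(0, n - 2)),
                                  "sink")[seq_len(n)])
  e <- if (length(edges)) {
    data.frame(from = vapply(edges, `[`, numeric(1), 1),
               to = vapply(edges, `[`, numeric(1), 2))
  } else {
    data.frame(from = integer(), to = integer())
  }
  e$labels <- rep(list("X"), nrow(e))
  cmp <- if (is.null(complements)) {
    data.frame(v1 = integer(), v2 = integer())
  } else {
    data.frame(v1 = vapply(complements, `[`, numeric(1), 1),
               v2 = vapply(complements, `[`, numeric(1), 2))
  }
  structure(list(vertices = vertices, edges = e, complements = cmp,
                 total_mass = (n + 1) * 100, tol = 0.5),
            class = "spectrum_graph")
}

# monoisotopic residue masses recomputed from atomic composition -- an
# oracle independent of the package's stored table
atomic_residue_masses <- function() {
  H <- 1.00782503207; C <- 12; N <- 14.0030740048
  O <- 15.9949146196; S <- 31.97207100
  comp <- list(
    G = c(2, 3, 1, 1, 0), A = c(3, 5, 1, 1, 0), S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0), V = c(5, 9, 1, 1, 0), T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1), L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0), D = c(4, 5, 1, 3, 0), Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0), M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0), F = c(9, 9, 1, 1, 0), R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0), W = c(11, 10, 2, 1, 0))
  vapply(comp, function(x) {
    x[1] * C + x[2] * H + x[3] * N + x[4] * O + x[5] * S
  }, numeric(1))
}
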