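## Extended spectrum graph construction.
##
## Vertices are the source (mass 0), the sink (mass M) and one vertex per
## peak. A directed edge joins u -> v when mass(v) - mass(u) matches at
## least one residue mass within tolerance; edges carry the full set of
## matching residue labels. A non-directed complement edge joins each pair
## of peaks whose masses sum to M within tolerance; complement edges never
## touch the source or the sink and a peak at M/2 is not paired with itself.

#' Build the extended spectrum graph of a preprocessed spectrum
#'
#' @param s a \code{spectrum} in abstract coordinates.
#' @param table residue table providing the edge masses.
#' @param tol mass tolerance (Da) for both edge and complement matching.
#' @param mods optional \code{mod_table}; when \code{allow_mod_edges} is
#'   TRUE, directed edges are also created for single modified residues.
#' @param allow_mod_edges create edges for residue-plus-modification masses
#'   (default FALSE: modifications are handled by gap filling).
#' @return object of class \code{spectrum_graph}: list with
#'   \code{vertices} (data frame id, mass, kind), \code{edges} (data frame
#'   from, to, labels list-column), \code{complements} (data frame v1, v2),
#'   \code{total_mass}, \code{tol}.
#' @examples
#' tab <- residue_table()
#' s <- spectrum(c(57.02146, 71.03711), 1, total_mass = 128.05857)
#' g <- build_graph(s, tab, tol = 0.001)
#' graph_stats(g)
#' @export
build_graph <- function(s, table = residue_table(), tol = 0.3,
                        mods = NULL, allow_mod_edges = FALSE) {
  M <- s$total_mass
  if (is.null(M) || M <= 0) stop("total mass M must be positive")
  mass <- c(0, s$peaks$mass, M)
  kind <- c("source", rep("peak", nrow(s$peaks)), "sink")
  n <- length(mass)
  id <- seq_len(n)
  # candidate edge masses: residues (and optionally singly modified residues)
  emass <- table$residues
  elab <- names(table$residues)
  if (allow_mod_edges && !is.null(mods)) {
    mm <- mods$mods
    emass <- c(emass, table$residues[mm$target] + mm$delta)
    elab <- c(elab, paste0(mm$target, "+", mm$label))
  }
  from <- integer(); to <- integer(); labels <- list()
  for (i in seq_len(n - 1L)) {
    d <- mass[(i + 1L):n] - mass[i]
    cand <- which(d >= min(emass) - tol & d <= max(emass) + tol)
    for (jrel in cand) {
      j <- i + jrel
      hit <- which(abs(emass - d[jrel]) <= tol)
      if (length(hit)) {
        from <- c(from, i); to <- c(to, j)
        o <- order(abs(emass[hit] - d[jrel]), elab[hit])
        labels[[length(labels) + 1L]] <- unique(elab[hit][o])
      }
    }
  }
  # complement edges among peaks only, no self pairing at M/2
  v1 <- integer(); v2 <- integer()
  peak_idx <- which(kind == "peak")
  if (length(peak_idx) > 1L) {
    for (a in seq_len(length(peak_idx) - 1L)) {
      i <- peak_idx[a]
      for (b in (a + 1L):length(peak_idx)) {
        j <- peak_idx[b]
        if (abs(mass[i] + mass[j] - M) <= tol) {
          v1 <- c(v1, i); v2 <- c(v2, j)
        }
      }
    }
  }
  edges <- data.frame(from = from, to = to)
  edges$labels <- labels
  structure(
    list(vertices = data.frame(id = id, mass = mass, kind = kind,
                               stringsAsFactors = FALSE),
         edges = edges,
         complements = data.frame(v1 = v1, v2 = v2),
         total_mass = M, tol = tol),
    class = "spectrum_graph"
  )
}

#' @export
print.spectrum_graph <- function(x, ...) {
  cat("<spectrum_graph> ", nrow(x$vertices), " vertices, ",
      nrow(x$edges), " directed edges, ", nrow(x$complements),
      " complement edges, M = ", format(x$total_mass), " Da\n", sep = "")
  invisible(x)
}

#' Summary counts for a spectrum graph
#'
#' @param g a \code{spectrum_graph}.
#' @return list with vertex/edge counts and directed-edge density.
#' @export
graph_stats <- function(g) {
  nv <- nrow(g$vertices)
  ne <- nrow(g$edges)
  nc <- nrow(g$complements)
  dens <- if (nv > 1L) ne / (nv * (nv - 1L) / 2) else 0
  list(n_vertices = nv, n_peaks = sum(g$vertices$kind == "peak"),
       n_directed = ne, n_complement = nc, density = dens)
}

#' Export a spectrum graph as plain text
#'
#' One edge per line: \code{D from to mass(from) mass(to) labels} for
#' directed edges and \code{C v1 v2 ...} for complement edges, preceded by
#' vertex lines \code{V id mass kind}.
#'
#' @param g a \code{spectrum_graph}.
#' @param path output file.
#' @export
write_graph_txt <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("V %d %.5f %s", g$vertices$id, g$vertices$mass,
                     g$vertices$kind), con)
  if (nrow(g$edges)) {
    lab <- vapply(g$edges$labels, paste, "", collapse = ",")
    writeLines(sprintf("D %d %d %s", g$edges$from, g$edges$to, lab), con)
  }
  if (nrow(g$complements)) {
    writeLines(sprintf("C %d %d", g$complements$v1, g$complements$v2), con)
  }
  invisible(path)
}

## --- internal adjacency helpers -------------------------------------------

# list of integer vectors: out-neighbors / in-neighbors per vertex id
graph_adjacency <- function(g) {
  n <- nrow(g$vertices)
  out <- vector("list", n); inn <- vector("list", n)
  for (k in seq_len(nrow(g$edges))) {
    f <- g$edges$from[k]; t <- g$edges$to[k]
    out[[f]] <- c(out[[f]], t)
    inn[[t]] <- c(inn[[t]], f)
  }
  list(out = out, inn = inn)
}

# undirected adjacency over both edge types (for decomposition)
mixed_adjacency <- function(g) {
  n <- nrow(g$vertices)
  adj <- vector("list", n)
  add <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
    adj[[b]] <<- c(adj[[b]], a)
  }
  for (k in seq_len(nrow(g$edges))) add(g$edges$from[k], g$edges$to[k])
  for (k in seq_len(nrow(g$complements))) {
    add(g$complements$v1[k], g$complements$v2[k])
  }
  lapply(adj, function(x) sort(unique(x)))
}

source_id <- function(g) g$vertices$id[g$vertices$kind == "source"]
sink_id <- function(g) g$vertices$id[g$vertices$kind == "sink"]
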