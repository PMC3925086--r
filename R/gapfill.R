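## Gap resolution: convert a longest antisymmetric partial path into a full
## sequencing result. Each pair of consecutive segments leaves a mass gap
## between the largest vertex of one segment and the smallest vertex of the
## next; the gap is explained by a multiset of residues (subset-sum over
## residue masses), falling back to at most one modified residue when no
## unmodified combination fits. Gap fills are compositions, not ordered
## subsequences, and are reported in brackets.

#' Mass gaps between consecutive segments
#'
#' @param p an \code{antisym_path}.
#' @param g the \code{spectrum_graph} it belongs to.
#' @return data frame with one row per gap: \code{left}, \code{right}
#'   (vertex ids), \code{delta} (Da), ascending mass order.
#' @export
find_gaps <- function(p, g) {
  mass <- g$vertices$mass
  k <- length(p$segments)
  if (k < 2L) {
    return(data.frame(left = integer(), right = integer(),
                      delta = numeric()))
  }
  left <- vapply(p$segments[-k], function(s) s[length(s)], integer(1))
  right <- vapply(p$segments[-1], `[`, integer(1), 1L)
  data.frame(left = left, right = right,
             delta = mass[right] - mass[left])
}

#' Residue multisets explaining a mass gap
#'
#' Searches multisets of residues whose masses sum to \code{delta} within
#' \code{tol}. Unmodified solutions are searched first; only when none
#' exists is a single modified residue admitted (configurable via
#' \code{max_mods}). Candidates are ranked by fewer residues, then fewer
#' modifications, then smaller absolute mass error.
#'
#' @param delta positive mass gap (Da).
#' @param table residue table.
#' @param mods \code{mod_table} consulted in the modified pass.
#' @param tol mass tolerance (Da).
#' @param max_residues largest multiset size considered; defaults to the
#'   subset-sum bound ceiling(delta / min residue mass).
#' @param max_mods maximum modified residues per gap (default 1).
#' @param max_candidates cap on returned candidates.
#' @return object of class \code{gap_fill}: list with \code{candidates}
#'   (list of character vectors of residue codes, modified residues coded
#'   "X+label"), \code{errors}, \code{n_mods}, and \code{status} ("exact",
#'   "modified" or "unresolved").
#' @examples
#' subset_fill(114.04293, tol = 0.01)  # {N} ranked before {G,G}
#' @export
subset_fill <- function(delta, table = residue_table(), mods = mod_table(),
                        tol = 0.02, max_residues = NULL, max_mods = 1L,
                        max_candidates = 20L) {
  stopifnot(delta > 0, tol >= 0)
  if (is.null(max_residues)) {
    max_residues <- max(1L, ceiling(delta / table$min_residue_mass))
  }
  plain <- fill_search(delta, table, NULL, tol, max_residues, 0L)
  if (length(plain$sets)) {
    return(rank_fills(plain, delta, "exact", max_candidates))
  }
  if (max_mods > 0L) {
    modded <- fill_search(delta, table, mods, tol, max_residues, max_mods)
    if (length(modded$sets)) {
      return(rank_fills(modded, delta, "modified", max_candidates))
    }
  }
  structure(list(candidates = list(), errors = numeric(),
                 n_mods = integer(), status = "unresolved", delta = delta),
            class = "gap_fill")
}

# iterative-deepening DFS over residue multisets: smallest multisets first,
# pruned by attainable mass bounds; at most max_mods modified residues.
fill_search <- function(delta, table, mods, tol, max_residues, max_mods) {
  res <- sort(table$residues)  # ascending
  codes <- names(res)
  items_mass <- unname(res)
  items_code <- codes
  items_mod <- rep(0L, length(res))
  if (!is.null(mods) && max_mods > 0L) {
    mm <- mods$mods
    items_mass <- c(items_mass, unname(table$residues[mm$target]) + mm$delta)
    items_code <- c(items_code, paste0(mm$target, "+", mm$label))
    items_mod <- c(items_mod, rep(1L, nrow(mm)))
  }
  o <- order(items_mass)
  items_mass <- items_mass[o]; items_code <- items_code[o]
  items_mod <- items_mod[o]
  mmin <- items_mass[1]; mmax <- items_mass[length(items_mass)]
  sets <- list(); errs <- numeric(); nm <- integer()
  nodes <- 0L; budget <- 200000L
  dfs <- function(start, left, remaining, acc, used_mods) {
    nodes <<- nodes + 1L
    if (nodes > budget) return(invisible())
    if (left == 0L) {
      if (abs(remaining) <= tol) {
        sets[[length(sets) + 1L]] <<- items_code[acc]
        errs[length(errs) + 1L] <<- abs(remaining)
        nm[length(nm) + 1L] <<- used_mods
      }
      return(invisible())
    }
    if (remaining < left * mmin - tol) return(invisible())
    if (remaining > left * mmax + tol) return(invisible())
    for (i in seq(start, length(items_mass))) {
      if (items_mass[i] > remaining + tol) break
      um <- used_mods + items_mod[i]
      if (um > max_mods) next
      dfs(i, left - 1L, remaining - items_mass[i], c(acc, i), um)
    }
  }
  for (k in seq_len(max_residues)) {
    dfs(1L, k, delta, integer(), 0L)
    if (nodes > budget) break
  }
  list(sets = sets, errs = errs, nm = nm)
}

rank_fills <- function(found, delta, status, max_candidates) {
  o <- order(lengths(found$sets), found$nm, found$errs)
  o <- o[seq_len(min(length(o), max_candidates))]
  structure(list(candidates = found$sets[o], errors = found$errs[o],
                 n_mods = found$nm[o], status = status, delta = delta),
            class = "gap_fill")
}

#' @export
print.gap_fill <- function(x, ...) {
  cat("<gap_fill> delta ", format(x$delta), " Da, status ", x$status,
      ", ", length(x$candidates), " candidate(s)\n", sep = "")
  for (i in seq_len(min(5L, length(x$candidates)))) {
    cat("  {", paste(x$candidates[[i]], collapse = ","), "} err ",
        format(x$errors[i], digits = 3), "\n", sep = "")
  }
  invisible(x)
}

# joint call label for a set of mass-equivalent residue codes ("L/I")
call_label <- function(codes) paste(codes, collapse = "/")

#' Assemble a sequencing result from a partial path and gap fills
#'
#' Concatenates per-edge residue calls (ambiguous mass-equal labels are
#' kept, e.g. "L/I") and bracketed gap fills in ascending mass order.
#' Unresolved gaps are emitted as a bracketed mass delta so the result
#' always conserves the total mass.
#'
#' @param p an \code{antisym_path}.
#' @param fills list of \code{gap_fill} objects, one per gap of \code{p}
#'   (as from \code{\link{find_gaps}} + \code{\link{subset_fill}}).
#' @param g the \code{spectrum_graph}.
#' @param table residue table (for element masses).
#' @return object of class \code{sequencing_result}: data frame of elements
#'   with columns \code{kind} (edge|gap), \code{start}, \code{end} (Da),
#'   \code{call}, \code{codes} (list), \code{status}; attributes
#'   \code{total_mass}, \code{orientation}, \code{string}.
#' @export
assemble <- function(p, fills, g, table = residue_table()) {
  mass <- g$vertices$mass
  gaps <- find_gaps(p, g)
  stopifnot(length(fills) == nrow(gaps))
  rows <- list()
  add_row <- function(kind, a, b, call, codes, status) {
    rows[[length(rows) + 1L]] <<- list(kind = kind, start = a, end = b,
                                       call = call, codes = list(codes),
                                       status = status)
  }
  edge_label <- function(u, v) {
    k <- which(g$edges$from == u & g$edges$to == v)
    if (length(k)) g$edges$labels[[k[1]]] else character()
  }
  for (si in seq_along(p$segments)) {
    seg <- p$segments[[si]]
    if (length(seg) > 1L) {
      for (i in seq_len(length(seg) - 1L)) {
        lab <- edge_label(seg[i], seg[i + 1])
        add_row("edge", mass[seg[i]], mass[seg[i + 1]],
                call_label(lab), lab, "called")
      }
    }
    if (si < length(p$segments)) {
      f <- fills[[si]]
      a <- mass[gaps$left[si]]; b <- mass[gaps$right[si]]
      if (f$status == "unresolved" || !length(f$candidates)) {
        add_row("gap", a, b, sprintf("[Δ%.3f]", b - a), character(),
                "unresolved")
      } else {
        codes <- sort(f$candidates[[1]])
        add_row("gap", a, b, paste0("[", paste(codes, collapse = ""), "]"),
                codes, f$status)
      }
    }
  }
  elements <- do.call(rbind, lapply(rows, function(r) {
    data.frame(kind = r$kind, start = r$start, end = r$end, call = r$call,
               status = r$status, stringsAsFactors = FALSE)
  }))
  elements$codes <- lapply(rows, function(r) r$codes[[1]])
  out <- structure(elements, class = c("sequencing_result", "data.frame"))
  attr(out, "total_mass") <- g$total_mass
  attr(out, "orientation") <- "as-read"
  attr(out, "string") <- paste(elements$call, collapse = "")
  out
}

#' @export
print.sequencing_result <- function(x, ...) {
  cat("<sequencing_result> ", attr(x, "string"), "\n  total mass ",
      format(attr(x, "total_mass")), " Da, ", nrow(x), " element(s)\n",
      sep = "")
  invisible(x)
}

#' Sequence string of a sequencing result
#' @param x a \code{sequencing_result}.
#' @param ... unused.
#' @export
format.sequencing_result <- function(x, ...) attr(x, "string")

# mass of one element (edge call: mass difference; gap: difference too)
element_masses <- function(res) res$end - res$start

#' Structured record of a sequencing result
#'
#' @param res a \code{sequencing_result}.
#' @return a list safe to serialize as JSON (elements, masses, provenance,
#'   alternatives).
#' @export
result_record <- function(res) {
  list(
    sequence = attr(res, "string"),
    total_mass = attr(res, "total_mass"),
    elements = lapply(seq_len(nrow(res)), function(i) {
      list(kind = res$kind[i], start = res$start[i], end = res$end[i],
           call = res$call[i], status = res$status[i],
           codes = res$codes[[i]])
    })
  )
}
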