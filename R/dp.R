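## Longest antisymmetric partial path by dynamic programming over a path
## decomposition.
##
## An antisymmetric partial path is a set of vertex-disjoint directed path
## segments whose mass intervals are pairwise disjoint (so the segments are
## linearly ordered by mass), using no two complementary vertices, anchored
## at the source (first segment) and the sink (last segment). Segments with
## disjoint mass intervals are exactly the runs of the mass-sorted selected
## vertex set, so a selection X determines the structure: sort X by mass;
## two consecutive vertices belong to the same segment exactly when a
## directed edge joins them, and the total length is the number of such
## consecutive pairs. (When no residue mass equals a sum of other residue
## masses this is the same as counting all selected edges -- the classical
## spectrum-graph idealization; the consecutive-pair reading additionally handles the
## recorded Asn = Gly+Gly and Gln = Gly+Ala coincidences, where a
## single-residue edge may skip over a selected vertex and simply goes
## unused.)
##
## The sweep introduces and forgets one vertex at a time along the (nice
## form of the) decomposition, keyed by the selection mask over the current
## bag; source and sink bits are forced to 1, so a table over a bag of size
## p holds at most 2^(p-2) entries, within the 2^(p-2) * (p+1) bound of the
## (selection, furthest-vertex) table layout. Two ingredients are
## not bag-local for an arbitrary decomposition and are made local by a
## conflict-completion preprocessing step:
##
##   * whether edge (u,v) joins mass-consecutive selected vertices depends
##     on every vertex w with mass strictly between u and v;
##   * nothing else: complement pairs are graph edges and share a bag.
##
## Completion minimally extends vertex bag-intervals so that each edge,
## both its endpoints and all vertices inside its mass span share a common
## bag; the edge's contribution is then decided at one sweep step where all
## of them are present. Reported decomposition widths are those of the
## original decomposition; the completion is internal to the solver.

# Selection masks are exact doubles (sums of distinct powers of two, up
# to 52 slots). AND is computed on 31-bit halves; OR follows from
# inclusion-exclusion; "a without b" is a - (a AND b).
.D31 <- 2^31
d_and <- function(a, b) {
  al <- as.integer(a %% .D31); ah <- as.integer(a %/% .D31)
  bl <- as.integer(b %% .D31); bh <- as.integer(b %/% .D31)
  bitwAnd(al, bl) + bitwAnd(ah, bh) * .D31
}
d_or <- function(a, b) a + b - d_and(a, b)

# for each directed edge, the vertices whose mass lies strictly inside the
# edge's mass span (they decide whether the edge joins consecutive
# selected vertices)
edge_spans <- function(g) {
  mass <- g$vertices$mass
  lapply(seq_len(nrow(g$edges)), function(k) {
    u <- g$edges$from[k]; v <- g$edges$to[k]
    setdiff(which(mass > mass[u] & mass < mass[v]), c(u, v))
  })
}

# complement pairs as a 2-column matrix
complement_pairs <- function(g) {
  if (nrow(g$complements)) as.matrix(g$complements) else
    matrix(integer(), ncol = 2)
}

## --- sweep preparation ----------------------------------------------------

# vertex bag-intervals [first, last] from an (augmented) decomposition
pd_intervals <- function(pd, n) {
  first <- rep(NA_integer_, n); last <- rep(NA_integer_, n)
  for (t in seq_along(pd$bags)) {
    for (v in pd$bags[[t]]) {
      if (is.na(first[v])) first[v] <- t
      last[v] <- t
    }
  }
  list(first = first, last = last)
}

# extend intervals so that each edge's endpoints and all vertices in its
# mass span share a common bag index (intervals only grow, so earlier
# guarantees survive later extensions)
complete_conflicts <- function(first, last, g, spans) {
  for (k in seq_len(nrow(g$edges))) {
    u <- g$edges$from[k]; v <- g$edges$to[k]
    lo <- max(first[u], first[v]); hi <- min(last[u], last[v])
    if (lo > hi) stop("decomposition does not cover edge {", u, ",", v, "}")
    W <- spans[[k]]
    if (!length(W)) next
    t_e <- min(hi, max(c(lo, first[W])))
    for (w in W) {
      if (first[w] > t_e) first[w] <- t_e
      if (last[w] < t_e) last[w] <- t_e
    }
  }
  list(first = first, last = last)
}

# build the atomic step sequence from intervals: at index t, introduce all
# vertices with first == t (source/sink first, then ascending mass), then
# forget those with last == t; source and sink are never forgotten.
sweep_steps <- function(first, last, mass, so, si) {
  stopifnot(!anyNA(first), all(last >= first))
  B <- max(last)
  steps <- list()
  for (t in seq_len(B)) {
    intro <- which(first == t)
    intro <- intro[order(match(intro, c(so, si), nomatch = 3L), mass[intro])]
    for (v in intro) steps[[length(steps) + 1L]] <- list(op = "intro", v = v)
    forg <- setdiff(which(last == t), c(so, si))
    forg <- forg[order(mass[forg])]
    for (v in forg) steps[[length(steps) + 1L]] <- list(op = "forget", v = v)
  }
  steps
}

## --- the sweep ------------------------------------------------------------

# Core sweep over atomic steps. Entries are rows of parallel vectors:
#   mask  selection bits over current bag slots
#   len   accumulated length (consecutive selected pairs joined by an edge)
#   Lv    furthest vertex of the source segment (vertex id; 0 = elsewhere,
#         i.e. the furthest vertex has been forgotten)
#   nsel  number of selected vertices (tie-break: fewer preferred, i.e.
#         fewer segments / unexplained gaps at equal length)
#   msum  total selected mass (final tie-break: smaller preferred)
#   back  row index into the previous step's table (traceback)
# Source and sink are forced selected. A complement pair is rejected
# whenever the introduced vertex is a member and both members are in the
# bag. Each edge's contribution is decided at the introduction step of the
# last-introduced vertex among {endpoints, spanned vertices} (conflict
# completion guarantees they are all in the bag there): +1 when both
# endpoints are selected and no spanned vertex is.
dp_sweep <- function(g, steps, state = NULL, max_bag = 52L,
                     canonical = FALSE) {
  n <- nrow(g$vertices)
  mass <- g$vertices$mass
  so <- source_id(g); si <- sink_id(g)
  adjd <- graph_adjacency(g)
  pairs <- complement_pairs(g)
  spans <- edge_spans(g)
  ne <- nrow(g$edges)
  M2 <- g$total_mass / 2
  compl_adj <- vector("list", n)
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    compl_adj[[a]] <- c(compl_adj[[a]], b)
    compl_adj[[b]] <- c(compl_adj[[b]], a)
  }

  if (is.null(state)) {
    slot_of <- integer(n)      # 0 = not in bag
    free_slots <- seq_len(max_bag)
    in_bag <- integer(0)       # vertex ids currently in bag
    tab <- list(mask = 0, len = 0L, Lv = 0L, nsel = 0L, msum = 0,
                back = 0L)
    tables <- list()
    bag_sizes <- integer(0)
    entry_counts <- integer(0)
    done <- list()
    intro_seen <- logical(n)
    edge_done <- logical(ne)
  } else {
    slot_of <- state$slot_of
    free_slots <- state$free_slots
    in_bag <- state$in_bag
    tab <- state$tab
    tables <- state$tables
    bag_sizes <- state$bag_sizes
    entry_counts <- state$entry_counts
    done <- state$steps
    intro_seen <- state$intro_seen
    edge_done <- state$edge_done
  }

  # slot -1 marks a vertex that is in the bag but unselected in every
  # entry (its slot was reclaimed); its bit reads as 0
  slot_bit <- function(vs) {
    s <- slot_of[vs]
    b <- numeric(length(vs))
    ok <- s > 0L
    b[ok] <- 2^(s[ok] - 1L)
    b
  }
  mask_of <- function(vs) {
    if (!length(vs)) return(0)
    sum(slot_bit(vs))  # distinct slots: plain sum is the bit union
  }

  for (s in seq_along(steps)) {
    st <- steps[[s]]
    x <- st$v
    if (st$op == "intro") {
      if (!length(free_slots)) {
        stop("bag size exceeded ", max_bag,
             " during sweep; pathwidth too large")
      }
      slot_of[x] <- free_slots[1L]
      free_slots <- free_slots[-1L]
      in_bag <- c(in_bag, x)
      intro_seen[x] <- TRUE
      bit <- slot_bit(x)

      m0 <- tab$mask
      # selected branch
      mask1 <- m0 + bit  # x's bit is new: plain sum sets it
      len1 <- tab$len
      nsel1 <- tab$nsel + 1L
      msum1 <- tab$msum + mass[x]
      Lv1 <- tab$Lv
      if (length(adjd$inn[[x]])) {
        ext <- Lv1 != 0L & Lv1 %in% adjd$inn[[x]]
        if (any(ext)) Lv1[ext] <- x
      }
      back1 <- seq_along(m0)

      # complement-pair filter on the selected branch
      ok <- rep(TRUE, length(mask1))
      if (nrow(pairs)) {
        rel <- which((pairs[, 1] == x | pairs[, 2] == x) &
                       slot_of[pairs[, 1]] > 0L & slot_of[pairs[, 2]] > 0L)
        for (k in rel) {
          pm <- slot_bit(pairs[k, 1]) + slot_bit(pairs[k, 2])
          ok <- ok & d_and(mask1, pm) != pm
        }
      }
      mask1 <- mask1[ok]; len1 <- len1[ok]; Lv1 <- Lv1[ok]
      nsel1 <- nsel1[ok]; msum1 <- msum1[ok]; back1 <- back1[ok]

      # chain-follow the source-segment endpoint annotation
      if (length(mask1)) {
        follow <- which(Lv1 == x)
        for (i in follow) {
          repeat {
            onb <- intersect(adjd$out[[Lv1[i]]], in_bag)
            if (!length(onb)) break
            selb <- onb[d_and(mask1[i], slot_bit(onb)) != 0]
            if (!length(selb)) break
            Lv1[i] <- selb[1L]
          }
        }
      }

      if (x == so || x == si) {
        if (x == so) Lv1[Lv1 == 0L] <- so
        tab <- list(mask = mask1, len = len1, Lv = Lv1, nsel = nsel1,
                    msum = msum1, back = back1)
      } else {
        tab <- list(mask = c(m0, mask1),
                    len = c(tab$len, len1),
                    Lv = c(tab$Lv, Lv1),
                    nsel = c(tab$nsel, nsel1),
                    msum = c(tab$msum, msum1),
                    back = c(seq_along(m0), back1))
      }

      # edge contributions decided at this step: edges whose endpoint and
      # span vertices have now all been introduced (and are all in bag)
      if (ne) {
        ready <- which(!edge_done &
                         intro_seen[g$edges$from] & intro_seen[g$edges$to])
        for (k in ready) {
          W <- spans[[k]]
          if (length(W) && !all(intro_seen[W])) next
          u <- g$edges$from[k]; v <- g$edges$to[k]
          if (slot_of[u] <= 0L || slot_of[v] <= 0L ||
              (length(W) && any(slot_of[W] == 0L))) {
            if (!canonical) {
              stop("internal error: edge {", u, ",", v,
                   "} not bag-local at its decision step")
            }
            # an endpoint with a reclaimed slot is unselected in every
            # entry: the edge contributes nothing
            if (slot_of[u] == -1L || slot_of[v] == -1L) {
              edge_done[k] <- TRUE
              next
            }
            stop("internal error: edge {", u, ",", v,
                 "} left the bag before its decision step")
          }
          uvm <- slot_bit(u) + slot_bit(v)
          wm <- mask_of(W)
          hit <- d_and(tab$mask, uvm) == uvm & d_and(tab$mask, wm) == 0
          tab$len <- tab$len + as.integer(hit)
          edge_done[k] <- TRUE
        }
      }
    } else {
      # forget x
      bit <- slot_bit(x)
      mask <- tab$mask - d_and(tab$mask, bit)
      Lv <- ifelse(tab$Lv == x, 0L, tab$Lv)
      o <- order(mask, -tab$len, tab$nsel, tab$msum, seq_along(mask))
      keep <- !duplicated(mask[o])
      sel <- o[keep]
      tab <- list(mask = mask[sel], len = tab$len[sel], Lv = Lv[sel],
                  nsel = tab$nsel[sel], msum = tab$msum[sel], back = sel)
      if (slot_of[x] > 0L) free_slots <- sort(c(free_slots, slot_of[x]))
      slot_of[x] <- 0L
      in_bag <- setdiff(in_bag, x)
    }
    # canonical entry merging (sound for the solver's shell-monotone pair
    # ordering): two entries with the same top selected low-side vertex,
    # bottom selected high-side vertex and identical bits on vertices with
    # still-pending complement checks have identical futures -- every
    # later edge decision either sees those witness bits or is doomed by
    # them -- so only the best (longest, then lightest) is kept.
    if (canonical && length(tab$mask) > 1L) {
      nent <- length(tab$mask)
      lows <- in_bag[mass[in_bag] <= M2]
      lows <- lows[order(mass[lows])]
      highs <- in_bag[mass[in_bag] > M2]
      highs <- highs[order(-mass[highs])]
      Tbit <- numeric(nent); Fbit <- numeric(nent)
      for (v in lows) {
        b <- slot_bit(v)
        if (b == 0) next
        hit <- d_and(tab$mask, b) != 0
        Tbit[hit] <- b
      }
      for (v in highs) {
        b <- slot_bit(v)
        if (b == 0) next
        hit <- d_and(tab$mask, b) != 0
        Fbit[hit] <- b
      }
      pend <- in_bag[vapply(in_bag, function(z) {
        length(compl_adj[[z]]) > 0L && !all(intro_seen[compl_adj[[z]]])
      }, logical(1))]
      static <- mask_of(unique(c(so, si, pend)))
      ckey <- d_or(d_or(d_and(tab$mask, static), Tbit), Fbit)
      o <- order(ckey, -tab$len, tab$nsel, tab$msum, seq_len(nent))
      sel <- sort(o[!duplicated(ckey[o])])
      if (length(sel) < nent) {
        tab <- list(mask = tab$mask[sel], len = tab$len[sel],
                    Lv = tab$Lv[sel], nsel = tab$nsel[sel],
                    msum = tab$msum[sel], back = tab$back[sel])
      }
    }
    # slot reclamation: a bag vertex whose bit is 0 in every entry can
    # never become selected again; free its slot for later vertices
    if (canonical && length(in_bag)) {
      U <- Reduce(d_or, tab$mask)
      for (v in in_bag) {
        if (slot_of[v] > 0L && v != so && v != si &&
            d_and(U, 2^(slot_of[v] - 1L)) == 0) {
          free_slots <- sort(c(free_slots, slot_of[v]))
          slot_of[v] <- -1L
        }
      }
    }

    bag_sizes <- c(bag_sizes, length(in_bag))
    entry_counts <- c(entry_counts, length(tab$mask))
    tables[[length(tables) + 1L]] <- list(tab = tab, bag = in_bag,
                                          slots = slot_of[in_bag],
                                          v = x, op = st$op)
  }
  list(tables = tables, bag_sizes = bag_sizes, entry_counts = entry_counts,
       steps = c(done, steps), slot_of = slot_of, free_slots = free_slots,
       in_bag = in_bag, tab = tab, intro_seen = intro_seen,
       edge_done = edge_done)
}

# traceback: recover the full selected vertex set of entry `row` in the
# final table
dp_traceback <- function(sweep, row) {
  tables <- sweep$tables
  sel <- integer(0)
  cur <- row
  for (s in rev(seq_along(tables))) {
    tb <- tables[[s]]
    if (tb$op == "intro") {
      x <- tb$v
      slot <- tb$slots[match(x, tb$bag)]
      if (slot > 0L && d_and(tb$tab$mask[cur], 2^(slot - 1L)) != 0) {
        sel <- c(sel, x)
      }
    }
    cur <- tb$tab$back[cur]
    if (s == 1L) break
  }
  sort(sel)
}

## --- public operations ----------------------------------------------------

#' Number of directed edges induced by a vertex selection
#'
#' Under the idealization that no residue mass is a sum of other residue
#' masses, every directed edge with both endpoints selected belongs to the
#' partial path, so the induced-edge count is the structure's length. (At
#' the recorded Asn = Gly+Gly and Gln = Gly+Ala coincidences a
#' single-residue edge may skip a selected vertex; the solver then counts
#' only edges joining mass-consecutive selected vertices.)
#'
#' @param g a \code{spectrum_graph}.
#' @param selected integer vector of selected vertex ids.
#' @return integer edge count.
#' @export
induced_length <- function(g, selected) {
  if (!nrow(g$edges)) return(0L)
  sum(g$edges$from %in% selected & g$edges$to %in% selected)
}

# length of a selection under the consecutive-pair reading
selection_length <- function(g, selected) {
  mass <- g$vertices$mass
  sel <- selected[order(mass[selected])]
  if (length(sel) < 2L) return(0L)
  sum(vapply(seq_len(length(sel) - 1L), function(i) {
    any(g$edges$from == sel[i] & g$edges$to == sel[i + 1])
  }, logical(1)))
}

#' Dynamic programming table for the left-end bag
#'
#' Enumerates the valid (selection, furthest-vertex) entries over a single
#' bag: at most one vertex per complementary pair is selected; the selected
#' vertices induce vertex-disjoint directed path segments; the segment
#' containing the source ends at the furthest vertex L (the source itself
#' when isolated); the length is the number of mass-consecutive selected
#' pairs joined by a directed edge. Source and sink bits are forced to 1.
#'
#' @param bag integer vector of vertex ids (must contain source and sink).
#' @param g a \code{spectrum_graph}.
#' @return a \code{dp_table}.
#' @export
leaf_entries <- function(bag, g) {
  so <- source_id(g); si <- sink_id(g)
  if (!all(c(so, si) %in% bag)) {
    stop("leaf bag must contain the source and the sink")
  }
  mass <- g$vertices$mass
  ord <- bag[order(match(bag, c(so, si), nomatch = 3L), mass[bag])]
  steps <- lapply(ord, function(v) list(op = "intro", v = v))
  sw <- dp_sweep(g, steps)
  as_dp_table(sw, length(sw$tables), g)
}

#' Transition between two adjacent bags
#'
#' Starting from the table of \code{bag_prev}, forgets the vertices leaving
#' the bag and introduces the new ones, producing the table of
#' \code{bag_next}. An entry is emitted only when some entry of \code{prev}
#' is consistent with it (selection agreement on shared vertices, the
#' complement constraint, L propagated along selected directed paths or set
#' to "elsewhere" once the furthest vertex is forgotten); its length is the
#' best consistent predecessor length plus the contribution of edges newly
#' decided in \code{bag_next}.
#'
#' @param prev \code{dp_table} for \code{bag_prev}.
#' @param bag_prev,bag_next integer vectors of vertex ids.
#' @param g a \code{spectrum_graph}.
#' @return a \code{dp_table} for \code{bag_next}.
#' @export
transition <- function(prev, bag_prev, bag_next, g) {
  stopifnot(inherits(prev, "dp_table"))
  mass <- g$vertices$mass
  drop <- setdiff(bag_prev, bag_next)
  add <- setdiff(bag_next, bag_prev)
  steps <- c(lapply(drop[order(mass[drop])],
                    function(v) list(op = "forget", v = v)),
             lapply(add[order(mass[add])],
                    function(v) list(op = "intro", v = v)))
  if (prev$step != length(prev$sweep$tables)) {
    stop("transition must resume from the most recent table of the sweep")
  }
  sw <- dp_sweep(g, steps, state = prev$sweep)
  as_dp_table(sw, length(sw$tables), g)
}

# convert sweep state at step s into a user-facing dp_table
as_dp_table <- function(sweep, s, g) {
  tb <- sweep$tables[[s]]
  bag <- sort(tb$bag)
  slots <- tb$slots[match(bag, tb$bag)]
  bits <- ifelse(slots > 0L, 2^(slots - 1L), 0)
  sel <- vapply(tb$tab$mask, function(m) {
    paste(as.integer(d_and(m, bits) != 0), collapse = "")
  }, "")
  entries <- data.frame(sel = sel, L = tb$tab$Lv, len = tb$tab$len,
                        stringsAsFactors = FALSE)
  structure(list(bag = bag, entries = entries, sweep = sweep, step = s),
            class = "dp_table")
}

#' @export
print.dp_table <- function(x, ...) {
  cat("<dp_table> bag {", paste(x$bag, collapse = ","), "}, ",
      nrow(x$entries), " entries\n", sep = "")
  print(utils::head(x$entries, 20L), row.names = FALSE)
  if (nrow(x$entries) > 20L) cat("...\n")
  invisible(x)
}

#' Longest antisymmetric partial path via the path-decomposition DP
#'
#' Fills a dynamic programming table for every node of the augmented path
#' decomposition from left to right, takes the maximum-length entry of the
#' right-end table, and traces back the selected vertices. Length ties are
#' broken deterministically toward the structure of smaller total selected
#' mass (in the worked two-residue example this picks the reading whose
#' first peak has the smaller mass).
#'
#' @param g a \code{spectrum_graph}.
#' @param pd optional \code{path_decomposition}; when missing the solver
#'   builds its own span-aware pair decomposition (fastest and always
#'   safe). A supplied decomposition is conflict-completed first.
#' @param keep_tables retain per-node tables in the result (for debugging
#'   dumps).
#' @param max_bag hard cap on concurrent bag slots (mask width).
#' @return object of class \code{antisym_path}: list with \code{segments}
#'   (list of vertex-id vectors, ascending mass), \code{total_length} and
#'   \code{selected} (all selected vertex ids).
#' @examples
#' tab <- residue_table()
#' s <- spectrum(c(57.02146, 71.03711), 1, total_mass = 128.05857)
#' g <- build_graph(s, tab, tol = 0.001)
#' p <- solve_lapp(g)
#' p$total_length  # 2: source -> 57.02 -> sink
#' @export
solve_lapp <- function(g, pd = NULL, keep_tables = FALSE, max_bag = 52L) {
  n <- nrow(g$vertices)
  so <- source_id(g); si <- sink_id(g)
  width <- NA_integer_
  canonical <- FALSE
  if (is.null(pd)) {
    pd <- augment_source_sink(solver_decomposition(g), g)
    canonical <- TRUE
  } else {
    width <- pd$width
    if (!isTRUE(pd$augmented)) pd <- augment_source_sink(pd, g)
  }
  iv <- pd_intervals(pd, n)
  if (anyNA(iv$first)) stop("decomposition does not cover all vertices")
  iv <- complete_conflicts(iv$first, iv$last, g, edge_spans(g))
  # conflict completion of an unfavourable decomposition can inflate the
  # bags past the solver's mask width; rebuild with the solver's own
  # span-aware pair decomposition in that case (the optimum is unaffected)
  if (!canonical) {
    occ <- integer(max(iv$last))
    for (v in seq_len(n)) {
      occ[iv$first[v]:iv$last[v]] <- occ[iv$first[v]:iv$last[v]] + 1L
    }
    if (max(occ) > max_bag - 2L) {
      pd <- augment_source_sink(solver_decomposition(g), g)
      canonical <- TRUE
      iv <- pd_intervals(pd, n)
      iv <- complete_conflicts(iv$first, iv$last, g, edge_spans(g))
    }
  }
  steps <- sweep_steps(iv$first, iv$last, g$vertices$mass, so, si)
  sw <- dp_sweep(g, steps, max_bag = max_bag, canonical = canonical)

  # table-size bound: 2^(p-2) * (p+1) with p the bag size
  p <- pmax(sw$bag_sizes, 2L)
  if (any(sw$entry_counts > 2^(p - 2) * (p + 1))) {
    stop("internal error: DP table exceeded its size bound")
  }

  final <- sw$tables[[length(sw$tables)]]$tab
  if (!length(final$mask)) stop("internal error: empty final DP table")
  best <- order(-final$len, final$nsel, final$msum)[1L]
  selected <- dp_traceback(sw, best)
  res <- build_antisym_path(g, selected)
  if (res$total_length != final$len[best]) {
    stop("internal error: traceback length mismatch (",
         res$total_length, " vs ", final$len[best], ")")
  }
  attr(res, "width") <- width
  if (keep_tables) attr(res, "tables") <- sw
  res
}

# assemble an antisym_path from a selected vertex set: segments are the
# maximal runs of mass-consecutive vertices joined by directed edges;
# isolated non-terminal vertices are dropped (re-joining their neighbors)
build_antisym_path <- function(g, selected) {
  so <- source_id(g); si <- sink_id(g)
  mass <- g$vertices$mass
  keep <- selected[order(mass[selected])]
  edge_ok <- function(a, b) any(g$edges$from == a & g$edges$to == b)
  repeat {
    if (length(keep) < 2L) break
    joined <- vapply(seq_len(length(keep) - 1L), function(i) {
      edge_ok(keep[i], keep[i + 1])
    }, logical(1))
    iso <- vapply(seq_along(keep), function(i) {
      left <- i > 1L && joined[i - 1L]
      right <- i <= length(joined) && joined[i]
      !(left || right) && !(keep[i] %in% c(so, si))
    }, logical(1))
    if (!any(iso)) break
    keep <- keep[!iso]
  }
  segments <- list()
  cur <- keep[1]
  if (length(keep) > 1L) {
    for (i in 2:length(keep)) {
      if (edge_ok(keep[i - 1], keep[i])) {
        cur <- c(cur, keep[i])
      } else {
        segments[[length(segments) + 1L]] <- cur
        cur <- keep[i]
      }
    }
  }
  segments[[length(segments) + 1L]] <- cur
  structure(
    list(segments = segments,
         total_length = sum(lengths(segments) - 1L),
         selected = keep),
    class = "antisym_path"
  )
}

#' @export
print.antisym_path <- function(x, ...) {
  cat("<antisym_path> length ", x$total_length, ", ",
      length(x$segments), " segment(s)\n", sep = "")
  for (s in x$segments) cat("  [", paste(s, collapse = " -> "), "]\n")
  invisible(x)
}

#' Check the structural invariants of an antisymmetric partial path
#'
#' @param p an \code{antisym_path}.
#' @param g the graph it lives in.
#' @return TRUE or a character vector of violations.
#' @export
validate_antisym_path <- function(p, g) {
  probs <- character()
  mass <- g$vertices$mass
  so <- source_id(g); si <- sink_id(g)
  edge_ok <- function(a, b) any(g$edges$from == a & g$edges$to == b)
  for (seg in p$segments) {
    if (length(seg) > 1L) {
      for (i in seq_len(length(seg) - 1L)) {
        if (!edge_ok(seg[i], seg[i + 1])) {
          probs <- c(probs, paste0("segment step ", seg[i], "->",
                                   seg[i + 1], " is not a directed edge"))
        }
      }
    } else if (!seg %in% c(so, si)) {
      probs <- c(probs, paste0("singleton segment at non-terminal ", seg))
    }
  }
  allv <- unlist(p$segments)
  if (anyDuplicated(allv)) probs <- c(probs, "segments are not disjoint")
  cp <- complement_pairs(g)
  if (nrow(cp)) {
    both <- cp[, 1] %in% allv & cp[, 2] %in% allv
    if (any(both)) {
      probs <- c(probs, paste0("complement pair {", cp[which(both)[1], 1],
                               ",", cp[which(both)[1], 2], "} selected"))
    }
  }
  if (length(p$segments) > 1L) {
    lo <- vapply(p$segments, function(s) min(mass[s]), numeric(1))
    hi <- vapply(p$segments, function(s) max(mass[s]), numeric(1))
    if (is.unsorted(lo) || any(hi[-length(hi)] >= lo[-1])) {
      probs <- c(probs, "segment mass intervals overlap or are unordered")
    }
  }
  if (p$segments[[1]][1] != so) probs <- c(probs, "first segment misses source")
  lastseg <- p$segments[[length(p$segments)]]
  if (lastseg[length(lastseg)] != si) {
    probs <- c(probs, "last segment does not end at sink")
  }
  tl <- sum(lengths(p$segments) - 1L)
  if (tl != p$total_length) probs <- c(probs, "total_length mismatch")
  if (length(probs)) probs else TRUE
}

#' Brute-force longest antisymmetric partial path (test oracle)
#'
#' Exhaustive enumeration over peak-vertex subsets (source and sink always
#' included), checking each candidate directly against the definition: the
#' mass-sorted selection splits into segments at consecutive pairs without
#' a directed edge; a valid structure selects no complementary pair and has
#' singleton segments only at the terminals; its length is the number of
#' edge-joined consecutive pairs. Independent of the decomposition DP.
#'
#' @param g a \code{spectrum_graph} with at most \code{max_vertices}
#'   vertices.
#' @param max_vertices size guard.
#' @return an \code{antisym_path} of maximum total length.
#' @export
brute_force_lapp <- function(g, max_vertices = 12L) {
  n <- nrow(g$vertices)
  if (n > max_vertices) {
    stop("brute_force_lapp limited to ", max_vertices, " vertices, got ", n)
  }
  so <- source_id(g); si <- sink_id(g)
  peaks <- setdiff(seq_len(n), c(so, si))
  mass <- g$vertices$mass
  cp <- complement_pairs(g)
  emat <- matrix(FALSE, n, n)
  if (nrow(g$edges)) {
    emat[cbind(g$edges$from, g$edges$to)] <- TRUE
  }
  best_len <- -1L; best_sel <- NULL; best_nsel <- Inf; best_msum <- Inf
  for (m in 0:(2^length(peaks) - 1)) {
    sel <- c(so, si, peaks[bitwAnd(bitwShiftR(m, seq_along(peaks) - 1L),
                                   1L) == 1L])
    if (nrow(cp) && any(cp[, 1] %in% sel & cp[, 2] %in% sel)) next
    sel <- sel[order(mass[sel])]
    k <- length(sel)
    joined <- if (k > 1L) emat[cbind(sel[-k], sel[-1])] else logical(0)
    # singleton segments are only allowed at the terminals
    iso <- !(c(FALSE, joined) | c(joined, FALSE)) & !(sel %in% c(so, si))
    if (any(iso)) next
    len <- sum(joined)
    msum <- sum(mass[sel])
    if (len > best_len ||
        (len == best_len && (k < best_nsel ||
                             (k == best_nsel && msum < best_msum)))) {
      best_len <- len; best_sel <- sel; best_nsel <- k; best_msum <- msum
    }
  }
  build_antisym_path(g, best_sel)
}

# longest source->sink path ignoring complement edges (independent check
# for the no-complement special case)
longest_path_dag <- function(g) {
  so <- source_id(g); si <- sink_id(g)
  n <- nrow(g$vertices)
  ord <- order(g$vertices$mass)
  dist <- rep(-Inf, n)
  dist[so] <- 0
  adj <- graph_adjacency(g)
  for (v in ord) {
    if (!is.finite(dist[v])) next
    for (w in adj$out[[v]]) dist[w] <- max(dist[w], dist[v] + 1)
  }
  dist[si]
}

#' Write DP tables of a solve run as text
#'
#' @param p result of \code{solve_lapp(..., keep_tables = TRUE)}.
#' @param path output file; one line per entry (node, bag, sel bits, L,
#'   len).
#' @export
write_dp_tables <- function(p, path) {
  sw <- attr(p, "tables")
  if (is.null(sw)) stop("solve_lapp was not run with keep_tables = TRUE")
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seq_along(sw$tables)) {
    tb <- sw$tables[[s]]
    bag <- sort(tb$bag)
    slots <- tb$slots[match(bag, tb$bag)]
    slot_bits <- ifelse(slots > 0L, 2^(slots - 1L), 0)
    for (i in seq_along(tb$tab$mask)) {
      bits <- paste(as.integer(d_and(tb$tab$mask[i], slot_bits) != 0),
                    collapse = "")
      writeLines(sprintf("node %d bag {%s} sel %s L %d len %d", s,
                         paste(bag, collapse = ","), bits, tb$tab$Lv[i],
                         tb$tab$len[i]), con)
    }
  }
  invisible(path)
}
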