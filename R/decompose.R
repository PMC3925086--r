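## Path decomposition of the extended spectrum graph.
##
## A path decomposition is an ordered sequence of vertex bags covering all
## vertices and edges, with each vertex occupying a contiguous run of bags;
## its width is (max bag size - 1). Both directed and complement edges count
## as adjacency. Decompositions are produced from vertex orderings: the
## ordering's boundary sets (vertices already placed that still have an
## unplaced neighbor) are exactly the bags, and the best achievable width
## over all orderings is the vertex separation number, which equals the
## pathwidth.

#' Compute a path decomposition of a spectrum graph
#'
#' The default strategy orders vertices greedily, repeatedly placing the
#' vertex that minimizes the size of the active boundary (ties broken by
#' ascending mass, making the result deterministic). Graphs with at most
#' \code{exact_limit} vertices are decomposed optimally by the
#' branch-and-bound of \code{\link{exact_pathwidth}}.
#'
#' @param g a \code{spectrum_graph}.
#' @param strategy "greedy" (boundary-minimizing ordering), "exact"
#'   (optimal, size-guarded) or "mass" (ascending-mass ordering, mostly a
#'   baseline for comparison).
#' @param exact_limit graphs with at most this many vertices use the exact
#'   ordering even under the greedy strategy.
#' @return object of class \code{path_decomposition}: list with \code{bags}
#'   (list of integer vertex-id vectors), \code{width}, \code{order} (the
#'   vertex ordering used) and \code{augmented} flag.
#' @export
decompose <- function(g, strategy = c("greedy", "exact", "mass"),
                      exact_limit = 14L) {
  strategy <- match.arg(strategy)
  n <- nrow(g$vertices)
  adj <- mixed_adjacency(g)
  ord <- switch(strategy,
    mass = order(g$vertices$mass),
    exact = exact_separation_order(adj, n),
    greedy = if (n <= exact_limit) {
      exact_separation_order(adj, n)
    } else {
      greedy_separation_order(adj, g$vertices$mass)
    })
  pd_from_order(ord, adj, n)
}

# mixed adjacency augmented so that each directed edge's endpoints and the
# vertices strictly inside its mass span form a clique: a decomposition of
# this graph brings every edge-decision group into a common bag, which is
# what the partial-path solver needs (see dp.R)
span_adjacency <- function(g, adj = mixed_adjacency(g)) {
  mass <- g$vertices$mass
  for (k in seq_len(nrow(g$edges))) {
    u <- g$edges$from[k]; v <- g$edges$to[k]
    W <- setdiff(which(mass > mass[u] & mass < mass[v]), c(u, v))
    grp <- c(u, v, W)
    if (length(grp) > 2L) {
      for (a in grp) adj[[a]] <- c(adj[[a]], setdiff(grp, a))
    }
  }
  lapply(adj, function(x) sort(unique(x)))
}

# Decomposition used internally by the solver: the outside-in pair
# ordering (ascending min(m, M - m), complement partners adjacent, low
# member first), with bags taken over the span-augmented adjacency so that
# every edge-decision group shares a bag. This ordering is shell-monotone
# -- low-side masses ascend, high-side masses descend -- which licenses
# the solver's canonical entry merging (see dp.R).
solver_decomposition <- function(g) {
  n <- nrow(g$vertices)
  mass <- g$vertices$mass
  M <- g$total_mass
  s <- pmin(mass, M - mass)
  ord <- order(s, mass)
  pd_from_order(ord, span_adjacency(g), n)
}

# Greedy boundary-minimizing vertex ordering. cnt_out[u] tracks the number
# of u's neighbors not yet placed; the boundary is {placed u: cnt_out[u]>0}.
greedy_separation_order <- function(adj, mass) {
  n <- length(adj)
  placed <- logical(n)
  cnt_out <- lengths(adj)
  in_boundary <- logical(n)
  b_now <- 0L
  ord <- integer(n)
  for (step in seq_len(n)) {
    cand <- which(!placed)
    best <- NA_integer_; best_b <- .Machine$integer.max
    for (v in cand) {
      leavers <- 0L
      for (u in adj[[v]]) {
        if (placed[u] && cnt_out[u] == 1L) leavers <- leavers + 1L
      }
      # cnt_out[v] counts unplaced neighbors of v; placing v does not
      # change that count, so it is v's outside degree after placement
      b_new <- b_now - leavers + (if (cnt_out[v] > 0L) 1L else 0L)
      if (b_new < best_b ||
          (b_new == best_b && mass[v] < mass[best])) {
        best <- v; best_b <- b_new
      }
    }
    v <- best
    placed[v] <- TRUE
    ord[step] <- v
    for (u in adj[[v]]) {
      cnt_out[u] <- cnt_out[u] - 1L
    }
    in_boundary[v] <- cnt_out[v] > 0L
    for (u in adj[[v]]) {
      if (placed[u] && cnt_out[u] == 0L) in_boundary[u] <- FALSE
    }
    b_now <- sum(in_boundary[placed])
  }
  ord
}

# bags from a vertex ordering: B_i = {ord_i} + placed vertices that still
# have a neighbor at position >= i
pd_from_order <- function(ord, adj, n) {
  pos <- integer(n)
  pos[ord] <- seq_len(n)
  last_nbr_pos <- vapply(seq_len(n), function(v) {
    if (length(adj[[v]])) max(pos[adj[[v]]]) else pos[v]
  }, integer(1))
  bags <- vector("list", n)
  for (i in seq_len(n)) {
    v <- ord[i]
    earlier <- ord[seq_len(i - 1L)]
    keep <- earlier[last_nbr_pos[earlier] >= i]
    bags[[i]] <- sort(c(keep, v))
  }
  structure(
    list(bags = bags, width = max(lengths(bags)) - 1L, order = ord,
         augmented = FALSE),
    class = "path_decomposition"
  )
}

#' @export
print.path_decomposition <- function(x, ...) {
  cat("<path_decomposition> ", length(x$bags), " bags, width ", x$width,
      if (isTRUE(x$augmented)) " (source/sink augmented)", "\n", sep = "")
  invisible(x)
}

#' Validate a path decomposition
#'
#' Checks vertex coverage, edge coverage (both directed and complement
#' edges) and contiguity of each vertex's bag run.
#'
#' @param pd a \code{path_decomposition}.
#' @param g the \code{spectrum_graph} it should decompose.
#' @return TRUE when valid, otherwise a character vector of violations with
#'   witnesses.
#' @export
validate_decomposition <- function(pd, g) {
  probs <- character()
  n <- nrow(g$vertices)
  allv <- sort(unique(unlist(pd$bags)))
  missing <- setdiff(seq_len(n), allv)
  if (length(missing)) {
    probs <- c(probs, paste0("coverage: vertex ", missing[1],
                             " in no bag"))
  }
  pairs <- rbind(as.matrix(g$edges[, c("from", "to")]),
                 as.matrix(g$complements))
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      ok <- any(vapply(pd$bags, function(b) {
        all(pairs[k, ] %in% b)
      }, logical(1)))
      if (!ok) {
        probs <- c(probs, paste0("edge coverage: {", pairs[k, 1], ",",
                                 pairs[k, 2], "} in no common bag"))
      }
    }
  }
  for (v in allv) {
    hit <- which(vapply(pd$bags, function(b) v %in% b, logical(1)))
    if (length(hit) && !identical(hit, seq(min(hit), max(hit)))) {
      probs <- c(probs, paste0("contiguity: vertex ", v,
                               " occurs in non-contiguous bags"))
    }
  }
  if (length(probs)) probs else TRUE
}

#' Add source and sink to every bag
#'
#' The partial-path dynamic program requires the source and the sink in
#' every bag; this can raise the reported width by at most 2.
#'
#' @param pd a \code{path_decomposition}.
#' @param g the decomposed \code{spectrum_graph}.
#' @return augmented \code{path_decomposition}.
#' @export
augment_source_sink <- function(pd, g) {
  so <- source_id(g); si <- sink_id(g)
  bags <- lapply(pd$bags, function(b) sort(unique(c(b, so, si))))
  structure(
    list(bags = bags, width = max(lengths(bags)) - 1L, order = pd$order,
         augmented = TRUE),
    class = "path_decomposition"
  )
}

# Optimal vertex ordering (vertex separation number) by subset dynamic
# programming: f(S) = max(boundary(S), min_{v in S} f(S \ v)), processed in
# ascending mask order (every S \ v is numerically smaller than S). Fully
# vectorized over subsets; guarded to small n.
exact_separation_order <- function(adj, n) {
  if (n > 16L) stop("exact ordering limited to 16 vertices, got ", n)
  bits <- as.integer(2^(seq_len(n) - 1))
  nbr_mask <- vapply(seq_len(n), function(v) {
    as.integer(sum(2^(adj[[v]] - 1)))
  }, integer(1))
  full <- as.integer(2^n - 1)
  S_all <- 0:full
  # boundary size per subset: members with a neighbor outside S
  b <- integer(full + 1L)
  for (v in seq_len(n)) {
    inS <- bitwAnd(S_all, bits[v]) != 0L
    out <- bitwAnd(rep(nbr_mask[v], full + 1L), full - S_all) != 0L
    b <- b + as.integer(inS & out)
  }
  f <- rep(Inf, full + 1L)
  choice <- integer(full + 1L)
  f[1] <- 0
  pred_best <- rep(Inf, full + 1L)
  # process by popcount layers so predecessor values are final
  pc <- b
  pc[] <- 0L
  for (v in seq_len(n)) {
    pc <- pc + as.integer(bitwAnd(S_all, bits[v]) != 0L)
  }
  for (k in seq_len(n)) {
    Sk <- S_all[pc == k]
    best <- rep(Inf, length(Sk))
    bestv <- integer(length(Sk))
    for (v in seq_len(n)) {
      has <- bitwAnd(Sk, bits[v]) != 0L
      if (!any(has)) next
      pred <- f[Sk[has] - bits[v] + 1L]
      better <- pred < best[has]
      if (any(better)) {
        idx <- which(has)[better]
        best[idx] <- pred[better]
        bestv[idx] <- v
      }
    }
    f[Sk + 1L] <- pmax(b[Sk + 1L], best)
    choice[Sk + 1L] <- bestv
  }
  ord <- integer(n)
  S <- full
  for (i in n:1) {
    v <- choice[S + 1L]
    ord[i] <- v
    S <- S - bits[v]
  }
  ord
}

#' Minimum pathwidth of a small graph
#'
#' Exact pathwidth via dynamic programming over vertex subsets (the vertex
#' separation number of the best ordering, which equals the pathwidth).
#' Intended as a test oracle; guarded to graphs with at most 14 vertices.
#'
#' @param g a \code{spectrum_graph}.
#' @param max_vertices size guard.
#' @return integer pathwidth.
#' @export
exact_pathwidth <- function(g, max_vertices = 14L) {
  n <- nrow(g$vertices)
  if (n > max_vertices) {
    stop("exact_pathwidth limited to ", max_vertices, " vertices, got ", n)
  }
  adj <- mixed_adjacency(g)
  ord <- exact_separation_order(adj, n)
  pd_from_order(ord, adj, n)$width
}

#' Write a decomposition dump (one bag per line)
#' @param pd a \code{path_decomposition}.
#' @param path output file.
#' @export
write_decomposition <- function(pd, path) {
  writeLines(vapply(pd$bags, paste, "", collapse = " "), path)
  invisible(path)
}
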