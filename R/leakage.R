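#' Short-band adjacency of a circuit
#'
#' Neighbour lists over the vertices of a circuit, restricted to pairs
#' within the short distance band.  This sub-graph is expected to coincide
#' with the intended computational DAG of the design; any extra short
#' edges are shortcuts or leaks.
#'
#' @param c a \code{walker_circuit}.
#' @param params a \code{\link{distance_params}} object.
#' @return list (one element per vertex, in the circuit's lexicographic
#'   (x, y) vertex order) of integer vectors of neighbour row indices,
#'   each sorted in that same order.
#' @export
short_adjacency <- function(c, params = distance_params()) {
  v <- c$vertices
  n <- nrow(v)
  d2 <- outer(v$x, v$x, "-")^2 + outer(v$y, v$y, "-")^2
  lapply(seq_len(n), function(i) {
    nb <- which(d2[i, ] <= params$dS^2 & d2[i, ] > 0)
    sort(nb)
  })
}

#' BFS successors of a place during indexing
#'
#' Given the current index assignment, the successors of vertex \code{x}
#' are its short-band neighbours \code{y} with \code{index(y) !=
#' index(x)} and (\code{index(y) == 0} or \code{index(y) != index(x) \%/\%
#' 2}); the second clause prevents walking back from a fork child (index
#' \code{2c} or \code{2c + 1}) to its parent (index \code{c}, integer
#' division).  Returned in lexicographic (x, y) position order.
#'
#' @param x vertex row index.
#' @param idx integer vector of current indices (0 = unindexed).
#' @param adj short adjacency list from \code{\link{short_adjacency}}.
#' @return integer vector of successor row indices.
#' @export
bfs_successors <- function(x, idx, adj) {
  nb <- adj[[x]]
  nb[idx[nb] != idx[x] & (idx[nb] == 0 | idx[nb] != idx[x] %/% 2)]
}

add_triple <- function(M, pre, post, type) {
  key <- paste(pre, post, type)
  if (!key %in% M$key)
    M[nrow(M) + 1L, ] <- list(as.integer(pre), as.integer(post), type, key)
  M
}

#' Index the places of a circuit's short-distance sub-graph
#'
#' Breadth-first search from the INIT vertex (index 1) that labels every
#' vertex with a positive integer index following the array embedding of a
#' binary decision DAG: a linear track shares one index, the two children
#' of a fork with index \code{c} receive \code{2c} and \code{2c + 1}, and
#' joins merge branches back.  While indexing, the algorithm collects the
#' set M of known transition types, triples (pre-index, post-index, type)
#' with type TRACK, FORK, JOIN or LEAK, which later drives the
#' classification of every stepping transition of the unfolded net.
#'
#' The BFS distinguishes six situations: the INIT place (one successor,
#' same index, TRACK); FORK places (two successors, indices \code{2c} and
#' \code{2c + 1}, FORK); JOIN places (undecidable successor treated
#' symmetrically, same index, TRACK); NORM places with two short
#' neighbours (track continuation, entry into a join, re-encounter of an
#' indexed join, or index override when backtracking onto an earlier
#' track); NORM places with three short neighbours (the same sub-cases
#' with an extra "marked" flag, plus LEAK triples for unmarked indexed
#' successors); FINAL places terminate branches.  Any configuration
#' outside these cases stops with an ambiguity error naming the vertex.
#'
#' @param c a \code{walker_circuit}.
#' @param params a \code{\link{distance_params}} object.
#' @param fork_order which fork successor receives the doubled index:
#'   the first in lexicographic position order (\code{"position"}, the
#'   default and the package's deterministic convention) or the second
#'   (\code{"swapped"}).  The classification table is invariant under
#'   this choice; the alternative order exists to assert exactly that.
#' @return list with \code{index} (named integer vector, vertex id ->
#'   index), \code{M} (data.frame \code{pre}, \code{post}, \code{type}),
#'   \code{marked} (character vector of marked vertex ids).
#' @export
index_places <- function(c, params = distance_params(),
                         fork_order = c("position", "swapped")) {
  fork_order <- match.arg(fork_order)
  v <- c$vertices
  n <- nrow(v)
  adj <- short_adjacency(c, params)
  idx <- integer(n)
  marked <- logical(n)
  M <- data.frame(pre = integer(), post = integer(),
                  type = character(), key = character(),
                  stringsAsFactors = FALSE)
  ambiguous <- function(i, case) {
    stop(sprintf("indexing ambiguity at vertex '%s' (%s, %s)",
                 v$id[i], v$type[i], case), call. = FALSE)
  }

  start <- which(v$type == "INIT")
  idx[start] <- 1L
  queue <- c(start)
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    tx <- v$type[x]
    succ <- bfs_successors(x, idx, adj)
    if (tx == "FINAL") {
      next                                   # branches end at finals
    } else if (tx == "INIT") {
      un <- succ[idx[succ] == 0]
      if (length(adj[[x]]) != 1 || length(un) > 1)
        ambiguous(x, "INIT must have exactly one successor")
      if (length(un)) {
        idx[un] <- idx[x]
        M <- add_triple(M, idx[x], idx[x], "TRACK")
        queue <- c(queue, un)
      }
    } else if (tx == "FORK") {
      if (length(adj[[x]]) != 3)
        ambiguous(x, sprintf("fork needs 3 short neighbours, has %d",
                             length(adj[[x]])))
      un <- succ[idx[succ] == 0]
      if (length(un) != 2)
        ambiguous(x, "fork needs two unindexed successors")
      if (fork_order == "swapped") un <- rev(un)
      idx[un[1]] <- 2L * idx[x]
      idx[un[2]] <- 2L * idx[x] + 1L
      M <- add_triple(M, idx[x], idx[un[1]], "FORK")
      M <- add_triple(M, idx[x], idx[un[2]], "FORK")
      queue <- c(queue, un)
    } else if (tx == "JOIN") {
      if (length(adj[[x]]) != 3)
        ambiguous(x, sprintf("join needs 3 short neighbours, has %d",
                             length(adj[[x]])))
      un <- succ[idx[succ] == 0]
      for (y in un) {                        # successor undecidable: treat
        idx[y] <- idx[x]                     # unindexed neighbours alike
        M <- add_triple(M, idx[x], idx[x], "TRACK")
        queue <- c(queue, y)
      }
    } else if (tx == "NORM" && length(adj[[x]]) == 2) {
      for (y in succ) {
        if (idx[y] == 0 && v$type[y] == "JOIN") {
          idx[y] <- 2L * idx[x]
          M <- add_triple(M, idx[x], idx[y], "JOIN")
          queue <- c(queue, y)
        } else if (idx[y] == 0) {
          idx[y] <- idx[x]
          M <- add_triple(M, idx[x], idx[y], "TRACK")
          queue <- c(queue, y)
        } else if (v$type[y] == "JOIN") {
          # re-encountered an indexed join from the second incoming track
          M <- add_triple(M, idx[x], idx[y], "JOIN")
        } else if (idx[y] < idx[x]) {
          # backtracked onto a previously visited track: override
          idx[y] <- idx[x]
          M <- add_triple(M, idx[x], idx[y], "TRACK")
          queue <- c(queue, y)
        } else {
          ambiguous(x, sprintf("no track case applies for neighbour '%s'",
                               v$id[y]))
        }
      }
    } else if (tx == "NORM" && length(adj[[x]]) == 3) {
      for (y in succ) {
        if (idx[y] == 0 && v$type[y] == "JOIN") {
          idx[y] <- 2L * idx[x]
          M <- add_triple(M, idx[x], idx[y], "JOIN")
          queue <- c(queue, y)
          marked[y] <- TRUE
        } else if (idx[y] == 0) {
          idx[y] <- idx[x]
          M <- add_triple(M, idx[x], idx[y], "TRACK")
          queue <- c(queue, y)
          marked[y] <- TRUE
        } else if (marked[y] && v$type[y] == "JOIN") {
          M <- add_triple(M, idx[x], idx[y], "JOIN")
        } else if (marked[y]) {
          if (idx[y] < idx[x]) {             # corner with shortcuts
            idx[y] <- idx[x]
            queue <- c(queue, y)
          }
          M <- add_triple(M, idx[x], idx[y], "TRACK")
        } else {
          M <- add_triple(M, idx[x], idx[y], "LEAK")
        }
      }
    } else {
      ambiguous(x, sprintf("%d short neighbours", length(adj[[x]])))
    }
  }
  if (any(idx == 0))
    stop("indexing incomplete: unreached vertices ",
         paste(v$id[idx == 0], collapse = ", "), call. = FALSE)
  list(index = stats::setNames(idx, v$id),
       M = M[, c("pre", "post", "type")],
       marked = v$id[marked])
}

#' Classify the stepping transitions of an unfolded net
#'
#' Every stepping transition (regular or final step, any distance band) is
#' looked up in the set M of known transition types by the index pair of
#' its source and target vertex, in either order; a match inherits the
#' recorded structural type (TRACK, FORK or JOIN, or a recorded LEAK), and
#' every non-matching transition is a leak.  Combined with the distance
#' band this yields a 12-way classification.  Loop, block and fail
#' transitions are not stepping transitions and are excluded.
#'
#' @param net a \code{gspn} from \code{\link{unfold_gspn}}.
#' @param indexing result of \code{\link{index_places}} on the same
#'   circuit (or a compatible list with \code{index} and \code{M}).
#' @return list with \code{table} (4 x 4 integer matrix, rows Track, Fork,
#'   Join, Leak; columns Short, Medium, Long, Sigma), and
#'   \code{transitions}: the net's stepping transitions with a
#'   \code{structural} and \code{class} column added.
#' @export
classify_transitions <- function(net, indexing) {
  idx <- indexing$index
  M <- indexing$M
  tr <- net$transitions
  tr <- tr[tr$role %in% c("STEP", "FINALSTEP"), , drop = FALSE]
  keys <- c(paste(M$pre, M$post), paste(M$post, M$pre))
  types <- c(M$type, M$type)
  # first match wins; M is generated deterministically
  look <- paste(idx[tr$source], idx[tr$target])
  hit <- match(look, keys)
  tr$structural <- ifelse(is.na(hit), "LEAK", types[hit])
  tr$class <- paste(tr$structural, tr$category, sep = "-")
  tab <- matrix(0L, 4, 4,
                dimnames = list(c("Track", "Fork", "Join", "Leak"),
                                c("Short", "Medium", "Long", "Sigma")))
  rows <- c(TRACK = "Track", FORK = "Fork", JOIN = "Join", LEAK = "Leak")
  cols <- c(SHORT = "Short", MEDIUM = "Medium", LONG = "Long")
  for (i in seq_len(nrow(tr))) {
    r <- rows[[tr$structural[i]]]; cl <- cols[[tr$category[i]]]
    tab[r, cl] <- tab[r, cl] + 1L
  }
  tab[, "Sigma"] <- rowSums(tab[, 1:3, drop = FALSE])
  list(table = tab, transitions = tr)
}

#' One-call classification of a circuit
#'
#' Convenience wrapper: unfold, index, classify.
#'
#' @inheritParams index_places
#' @param semantics stepping semantics passed to \code{\link{unfold_gspn}}.
#' @return as \code{\link{classify_transitions}}, plus \code{indexing}.
#' @export
classify_circuit <- function(c, params = distance_params(),
                             semantics = "BURNT_BRIDGES") {
  net <- unfold_gspn(c, params, semantics)
  indexing <- index_places(c, params)
  res <- classify_transitions(net, indexing)
  res$indexing <- indexing
  res
}

#' Advisory consistency check of the known-transition-type set
#'
#' The index pairs recorded in M normally follow arithmetic patterns:
#' TRACK pairs share an index; FORK pairs satisfy \code{post == 2 * pre}
#' or \code{post == 2 * pre + 1}; JOIN pairs satisfy \code{post == 2 *
#' pre} or \code{post < pre}.  Joins reached through a fork-join diamond
#' can violate the JOIN pattern, which is why classification is by lookup,
#' not by arithmetic; this report flags such triples for inspection.
#'
#' @param indexing result of \code{\link{index_places}}.
#' @return data.frame of M with a logical \code{consistent} column.
#' @export
consistency_report <- function(indexing) {
  M <- indexing$M
  ok <- vapply(seq_len(nrow(M)), function(i) {
    p <- M$pre[i]; q <- M$post[i]
    switch(M$type[i],
           TRACK = p == q,
           FORK = q == 2 * p || q == 2 * p + 1,
           JOIN = q == 2 * p || q < p,
           LEAK = TRUE)
  }, logical(1))
  M$consistent <- ok
  M
}
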