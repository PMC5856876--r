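#' Build the reachability graph of a net
#'
#' Breadth-first exploration of all markings reachable from the net's
#' initial marking (after programming with \code{\link{apply_assignment}}).
#' In \code{TIMEFREE} mode immediate and stochastic transitions interleave
#' freely (the qualitative Petri net); in \code{PRIORITY} mode enabled
#' immediate transitions pre-empt stochastic ones (the GSPN view), which
#' yields a subgraph of the time-free graph.  Exploration order is
#' deterministic: markings are expanded FIFO and transitions in their
#' creation order.
#'
#' @param net a \code{gspn} with assignment applied.
#' @param mode \code{"TIMEFREE"} or \code{"PRIORITY"}.
#' @param limit maximum number of markings before an explicit error
#'   (default 5e5, the practical bound of explicit-state exploration).
#' @return object of class \code{reachability_graph}: list with
#'   \code{markings} (integer matrix, one row per marking, columns =
#'   places), \code{arcs} (data.frame \code{from}, \code{to} marking row
#'   numbers and \code{transition} id), \code{root} (= 1), \code{places}.
#' @export
build_reachability_graph <- function(net, mode = c("PRIORITY", "TIMEFREE"),
                                     limit = 5e5) {
  mode <- match.arg(mode)
  pl <- net$places$id
  tr <- net$transitions
  nt <- nrow(tr)
  # flat arc vectors for fast enabling checks
  tIdx <- integer(0); pIdx <- integer(0); w <- integer(0)
  oIdx <- integer(0); oP <- integer(0); ow <- integer(0)
  for (k in seq_len(nt)) {
    p <- net$pre[[tr$id[k]]]; q <- net$post[[tr$id[k]]]
    tIdx <- c(tIdx, rep(k, length(p)))
    pIdx <- c(pIdx, match(names(p), pl)); w <- c(w, unname(p))
    oIdx <- c(oIdx, rep(k, length(q)))
    oP <- c(oP, match(names(q), pl)); ow <- c(ow, unname(q))
  }
  isimm <- tr$kind == "IMMEDIATE"
  t_levels <- sort(unique(tIdx))
  enabled_idx <- function(m) {
    def <- pmax(w - m[pIdx], 0L)
    bad <- rowsum(def, tIdx, reorder = TRUE)
    en <- t_levels[bad[, 1] == 0]
    if (mode == "PRIORITY") {
      imm <- en[isimm[en]]
      if (length(imm)) return(imm)
    }
    en
  }
  m0 <- unname(net$m0[pl])
  seen <- new.env(hash = TRUE, parent = emptyenv())
  markings <- vector("list", 1024L)
  markings[[1]] <- m0
  assign(paste(m0, collapse = ","), 1L, envir = seen)
  nmark <- 1L
  head <- 1L
  # pre-split arc vectors per transition (cheap firing), growable arc store
  pre_by_t <- split(seq_along(tIdx), factor(tIdx, levels = seq_len(nt)))
  post_by_t <- split(seq_along(oIdx), factor(oIdx, levels = seq_len(nt)))
  narc <- 0L
  from <- integer(1024L); to <- integer(1024L); lab <- integer(1024L)
  while (head <= nmark) {
    m <- markings[[head]]
    for (k in enabled_idx(m)) {
      m2 <- m
      sel <- pre_by_t[[k]]
      m2[pIdx[sel]] <- m2[pIdx[sel]] - w[sel]
      sel2 <- post_by_t[[k]]
      m2[oP[sel2]] <- m2[oP[sel2]] + ow[sel2]
      key <- paste(m2, collapse = ",")
      j <- seen[[key]]
      if (is.null(j)) {
        nmark <- nmark + 1L
        if (nmark > limit)
          stop("state-space limit exceeded (", limit, " markings)",
               call. = FALSE)
        if (nmark > length(markings))
          markings <- c(markings, vector("list", length(markings)))
        markings[[nmark]] <- m2
        assign(key, nmark, envir = seen)
        j <- nmark
      }
      narc <- narc + 1L
      if (narc > length(from)) {
        from <- c(from, integer(length(from)))
        to <- c(to, integer(length(to)))
        lab <- c(lab, integer(length(lab)))
      }
      from[narc] <- head; to[narc] <- j; lab[narc] <- k
    }
    head <- head + 1L
  }
  mm <- do.call(rbind, markings[seq_len(nmark)])
  colnames(mm) <- pl
  keep <- seq_len(narc)
  structure(list(markings = mm,
                 arcs = data.frame(from = from[keep], to = to[keep],
                                   transition = tr$id[lab[keep]],
                                   stringsAsFactors = FALSE),
                 root = 1L, places = pl, mode = mode),
            class = "reachability_graph")
}

#' @export
print.reachability_graph <- function(x, ...) {
  cat(sprintf("reachability_graph (%s): %d markings, %d arcs\n",
              x$mode, nrow(x$markings), nrow(x$arcs)))
  invisible(x)
}

#' Boundedness of a reachability graph
#'
#' @param rg a \code{reachability_graph}.
#' @return the smallest k such that no reachable marking puts more than k
#'   tokens on any place.
#' @export
check_bound <- function(rg) {
  max(rg$markings)
}

#' Dead states of a reachability graph
#'
#' Markings without outgoing arcs.  Because every final place carries a
#' loop transition, a walker resting on a final anchorage is never dead;
#' dead states are walkers trapped at non-final anchorages (or blocking
#' configurations with no move at all).
#'
#' @param rg a \code{reachability_graph}.
#' @return integer vector of marking row numbers that are dead.
#' @export
dead_states <- function(rg) {
  setdiff(seq_len(nrow(rg$markings)), unique(rg$arcs$from))
}

#' Strongly-connected-component summary: reversibility and liveness
#'
#' A net is reversible iff its reachability graph is strongly connected,
#' and live iff every transition labels an arc inside every terminal SCC
#' (an SCC from which no other SCC is reachable).  Burnt-bridges walker
#' nets are neither: their reachability graphs are acyclic apart from the
#' self-loops at final markings.
#'
#' @param rg a \code{reachability_graph}.
#' @param transitions character vector of all transition ids of the net
#'   (defaults to those appearing in the graph's arcs).
#' @return list \code{reversible}, \code{live}, \code{scc_count},
#'   \code{terminal_scc_count}, \code{bound}, \code{dead_count}.
#' @export
scc_analysis <- function(rg, transitions = unique(rg$arcs$transition)) {
  n <- nrow(rg$markings)
  g <- igraph::graph_from_data_frame(
    rg$arcs[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g, mode = "strong")
  member <- comp$membership
  reversible <- comp$no == 1
  # terminal SCCs: no arc leaves the component
  leaving <- member[rg$arcs$from] != member[rg$arcs$to]
  nonterminal <- unique(member[rg$arcs$from][leaving])
  terminal <- setdiff(seq_len(comp$no), nonterminal)
  live <- length(transitions) > 0
  for (s in terminal) {
    inside <- !leaving & member[rg$arcs$from] == s
    if (!all(transitions %in% rg$arcs$transition[inside])) {
      live <- FALSE
      break
    }
  }
  list(reversible = reversible, live = live,
       scc_count = comp$no, terminal_scc_count = length(terminal),
       bound = check_bound(rg), dead_count = length(dead_states(rg)))
}

#' Full qualitative report for one input assignment
#'
#' @param net a \code{gspn} (assignment applied or not).
#' @param a optional assignment to apply first.
#' @param mode exploration mode, see
#'   \code{\link{build_reachability_graph}}.
#' @param limit state-space limit.
#' @return list: the \code{scc_analysis} fields plus \code{n_markings},
#'   \code{n_arcs} and the graph itself.
#' @export
qualitative_report <- function(net, a = NULL, mode = "TIMEFREE",
                               limit = 5e5) {
  if (!is.null(a)) net <- apply_assignment(net, a)
  rg <- build_reachability_graph(net, mode, limit)
  rep <- scc_analysis(rg, transitions = net$transitions$id)
  rep$n_markings <- nrow(rg$markings)
  rep$n_arcs <- nrow(rg$arcs)
  rep$graph <- rg
  rep
}

#' Export a reachability graph to DOT
#'
#' @param rg a \code{reachability_graph}.
#' @param path output file.
#' @return invisibly \code{path}.
#' @export
export_dot <- function(rg, path) {
  lines <- c("digraph reachability {",
             sprintf("  m%d;", seq_len(nrow(rg$markings))),
             sprintf("  m%d -> m%d [label=\"%s\"];",
                     rg$arcs$from, rg$arcs$to, rg$arcs$transition),
             "}")
  writeLines(lines, path)
  invisible(path)
}
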