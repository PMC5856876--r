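#' Unfold a walker circuit into a generalised stochastic Petri net
#'
#' The unfolding realises the grid-based walker model as a plain GSPN.
#' Each vertex becomes an anchorage place \code{A_<id>} holding one
#' availability token; the INIT place holds a second token representing
#' the walker.  For every ordered pair of vertices (u, v) with u non-final
#' and distance within the long band, a stochastic stepping transition is
#' generated with the rate of its distance band; steps into finals are
#' marked \code{FINALSTEP} (finals are never sources: a walker cannot
#' leave a final anchorage).  Arc weights encode the stepping semantics:
#' \describe{
#'   \item{burnt-bridges}{the step consumes both tokens of the source (the
#'     walker and the availability token, so the source can never be
#'     revisited) plus the availability token of the target, and puts two
#'     tokens on the target.}
#'   \item{unguided}{as above, but one token is returned to the source,
#'     which therefore stays visitable.}
#' }
#' Each final place gets a \code{LOOP} transition (weight-2 self-loop)
#' that keeps final markings non-dead, so dead states signal a genuinely
#' trapped walker.  The blocking fault model adds, per labelled (non-eps,
#' non-final) vertex w, a control place \code{B_<w>} and an immediate
#' conflict pair: \code{BLOCK} (weight 0.7) consumes the control token and
#' the availability token of w, \code{FAIL} (weight 0.3) consumes only the
#' control token and leaves w visitable.  Immediate transitions fire with
#' highest priority and zero delay.
#'
#' @param c a validated \code{walker_circuit}.
#' @param params a \code{\link{distance_params}} object.
#' @param semantics \code{"BURNT_BRIDGES"} or \code{"UNGUIDED"}.
#' @param block_weight probability that blocking a labelled anchorage
#'   succeeds (its FAIL twin gets \code{1 - block_weight}).
#' @return an object of class \code{gspn}: list with data.frames
#'   \code{places} (id, kind, vertex) and \code{transitions} (id, kind,
#'   rate, weight, role, source, target, vertex, category), arc lists
#'   \code{pre}/\code{post} (per transition, named integer weight
#'   vectors), initial marking \code{m0}, and \code{semantics}.
#' @export
unfold_gspn <- function(c, params = distance_params(),
                        semantics = c("BURNT_BRIDGES", "UNGUIDED"),
                        block_weight = 0.7) {
  semantics <- match.arg(semantics)
  stopifnot(block_weight >= 0, block_weight <= 1)
  validate_circuit(c)
  v <- c$vertices                         # already in (x, y) order
  n <- nrow(v)
  aplace <- paste0("A_", v$id)
  labelled <- v$type != "FINAL" &
    vapply(v$label, function(l) !parse_label(l)$eps, logical(1))
  bplace <- if (any(labelled)) paste0("B_", v$id[labelled]) else character(0)

  places <- data.frame(
    id = c(aplace, bplace),
    kind = c(rep("ANCHORAGE", n), rep("BLOCKCTRL", sum(labelled))),
    vertex = c(v$id, v$id[labelled]),
    stringsAsFactors = FALSE)

  trs <- list(); pre <- list(); post <- list()
  addt <- function(id, kind, rate, weight, role, source, target, vertex,
                   category, p, q) {
    trs[[length(trs) + 1L]] <<- data.frame(
      id = id, kind = kind, rate = rate, weight = weight, role = role,
      source = source, target = target, vertex = vertex,
      category = category, stringsAsFactors = FALSE)
    pre[[id]] <<- p
    post[[id]] <<- q
  }

  for (i in seq_len(n)) {
    if (v$type[i] == "FINAL") next
    for (j in seq_len(n)) {
      if (i == j) next
      d2 <- squared_distance(v$x[i], v$y[i], v$x[j], v$y[j])
      if (d2 > params$dL^2) next
      cat_ <- step_category(v$x[i], v$y[i], v$x[j], v$y[j], params)
      role <- if (v$type[j] == "FINAL") "FINALSTEP" else "STEP"
      id <- sprintf("t_%s_%s", v$id[i], v$id[j])
      if (semantics == "BURNT_BRIDGES") {
        p <- stats::setNames(c(2L, 1L), c(aplace[i], aplace[j]))
        q <- stats::setNames(2L, aplace[j])
      } else {
        p <- stats::setNames(c(2L, 1L), c(aplace[i], aplace[j]))
        q <- stats::setNames(c(1L, 2L), c(aplace[i], aplace[j]))
      }
      addt(id, "STOCHASTIC", step_rate(cat_, params), NA_real_, role,
           v$id[i], v$id[j], NA_character_, cat_, p, q)
    }
  }
  for (i in which(v$type == "FINAL")) {
    id <- paste0("loop_", v$id[i])
    addt(id, "STOCHASTIC", params$k_s, NA_real_, "LOOP",
         NA_character_, NA_character_, v$id[i], NA_character_,
         stats::setNames(2L, aplace[i]), stats::setNames(2L, aplace[i]))
  }
  for (i in which(labelled)) {
    b <- paste0("B_", v$id[i])
    addt(paste0("block_", v$id[i]), "IMMEDIATE", NA_real_, block_weight,
         "BLOCK", NA_character_, NA_character_, v$id[i], NA_character_,
         stats::setNames(c(1L, 1L), c(b, aplace[i])), stats::setNames(integer(0), character(0)))
    addt(paste0("fail_", v$id[i]), "IMMEDIATE", NA_real_, 1 - block_weight,
         "FAIL", NA_character_, NA_character_, v$id[i], NA_character_,
         stats::setNames(1L, b), stats::setNames(integer(0), character(0)))
  }
  transitions <- do.call(rbind, trs)
  rownames(transitions) <- NULL

  m0 <- stats::setNames(rep(1L, nrow(places)), places$id)
  m0[startsWith(places$id, "B_")] <- 0L
  m0[paste0("A_", v$id[v$type == "INIT"])] <- 2L

  structure(list(places = places, transitions = transitions,
                 pre = pre, post = post, m0 = m0,
                 semantics = semantics, circuit = c, params = params),
            class = "gspn")
}

#' @export
print.gspn <- function(x, ...) {
  tt <- table(x$transitions$role)
  cat(sprintf("gspn (%s): %d places, %d transitions\n",
              x$semantics, nrow(x$places), nrow(x$transitions)))
  cat("  ", paste(sprintf("%s=%d", names(tt), tt), collapse = " "), "\n")
  invisible(x)
}

#' Program a net for concrete input values
#'
#' Returns a copy of the net whose blocking-control places hold one token
#' exactly for the anchorages that must be blocked under the assignment
#' (label literal false); the immediate block/fail pairs then resolve the
#' blocking probabilistically before any timed transition fires.
#'
#' @param net a \code{gspn}.
#' @param a named logical assignment over the circuit inputs.
#' @return the net with an updated initial marking.
#' @export
apply_assignment <- function(net, a) {
  blocked <- blocked_vertices(net$circuit, a)
  bids <- net$places$id[net$places$kind == "BLOCKCTRL"]
  net$m0[bids] <- 0L
  hit <- paste0("B_", blocked)
  net$m0[intersect(hit, bids)] <- 1L
  net$assignment <- a
  net
}

#' Enabled transitions of a marking
#'
#' A transition is enabled when every pre-place holds at least the arc
#' weight.  Under GSPN priority semantics, enabled immediate transitions
#' pre-empt all stochastic ones, so if any immediate transition is
#' enabled only immediate transitions are returned; the time-free
#' (qualitative) view can request the unprioritised set.
#'
#' @param net a \code{gspn}.
#' @param m marking (named integer vector over the net's places).
#' @param priority apply immediate-transition priority?
#' @return character vector of enabled transition ids.
#' @export
enabled_transitions <- function(net, m, priority = TRUE) {
  tr <- net$transitions
  en <- vapply(tr$id, function(id) {
    p <- net$pre[[id]]
    length(p) > 0 && all(m[names(p)] >= p)
  }, logical(1))
  ids <- tr$id[en]
  if (priority) {
    imm <- ids[tr$kind[en] == "IMMEDIATE"]
    if (length(imm)) return(imm)
  }
  ids
}

#' Fire a transition
#'
#' @param net a \code{gspn}.
#' @param m marking.
#' @param t transition id, enabled in \code{m}.
#' @return the successor marking \code{m - pre + post}.
#' @export
fire_transition <- function(net, m, t) {
  p <- net$pre[[t]]
  if (!length(p) || !all(m[names(p)] >= p))
    stop("transition '", t, "' is not enabled")
  m[names(p)] <- m[names(p)] - p
  q <- net$post[[t]]
  if (length(q)) m[names(q)] <- m[names(q)] + q
  m
}

#' Plain-text dump of a net
#'
#' Writes places, transitions, arcs and the initial marking as a stable,
#' diff-friendly text block, for golden-file tests and inspection.
#'
#' @param net a \code{gspn}.
#' @param path output file, or \code{NULL} to return the lines.
#' @return invisibly the character vector of lines.
#' @export
dump_gspn <- function(net, path = NULL) {
  lines <- c(sprintf("gspn semantics=%s", net$semantics), "places:")
  lines <- c(lines, sprintf("  %s kind=%s m0=%d", net$places$id,
                            net$places$kind, net$m0[net$places$id]))
  lines <- c(lines, "transitions:")
  for (i in seq_len(nrow(net$transitions))) {
    t <- net$transitions[i, ]
    pr <- net$pre[[t$id]]; po <- net$post[[t$id]]
    lines <- c(lines, sprintf(
      "  %s kind=%s role=%s %s pre={%s} post={%s}",
      t$id, t$kind, t$role,
      if (t$kind == "STOCHASTIC") sprintf("rate=%g", t$rate)
      else sprintf("weight=%g", t$weight),
      paste(sprintf("%s:%d", names(pr), pr), collapse = ","),
      paste(sprintf("%s:%d", names(po), po), collapse = ",")))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Export a net to PNML
#'
#' Standard Petri Net Markup Language (place/transition view; rates and
#' weights carried in tool-specific annotations) for interoperability
#' with external Petri net tools.
#'
#' @param net a \code{gspn}.
#' @param path output file.
#' @return invisibly \code{path}.
#' @export
export_pnml <- function(net, path) {
  if (!requireNamespace("xml2", quietly = TRUE))
    stop("export_pnml needs the xml2 package")
  doc <- xml2::xml_new_root("pnml",
    xmlns = "http://www.pnml.org/version-2009/grammar/pnml")
  netn <- xml2::xml_add_child(doc, "net", id = "walker",
    type = "http://www.pnml.org/version-2009/grammar/ptnet")
  page <- xml2::xml_add_child(netn, "page", id = "page0")
  for (i in seq_len(nrow(net$places))) {
    p <- xml2::xml_add_child(page, "place", id = net$places$id[i])
    nm <- xml2::xml_add_child(p, "name")
    xml2::xml_add_child(nm, "text", net$places$id[i])
    if (net$m0[[net$places$id[i]]] > 0) {
      mk <- xml2::xml_add_child(p, "initialMarking")
      xml2::xml_add_child(mk, "text", as.character(net$m0[[net$places$id[i]]]))
    }
  }
  for (i in seq_len(nrow(net$transitions))) {
    t <- net$transitions[i, ]
    tn <- xml2::xml_add_child(page, "transition", id = t$id)
    ts <- xml2::xml_add_child(tn, "toolspecific", tool = "walkernet",
                              version = "1")
    if (t$kind == "STOCHASTIC")
      xml2::xml_add_child(ts, "rate", as.character(t$rate))
    else
      xml2::xml_add_child(ts, "weight", as.character(t$weight))
    arcs <- c(lapply(names(net$pre[[t$id]]), function(pl)
                c(src = pl, tgt = t$id, w = net$pre[[t$id]][[pl]])),
              lapply(names(net$post[[t$id]]), function(pl)
                c(src = t$id, tgt = pl, w = net$post[[t$id]][[pl]])))
    for (k in seq_along(arcs)) {
      a <- arcs[[k]]
      an <- xml2::xml_add_child(page, "arc",
        id = sprintf("%s_arc%d", t$id, k), source = a[["src"]],
        target = a[["tgt"]])
      ins <- xml2::xml_add_child(an, "inscription")
      xml2::xml_add_child(ins, "text", a[["w"]])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
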