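VERTEX_TYPES <- c("INIT", "NORM", "FORK", "JOIN", "FINAL")

#' Construct a grid-embedded walker circuit
#'
#' A walker circuit is a planar undirected graph of anchorages embedded in a
#' regular rectangular grid.  Each vertex has a 1-based grid position
#' (\code{x} = row, \code{y} = column), a type (\code{INIT}, \code{NORM},
#' \code{FORK}, \code{JOIN}, \code{FINAL}), a label (a literal over the
#' circuit's Boolean input variables, or the empty label \code{"eps"} for
#' unblockable anchorages), and, for final vertices only, an output truth
#' value \code{"T"} or \code{"F"}.  The circuit additionally stores the
#' Boolean function it is meant to compute, since correctness of a walker
#' run (reaching a final whose output equals the function value) cannot be
#' judged from the graph alone.
#'
#' @param vertices data.frame with columns \code{id}, \code{x}, \code{y},
#'   \code{type}, \code{label} (e.g. \code{"x"}, \code{"!x"}, \code{"eps"})
#'   and optionally \code{out} (\code{"T"}/\code{"F"} for finals, \code{NA}
#'   otherwise).
#' @param inputs character vector of Boolean input variable names.
#' @param fun Boolean expression over \code{inputs} as a string, using
#'   \code{!}, \code{&}, \code{|} and parentheses.
#' @param edges optional two-column matrix/data.frame of vertex-id pairs:
#'   the declared intended edge set.  When present it is used for degree
#'   validation (INIT and FINAL have 1 adjacent edge, NORM 2, FORK/JOIN 3);
#'   walker steps themselves are always derived from grid distances.
#' @param validate run \code{\link{validate_circuit}}?
#' @return an object of class \code{walker_circuit}.
#' @export
walker_circuit <- function(vertices, inputs, fun, edges = NULL,
                           validate = TRUE) {
  stopifnot(is.data.frame(vertices),
            all(c("id", "x", "y", "type", "label") %in% names(vertices)))
  v <- vertices
  v$id <- as.character(v$id)
  v$x <- as.integer(v$x)
  v$y <- as.integer(v$y)
  v$type <- as.character(v$type)
  v$label <- as.character(v$label)
  if (!"out" %in% names(v)) v$out <- NA_character_
  v$out <- as.character(v$out)
  # deterministic vertex order: lexicographic (x, y)
  v <- v[order(v$x, v$y), , drop = FALSE]
  rownames(v) <- NULL
  if (!is.null(edges)) {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "character"
    stopifnot(ncol(edges) == 2)
  }
  c0 <- structure(list(vertices = v, inputs = as.character(inputs),
                       fun = fun, edges = edges),
                  class = "walker_circuit")
  if (validate) validate_circuit(c0)
  c0
}

#' @export
print.walker_circuit <- function(x, ...) {
  cat(sprintf("walker_circuit: %d vertices on a %d x %d grid, function '%s'\n",
              nrow(x$vertices), max(x$vertices$x), max(x$vertices$y), x$fun))
  tab <- table(factor(x$vertices$type, levels = VERTEX_TYPES))
  cat("  ", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

parse_label <- function(label) {
  if (label == "eps" || label == "") {
    list(eps = TRUE, var = NA_character_, neg = FALSE)
  } else if (startsWith(label, "!")) {
    list(eps = FALSE, var = substring(label, 2), neg = TRUE)
  } else {
    list(eps = FALSE, var = label, neg = FALSE)
  }
}

#' Validate a walker circuit against the design-rule invariants
#'
#' Checks: unique vertex ids; 1-based integer coordinates, pairwise
#' distinct; exactly one INIT vertex, labelled \code{eps}; at least one
#' FINAL vertex; outputs present exactly on finals; finals unlabelled
#' (\code{eps}); every label literal over a declared input variable; and,
#' if a declared edge set is present, the per-type vertex degrees
#' (INIT/FINAL 1, NORM 2, FORK/JOIN 3).
#'
#' @param c a \code{walker_circuit}.
#' @return invisibly \code{TRUE}; stops with a message naming the violated
#'   invariant and the offending vertex id otherwise.
#' @export
validate_circuit <- function(c) {
  v <- c$vertices
  fail <- function(...) stop("circuit validation: ", sprintf(...), call. = FALSE)
  if (anyDuplicated(v$id)) fail("duplicate vertex id '%s'", v$id[duplicated(v$id)][1])
  if (any(is.na(v$x)) || any(is.na(v$y)) || any(v$x < 1) || any(v$y < 1))
    fail("coordinates must be integers >= 1")
  pos <- paste(v$x, v$y)
  if (anyDuplicated(pos))
    fail("vertices share position (%s)", pos[duplicated(pos)][1])
  bad <- setdiff(v$type, VERTEX_TYPES)
  if (length(bad)) fail("unknown vertex type '%s'", bad[1])
  ninit <- sum(v$type == "INIT")
  if (ninit == 0) fail("no INIT vertex")
  if (ninit > 1) fail("multiple INIT vertices")
  if (!any(v$type == "FINAL")) fail("no FINAL vertex")
  init <- v[v$type == "INIT", ]
  if (init$label != "eps")
    fail("INIT vertex '%s' must be labelled eps", init$id)
  for (i in seq_len(nrow(v))) {
    lab <- parse_label(v$label[i])
    isfin <- v$type[i] == "FINAL"
    if (isfin && !lab$eps)
      fail("FINAL vertex '%s' carries a label", v$id[i])
    if (isfin && (is.na(v$out[i]) || !v$out[i] %in% c("T", "F")))
      fail("FINAL vertex '%s' needs output T or F", v$id[i])
    if (!isfin && !is.na(v$out[i]))
      fail("non-FINAL vertex '%s' carries an output", v$id[i])
    if (!lab$eps && !lab$var %in% c$inputs)
      fail("vertex '%s' labelled with unknown variable '%s'", v$id[i], lab$var)
  }
  check_bool_expr(c$fun, c$inputs)
  if (!is.null(c$edges)) {
    ids <- c(c$edges)
    if (!all(ids %in% v$id))
      fail("declared edge references unknown vertex '%s'",
           setdiff(ids, v$id)[1])
    deg <- table(factor(ids, levels = v$id))
    want <- c(INIT = 1, FINAL = 1, NORM = 2, FORK = 3, JOIN = 3)
    for (i in seq_len(nrow(v))) {
      d <- deg[[v$id[i]]]
      if (d != want[[v$type[i]]])
        fail("vertex '%s' (%s) has declared degree %d, expected %d",
             v$id[i], v$type[i], d, want[[v$type[i]]])
    }
  }
  invisible(TRUE)
}

check_bool_expr <- function(fun, inputs) {
  toks <- regmatches(fun, gregexpr("[A-Za-z_][A-Za-z0-9_]*|[!&|()]|\\s+|.",
                                   fun))[[1]]
  toks <- toks[!grepl("^\\s+$", toks)]
  words <- toks[grepl("^[A-Za-z_]", toks)]
  bad <- setdiff(words, inputs)
  if (length(bad))
    stop("circuit validation: function uses undeclared variable '",
         bad[1], "'", call. = FALSE)
  ok <- grepl("^([A-Za-z_][A-Za-z0-9_]*|[!&|()])$", toks)
  if (!all(ok))
    stop("circuit validation: illegal token '", toks[!ok][1],
         "' in function", call. = FALSE)
  invisible(TRUE)
}

#' Evaluate a vertex label under an input assignment
#'
#' The empty label evaluates to \code{TRUE} (the anchorage can never be
#' blocked); a positive literal evaluates to the variable's value, a
#' negated literal to its negation.
#'
#' @param label label string (\code{"eps"}, \code{"x"}, \code{"!x"}, ...).
#' @param a named logical vector, one entry per input variable.
#' @return logical scalar.
#' @export
evaluate_label <- function(label, a) {
  lab <- parse_label(label)
  if (lab$eps) return(TRUE)
  if (!lab$var %in% names(a)) stop("unknown variable '", lab$var, "'")
  val <- a[[lab$var]]
  if (lab$neg) !val else val
}

#' Blocked anchorages for an input assignment
#'
#' Programming a walker circuit for concrete input values means blocking
#' every anchorage whose label literal evaluates to false; the walker then
#' cannot visit it (unless the blocking mechanism fails, see
#' \code{\link{unfold_gspn}}).  Final and eps-labelled vertices are never
#' blocked.
#'
#' @param c a \code{walker_circuit}.
#' @param a named logical assignment over the circuit inputs.
#' @return character vector of blocked vertex ids.
#' @export
blocked_vertices <- function(c, a) {
  v <- c$vertices
  keep <- vapply(seq_len(nrow(v)), function(i) {
    v$type[i] != "FINAL" && !evaluate_label(v$label[i], a)
  }, logical(1))
  v$id[keep]
}

#' Evaluate the circuit's target Boolean function
#'
#' @param c a \code{walker_circuit}.
#' @param a named logical assignment over the circuit inputs.
#' @return logical scalar: the intended output for those inputs.
#' @export
evaluate_function <- function(c, a) {
  if (!all(c$inputs %in% names(a)))
    stop("assignment must cover all inputs: ",
         paste(setdiff(c$inputs, names(a)), collapse = ", "))
  check_bool_expr(c$fun, c$inputs)
  env <- list2env(as.list(a), parent = baseenv())
  isTRUE(eval(parse(text = c$fun)[[1]], env))
}

#' All input assignments of a circuit
#'
#' @param c a \code{walker_circuit}.
#' @return list of named logical vectors, all 2^n assignments in a fixed
#'   (binary counting) order.
#' @export
all_assignments <- function(c) {
  n <- length(c$inputs)
  lapply(0:(2^n - 1), function(k) {
    bits <- as.logical(bitwAnd(k, 2^(seq_len(n) - 1)) > 0)
    stats::setNames(bits, c$inputs)
  })
}

#' Read / write circuit files
#'
#' Circuits are stored as YAML documents with keys \code{inputs} (list of
#' variable names), \code{function} (expression string), \code{vertices}
#' (list of maps with \code{id}, \code{x}, \code{y}, \code{type},
#' \code{label}, and \code{out} for finals) and optionally \code{edges}
#' (list of id pairs).  \code{load_circuit} validates the document
#' structure and then all circuit invariants; \code{save_circuit} writes a
#' file that round-trips to a structurally identical circuit.
#'
#' @param path file path.
#' @return \code{load_circuit}: a validated \code{walker_circuit}.
#' @export
load_circuit <- function(path) {
  if (!file.exists(path)) stop("circuit file not found: ", path)
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("circuit parse error: ",
                                           conditionMessage(e), call. = FALSE))
  for (k in c("inputs", "function", "vertices"))
    if (is.null(doc[[k]])) stop("circuit file lacks key '", k, "'")
  vv <- lapply(doc$vertices, function(r) {
    # YAML 1.1 reads the bare scalars y/n/T/F as booleans; undo that for
    # the coordinate key and for output truth values
    names(r)[names(r) == "TRUE"] <- "y"
    if (!is.null(r$out) && is.logical(r$out))
      r$out <- if (r$out) "T" else "F"
    r
  })
  vertices <- data.frame(
    id = vapply(vv, function(r) as.character(r$id), ""),
    x = vapply(vv, function(r) as.integer(r$x), 1L),
    y = vapply(vv, function(r) as.integer(r$y), 1L),
    type = vapply(vv, function(r) as.character(r$type), ""),
    label = vapply(vv, function(r)
      if (is.null(r$label)) "eps" else as.character(r$label), ""),
    out = vapply(vv, function(r)
      if (is.null(r$out)) NA_character_ else as.character(r$out), ""),
    stringsAsFactors = FALSE)
  edges <- NULL
  if (!is.null(doc$edges))
    edges <- do.call(rbind, lapply(doc$edges, function(e)
      c(as.character(e[[1]]), as.character(e[[2]]))))
  walker_circuit(vertices, inputs = unlist(doc$inputs),
                 fun = doc[["function"]], edges = edges)
}

#' @rdname load_circuit
#' @param c a \code{walker_circuit}.
#' @export
save_circuit <- function(c, path) {
  v <- c$vertices
  verts <- lapply(seq_len(nrow(v)), function(i) {
    r <- list(id = v$id[i], x = v$x[i], y = v$y[i],
              type = v$type[i], label = v$label[i])
    if (!is.na(v$out[i])) r$out <- v$out[i]
    r
  })
  doc <- list(inputs = as.list(c$inputs), `function` = c$fun,
              vertices = verts)
  if (!is.null(c$edges))
    doc$edges <- lapply(seq_len(nrow(c$edges)),
                        function(i) as.list(unname(c$edges[i, ])))
  yaml::write_yaml(doc, path)
  invisible(NULL)
}
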