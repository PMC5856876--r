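#' Packaged example circuits
#'
#' Three circuits ship with the package as circuit files under
#' \code{inst/extdata}:
#' \describe{
#'   \item{\code{toy_circuit()}}{a minimal single-input circuit (6 vertices
#'     on a 7 x 8 grid: INIT, track, one fork whose labelled branches end
#'     in a true and a false final) used throughout the documentation.}
#'   \item{\code{naive_layout()}}{a compact layout of the three-input
#'     disjunction x | y | z as a binary decision DAG (three forks, two
#'     joins, a true and a false final).  The tight packing keeps the
#'     circuit small but places parallel tracks within interaction range,
#'     producing many leakage transitions.}
#'   \item{\code{optimised_layout()}}{the same decision DAG laid out with
#'     larger separations between branches, trading a slightly larger
#'     area and longer tracks for far fewer leakage transitions.}
#' }
#' The two x | y | z layouts are synthetic reconstructions (see the file
#' names): coordinate sets engineered so that the classification table of
#' the compact layout exhibits the reference leakage profile of a naive
#' design and the spread layout that of an optimised design, with
#' identical short-band fork/join structure.  Their structural
#' classification tables are frozen in the package tests.
#'
#' @return a validated \code{walker_circuit}.
#' @export
toy_circuit <- function() {
  load_circuit(system.file("extdata", "toy_synthetic.yaml",
                           package = "walkernet", mustWork = TRUE))
}

#' @rdname toy_circuit
#' @export
naive_layout <- function() {
  load_circuit(system.file("extdata", "xyz_naive_synthetic.yaml",
                           package = "walkernet", mustWork = TRUE))
}

#' @rdname toy_circuit
#' @export
optimised_layout <- function() {
  load_circuit(system.file("extdata", "xyz_optimised_synthetic.yaml",
                           package = "walkernet", mustWork = TRUE))
}

#' Parameters for the random circuit generator
#'
#' @param n_inputs number of Boolean input variables (tree depth).
#' @param track_length integer range (min, max) of normal anchorages per
#'   straight track segment.
#' @param branch_separation vertical grid distance between adjacent leaf
#'   tracks; with the default distance parameters any value above
#'   \code{dS} guarantees that no unintended short-band edge connects two
#'   different branches.
#' @param fun optional Boolean expression string; a random expression
#'   over the inputs is generated when \code{NULL}.
#' @param seed integer seed; the same seed yields the same circuit.
#' @return a \code{generator_params} list.
#' @export
generator_params <- function(n_inputs = 2, track_length = c(2, 4),
                             branch_separation = 10, fun = NULL,
                             seed = 1L) {
  stopifnot(n_inputs >= 1, track_length[1] >= 1,
            track_length[2] >= track_length[1], branch_separation >= 1)
  structure(list(n_inputs = n_inputs, track_length = track_length,
                 branch_separation = branch_separation, fun = fun,
                 seed = as.integer(seed)),
            class = "generator_params")
}

#' Generate a random walker circuit
#'
#' Builds a full binary decision tree over the input variables: from the
#' initial anchorage a track leads to a fork per variable, whose two
#' branches (first anchorage labelled with the positive and negated
#' literal) diverge diagonally onto disjoint horizontal bands separated
#' by \code{branch_separation} rows and continue with straight tracks of
#' random length; leaves are final anchorages whose output is the value
#' of the circuit function on the path assignment.  All intended steps
#' have lattice distance 2 (one diagonal or axial grid step of two
#' units), so the short-band sub-graph equals the intended tree whenever
#' the branch separation exceeds the short radius.
#'
#' @param p a \code{\link{generator_params}} object.
#' @return a validated \code{walker_circuit}.
#' @export
random_circuit <- function(p = generator_params()) {
  set.seed(p$seed)
  k <- p$n_inputs
  inputs <- if (k <= 26) letters[23 + seq_len(min(k, 3))] else NULL
  if (k > 3 || is.null(inputs)) inputs <- paste0("v", seq_len(k))
  fun <- p$fun
  if (is.null(fun)) {
    ord <- sample(inputs)
    fun <- ifelse(stats::runif(1) < 0.5, paste0("!", ord[1]), ord[1])
    for (v in ord[-1]) {
      lit <- if (stats::runif(1) < 0.5) paste0("!", v) else v
      op <- if (stats::runif(1) < 0.5) "&" else "|"
      fun <- sprintf("(%s %s %s)", fun, op, lit)
    }
  }
  sep <- p$branch_separation
  rows <- list(); nid <- 0L
  add <- function(x, y, type, label = "eps", out = NA) {
    nid <<- nid + 1L
    rows[[nid]] <<- data.frame(id = sprintf("a%02d", nid), x = x, y = y,
                               type = type, label = label, out = out,
                               stringsAsFactors = FALSE)
    rows[[nid]]$id
  }
  rlen <- function() sample(seq(p$track_length[1], p$track_length[2]), 1)
  tmpc <- list(inputs = inputs, fun = fun)

  # leaf band height of a subtree with m variables left
  build <- function(r, y, vars, assign_so_far, first_label) {
    # straight track eastwards
    L <- rlen()
    for (q in seq_len(L)) {
      lab <- if (q == 1 && !is.na(first_label)) first_label else "eps"
      add(r, y, "NORM", lab)
      y <- y + 2
    }
    if (!length(vars)) {
      val <- isTRUE(eval(parse(text = fun)[[1]],
                         list2env(as.list(assign_so_far), parent = baseenv())))
      add(r, y, "FINAL", "eps", if (val) "T" else "F")
      return(invisible(NULL))
    }
    v <- vars[1]
    add(r, y, "FORK")
    # children diverge diagonally to the centres of the two half-bands
    # (rounded up to an even row offset so diagonal steps land on the grid)
    half <- ceiling(sep * 2^(length(vars) - 2) / 2) * 2
    for (s in c(-1, 1)) {
      rr <- r + s * 2; yy <- y + 2
      steps <- max(half / 2 - 1, 0)
      first <- TRUE
      lab <- if (s < 0) v else paste0("!", v)
      while (steps > 0) {
        add(rr, yy, "NORM", if (first) lab else "eps")
        first <- FALSE
        rr <- rr + s * 2; yy <- yy + 2
        steps <- steps - 1
      }
      a2 <- assign_so_far
      a2[[v]] <- s < 0
      build(rr, yy, vars[-1], a2,
            if (first) lab else NA)
    }
  }
  r0 <- sep * 2^(k - 1) + 3
  add(r0, 1, "INIT")
  build(r0, 3, inputs, stats::setNames(as.list(rep(NA, k)), inputs), NA)
  v <- do.call(rbind, rows)
  # shift onto the positive quadrant
  v$x <- v$x - min(v$x) + 1L
  v$y <- v$y - min(v$y) + 1L
  walker_circuit(v, inputs = inputs, fun = fun)
}
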