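test_that("a single track shares the initial index", {
  ix <- index_places(line_circuit())
  expect_equal(unname(ix$index), c(1L, 1L, 1L))
  expect_equal(nrow(ix$M), 1)
  expect_equal(ix$M$type, "TRACK")
  expect_equal(c(ix$M$pre, ix$M$post), c(1L, 1L))
})

test_that("fork children receive doubled indices", {
  ix <- index_places(toy_circuit())
  idx <- ix$index
  expect_equal(unname(idx[c("v0", "f")]), c(1L, 1L))
  expect_setequal(unname(idx[c("a", "b")]), c(2L, 3L))
  expect_equal(unname(idx["fT"]), unname(idx["a"]))   # finals inherit
  expect_equal(unname(idx["fF"]), unname(idx["b"]))
  expect_true(all(c("FORK", "TRACK") %in% ix$M$type))
})

test_that("layout fixtures index to their designed values", {
  # frozen per-segment indices of the x|y|z decision DAG
  expect_seg <- function(circ, ix) {
    idx <- ix$index
    seg_of <- function(pat) idx[grepl(pat, names(idx))]
    expect_true(all(seg_of("^v0|^fA") == 1))
    expect_true(all(seg_of("^x\\d") == 2))
    expect_true(all(seg_of("^nx\\d|^fB") == 3))
    expect_true(all(seg_of("^y\\d") == 6))
    expect_true(all(seg_of("^ny\\d|^fC") == 7))
    expect_true(all(seg_of("^z\\d") == 14))
    expect_true(all(seg_of("^nz\\d|^fF") == 15))
    expect_true(all(seg_of("^J1|^i\\d") == 4))
    expect_true(all(seg_of("^J2|^j\\d|^fT") == 8))
  }
  for (circ in list(naive_layout(), optimised_layout()))
    expect_seg(circ, index_places(circ))
})

test_that("classification is a partition into the 12 classes", {
  for (circ in list(naive_layout(), optimised_layout(), toy_circuit())) {
    cls <- classify_circuit(circ)
    nsteps <- sum(cls$transitions$role %in% c("STEP", "FINALSTEP"))
    expect_equal(sum(cls$table[, "Sigma"]), nsteps)
    expect_equal(cls$table[, "Sigma"], rowSums(cls$table[, 1:3]))
    expect_true(all(cls$transitions$structural %in%
                      c("TRACK", "FORK", "JOIN", "LEAK")))
    expect_true(all(cls$transitions$category %in%
                      c("SHORT", "MEDIUM", "LONG")))
  }
})

test_that("short-band fork and join counts are layout invariant", {
  t1 <- classify_circuit(naive_layout())$table
  t2 <- classify_circuit(optimised_layout())$table
  expect_equal(t1["Fork", "Short"], 12L)
  expect_equal(t2["Fork", "Short"], 12L)
  expect_equal(t1["Join", "Short"], 8L)
  expect_equal(t2["Join", "Short"], 8L)
})

test_that("indexing and classification are deterministic", {
  a <- classify_circuit(naive_layout())
  b <- classify_circuit(naive_layout())
  expect_identical(a$table, b$table)
  expect_identical(a$indexing$index, b$indexing$index)
  expect_identical(a$transitions$class, b$transitions$class)
})

test_that("swapping fork children leaves the table unchanged", {
  for (seed in 1:5) {
    circ <- random_circuit(generator_params(n_inputs = 3, seed = seed,
                                            branch_separation = 6))
    net <- unfold_gspn(circ)
    ix1 <- index_places(circ)
    ix2 <- index_places(circ, fork_order = "swapped")
    expect_false(identical(ix1$index, ix2$index))  # relabelling did happen
    t1 <- classify_transitions(net, ix1)$table
    t2 <- classify_transitions(net, ix2)$table
    expect_equal(t1, t2)
  }
})

test_that("generated circuits with wide separation have no short leaks", {
  for (seed in 1:5) {
    circ <- random_circuit(generator_params(n_inputs = 2, seed = seed,
                                            branch_separation = 10))
    tab <- classify_circuit(circ)$table
    expect_equal(tab["Leak", "Short"], 0L)
  }
})

test_that("the successor predicate excludes same-index and parent nodes", {
  circ <- toy_circuit()
  adj <- short_adjacency(circ)
  v <- circ$vertices
  n <- nrow(v)
  pos <- function(id) which(v$id == id)
  idx <- integer(n)
  idx[pos("v0")] <- 1L
  # unindexed neighbour of INIT is a successor
  expect_equal(v$id[bfs_successors(pos("v0"), idx, adj)], "f")
  # same index -> excluded
  idx[pos("f")] <- 1L
  expect_false(pos("v0") %in% bfs_successors(pos("f"), idx, adj))
  # fork child must not walk back to the parent (index c = child %/% 2)
  idx[pos("a")] <- 2L
  expect_false(pos("f") %in% bfs_successors(pos("a"), idx, adj))
})

test_that("consistency report flags only pattern-violating triples", {
  fake <- list(M = data.frame(
    pre = c(1L, 1L, 3L, 2L, 6L),
    post = c(1L, 2L, 4L, 4L, 4L),
    type = c("TRACK", "FORK", "JOIN", "JOIN", "JOIN"),
    stringsAsFactors = FALSE))
  rep <- consistency_report(fake)
  expect_equal(rep$consistent, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  # fixtures produce fully consistent sets
  expect_true(all(consistency_report(index_places(naive_layout()))$consistent))
})

test_that("ambiguous short sub-graphs are rejected with a diagnostic", {
  # a 2x2 clump: INIT with two short neighbours
  v <- data.frame(id = c("v0", "a", "b", "f"),
                  x = c(1, 1, 3, 3), y = c(1, 3, 1, 3),
                  type = c("INIT", "NORM", "NORM", "FINAL"),
                  label = c("eps", "eps", "eps", "eps"),
                  out = c(NA, NA, NA, "T"))
  circ <- walker_circuit(v, inputs = "x", fun = "x")
  expect_error(index_places(circ), "ambiguity.*v0")
})
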