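test_that("reachability exploration terminates and is 2-bounded", {
  net <- apply_assignment(unfold_gspn(line_circuit()), c(x = TRUE))
  rg <- build_reachability_graph(net, "TIMEFREE")
  expect_gt(nrow(rg$markings), 1)
  expect_equal(check_bound(rg), 2)
  # walker-free variant is 1-bounded
  net1 <- net; net1$m0["A_v0"] <- 1L
  expect_equal(check_bound(build_reachability_graph(net1, "TIMEFREE")), 1)
})

test_that("the priority graph is a subgraph of the time-free graph", {
  net <- apply_assignment(unfold_gspn(line_circuit()), c(x = FALSE))
  tf <- build_reachability_graph(net, "TIMEFREE")
  pr <- build_reachability_graph(net, "PRIORITY")
  key <- function(rg) apply(rg$markings, 1, paste, collapse = ",")
  expect_true(all(key(pr) %in% key(tf)))
  arckey <- function(rg) {
    k <- key(rg)
    paste(k[rg$arcs$from], rg$arcs$transition, k[rg$arcs$to])
  }
  expect_true(all(arckey(pr) %in% arckey(tf)))
  expect_lt(nrow(pr$markings), nrow(tf$markings))
})

test_that("final markings only loop; trapped walkers are dead", {
  net <- apply_assignment(unfold_gspn(line_circuit()), c(x = FALSE))
  rg <- build_reachability_graph(net, "PRIORITY")
  finals <- which(rg$markings[, "A_v2"] == 2)
  expect_gt(length(finals), 0)
  for (f in finals) {
    out <- rg$arcs[rg$arcs$from == f, ]
    expect_true(all(out$transition == "loop_v2"))
    expect_true(all(out$to == f))
  }
  # dead states never carry a final walker
  dd <- dead_states(rg)
  expect_true(all(rg$markings[dd, "A_v2"] < 2))
  # blocking succeeded but the long-range final step keeps INIT alive
  blocked_start <- which(rg$markings[, "A_v0"] == 2 &
                           rg$markings[, "A_v1"] == 0 &
                           rg$markings[, "B_v1"] == 0)
  expect_false(any(blocked_start %in% dd))
  # a final beyond the long band leaves a genuinely trapped walker
  trap <- apply_assignment(unfold_gspn(trap_circuit()), c(x = FALSE))
  rgt <- build_reachability_graph(trap, "PRIORITY")
  expect_gt(length(dead_states(rgt)), 0)
})

test_that("burnt-bridges nets are neither reversible nor live", {
  for (circ in list(line_circuit(), toy_circuit())) {
    net <- unfold_gspn(circ)
    a <- stats::setNames(rep(TRUE, length(circ$inputs)), circ$inputs)
    rep <- qualitative_report(net, a, "TIMEFREE")
    expect_false(rep$reversible)
    expect_false(rep$live)
    expect_equal(rep$bound, 2)
  }
  # a one-marking graph with a self-loop is both reversible and live
  rg1 <- structure(list(
    markings = matrix(2L, 1, 1, dimnames = list(NULL, "A_f")),
    arcs = data.frame(from = 1L, to = 1L, transition = "loop_f"),
    root = 1L, places = "A_f", mode = "TIMEFREE"),
    class = "reachability_graph")
  rep1 <- scc_analysis(rg1, transitions = "loop_f")
  expect_true(rep1$reversible)
  expect_true(rep1$live)
})

test_that("time-free graphs are acyclic up to final self-loops", {
  for (circ in list(line_circuit(), toy_circuit())) {
    net <- unfold_gspn(circ)
    for (a in all_assignments(circ)) {
      rg <- build_reachability_graph(apply_assignment(net, a), "TIMEFREE")
      arcs <- rg$arcs[rg$arcs$from != rg$arcs$to, ]
      g <- igraph::graph_from_data_frame(
        arcs[, c("from", "to")], directed = TRUE,
        vertices = data.frame(name = seq_len(nrow(rg$markings))))
      expect_true(igraph::is_dag(g))
    }
  }
})

test_that("post-immediate markings conserve exactly one walker", {
  # under GSPN priority the blocking phase completes before the walker
  # moves, so every settled marking carries exactly one walker
  for (circ in list(line_circuit(), toy_circuit())) {
    net <- unfold_gspn(circ)
    aplaces <- net$places$id[net$places$kind == "ANCHORAGE"]
    for (a in all_assignments(circ)) {
      netb <- apply_assignment(net, a)
      rg <- build_reachability_graph(netb, "PRIORITY")
      post_imm <- vapply(seq_len(nrow(rg$markings)), function(i) {
        m <- rg$markings[i, ]
        !any(vapply(netb$transitions$id[netb$transitions$kind == "IMMEDIATE"],
                    function(t) all(m[names(netb$pre[[t]])] >= netb$pre[[t]]),
                    logical(1)))
      }, logical(1))
      counts <- rg$markings[post_imm, aplaces, drop = FALSE]
      expect_true(all(rowSums(counts == 2) == 1))
      expect_true(all(counts <= 2))
    }
  }
})

test_that("absence of time-free dead states carries over to priority", {
  # guaranteed dead-free case: a single unblockable step
  net0 <- apply_assignment(unfold_gspn(single_step_circuit()), c(x = TRUE))
  tf0 <- build_reachability_graph(net0, "TIMEFREE")
  expect_equal(length(dead_states(tf0)), 0)
  expect_equal(length(dead_states(build_reachability_graph(net0, "PRIORITY"))),
               0)
  for (seed in 1:2) {
    circ <- random_circuit(generator_params(n_inputs = 1, seed = seed,
                                            branch_separation = 6,
                                            track_length = c(1, 2)))
    net <- unfold_gspn(circ)
    for (a in all_assignments(circ)) {
      netb <- apply_assignment(net, a)
      tf <- build_reachability_graph(netb, "TIMEFREE")
      if (length(dead_states(tf)) == 0) {
        pr <- build_reachability_graph(netb, "PRIORITY")
        expect_equal(length(dead_states(pr)), 0)
      }
    }
  }
})

test_that("reachability graphs export to DOT", {
  net <- apply_assignment(unfold_gspn(line_circuit()), c(x = TRUE))
  rg <- build_reachability_graph(net, "PRIORITY")
  path <- tempfile(fileext = ".dot")
  export_dot(rg, path)
  lines <- readLines(path)
  expect_equal(lines[1], "digraph reachability {")
  expect_equal(sum(grepl("->", lines)), nrow(rg$arcs))
})

test_that("the state-space limit raises an explicit error", {
  net <- apply_assignment(unfold_gspn(toy_circuit()), c(x = TRUE))
  expect_error(build_reachability_graph(net, "TIMEFREE", limit = 3),
               "state-space limit")
})
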