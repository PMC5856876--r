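STRUCTURAL_TYPES <- c("TRACK", "FORK", "JOIN", "LEAK")
STEP_BANDS <- c("SHORT", "MEDIUM", "LONG")
STEP_CLASSES <- as.vector(outer(STRUCTURAL_TYPES, STEP_BANDS, paste, sep = "-"))

#' Simulation configuration
#'
#' @param tau time horizon in seconds; all transient, reward and
#'   performability measures are evaluated at/up to this bound (default
#'   12000 s = 200 min).
#' @param runs_per_assignment number of simulated walker runs per input
#'   assignment (default 20000, giving standard errors below half a
#'   percentage point on mid-range probabilities).
#' @param seed integer seed for the run.
#' @param assignments \code{"ALL"} (all 2^n input assignments, averaged
#'   uniformly) or a list of named logical vectors.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(tau = 12000, runs_per_assignment = 20000,
                       seed = 1L, assignments = "ALL") {
  stopifnot(tau >= 0, runs_per_assignment >= 1)
  structure(list(tau = tau, runs_per_assignment = as.integer(runs_per_assignment),
                 seed = as.integer(seed), assignments = assignments),
            class = "sim_config")
}

#' Compile a circuit into a flat stepping model
#'
#' Internal precomputation shared by the simulator and the exact oracle:
#' the classified stepping transitions as an edge list with rates and
#' 12-way class ids, grouped by source vertex.
#'
#' @inheritParams classify_circuit
#' @param block_weight blocking success probability.
#' @return list used by \code{\link{simulate_circuit}} and
#'   \code{\link{exact_transient}}.
#' @keywords internal
compile_sim_model <- function(c, params = distance_params(),
                              semantics = "BURNT_BRIDGES",
                              block_weight = 0.7) {
  cls <- classify_circuit(c, params, semantics)
  v <- c$vertices
  tr <- cls$transitions
  from <- match(tr$source, v$id)
  to <- match(tr$target, v$id)
  ord <- order(from, to)
  tr <- tr[ord, ]; from <- from[ord]; to <- to[ord]
  class_id <- match(tr$class, STEP_CLASSES)
  n <- nrow(v)
  range_start <- integer(n); range_end <- integer(n)
  for (i in seq_len(n)) {
    sel <- which(from == i)
    range_start[i] <- if (length(sel)) min(sel) - 1L else 0L
    range_end[i] <- if (length(sel)) max(sel) else 0L
  }
  list(circuit = c, params = params, semantics = semantics,
       block_weight = block_weight,
       step_from = from, step_to = to, step_rate = tr$rate,
       step_class = class_id, transitions = tr,
       range_start = range_start, range_end = range_end,
       init = match(v$id[v$type == "INIT"], v$id),
       is_final = v$type == "FINAL",
       out_true = v$type == "FINAL" & v$out == "T",
       classification = cls$table)
}

#' Stochastic simulation of a walker circuit
#'
#' Simulates the programmed GSPN for every requested input assignment:
#' the immediate block/fail conflicts are resolved at time zero
#' (independent Bernoulli draws with the blocking success probability, to
#' which the weighted immediate races are equivalent because each
#' conflict is local to one anchorage), then the walker performs a
#' continuous-time jump process over the stepping transitions until it is
#' absorbed at a final anchorage, trapped in a dead marking, or the time
#' horizon passes.  Loop transitions at finals carry no reward and finals
#' cannot be left, so runs stop on arrival.
#'
#' @param c a \code{walker_circuit}.
#' @param cfg a \code{\link{sim_config}}.
#' @param params distance/rate parameters.
#' @param semantics stepping semantics.
#' @param block_weight blocking success probability.
#' @return object of class \code{walker_sim}: per-assignment run
#'   outcomes (status FINAL/DEAD/IN_TRANSIT, arrival time, step counts by
#'   class) plus the compiled model; input to
#'   \code{\link{transient_estimates}}, \code{\link{expected_rewards}}
#'   and \code{\link{step_distribution}}, which therefore share one set
#'   of trajectories.
#' @export
simulate_circuit <- function(c, cfg = sim_config(),
                             params = distance_params(),
                             semantics = "BURNT_BRIDGES",
                             block_weight = 0.7) {
  model <- compile_sim_model(c, params, semantics, block_weight)
  assigns <- if (identical(cfg$assignments, "ALL")) all_assignments(c)
             else cfg$assignments
  set.seed(cfg$seed)
  v <- c$vertices
  runs <- lapply(assigns, function(a) {
    blocked <- match(blocked_vertices(c, a), v$id)
    res <- simulate_runs_cpp(
      n_vertices = nrow(v),
      step_from = model$step_from, step_to = model$step_to,
      step_rate = model$step_rate, step_class = model$step_class,
      n_classes = length(STEP_CLASSES),
      range_start = model$range_start, range_end = model$range_end,
      init = model$init, is_final = model$is_final,
      blocked = as.integer(blocked), block_prob = model$block_weight,
      tau = cfg$tau, n_runs = cfg$runs_per_assignment,
      burnt_bridges = model$semantics == "BURNT_BRIDGES")
    colnames(res$class_steps) <- STEP_CLASSES
    res$status <- c("FINAL", "DEAD", "IN_TRANSIT")[res$status + 1L]
    res$final_vertex <- v$id[res$final_vertex]
    res$correct <- !is.na(res$final_vertex) &
      (model$out_true[match(res$final_vertex, v$id)] ==
         evaluate_function(c, a))
    res$assignment <- a
    res
  })
  structure(list(runs = runs, model = model, cfg = cfg),
            class = "walker_sim")
}

mean_se <- function(x) {
  n <- length(x)
  c(mean = mean(x), se = stats::sd(x) / sqrt(n))
}

#' Transient probability estimates
#'
#' Estimates, per input assignment and averaged uniformly over
#' assignments, the probability that the walker has reached any final
#' anchorage by the time horizon (FINAL), the correct final anchorage
#' (CORRECT: the final's output equals the circuit function's value for
#' the inputs), a dead marking (DEADLOCK), and the conditional
#' probability CONDITION = CORRECT / FINAL.  Finals are absorbing, so
#' "at tau" equals "by tau".  Normal-approximation standard errors
#' accompany every estimate.
#'
#' @param sim a \code{walker_sim} from \code{\link{simulate_circuit}}.
#' @return list with \code{per_assignment} (data.frame) and
#'   \code{averaged} (named vector, probabilities in [0, 1]) plus
#'   \code{averaged_se}.
#' @export
transient_estimates <- function(sim) {
  per <- lapply(sim$runs, function(r) {
    n <- length(r$status)
    c(FINAL = mean(r$status == "FINAL"),
      CORRECT = mean(r$correct),
      DEADLOCK = mean(r$status == "DEAD"),
      IN_TRANSIT = mean(r$status == "IN_TRANSIT"),
      n = n)
  })
  per <- as.data.frame(do.call(rbind, per))
  avg <- colMeans(per[, c("FINAL", "CORRECT", "DEADLOCK", "IN_TRANSIT")])
  n <- per$n[1]
  a <- nrow(per)
  se <- sqrt(colSums(per[, c("FINAL", "CORRECT", "DEADLOCK", "IN_TRANSIT")] *
                       (1 - per[, c("FINAL", "CORRECT", "DEADLOCK",
                                    "IN_TRANSIT")]) / n)) / a
  cond <- if (avg[["FINAL"]] > 0) avg[["CORRECT"]] / avg[["FINAL"]] else NA_real_
  cond_se <- if (!is.na(cond) && avg[["FINAL"]] > 0)
    cond * sqrt((se[["CORRECT"]] / avg[["CORRECT"]])^2 +
                  (se[["FINAL"]] / avg[["FINAL"]])^2) else NA_real_
  list(per_assignment = per,
       averaged = c(avg, CONDITION = cond),
       averaged_se = c(se, CONDITION = cond_se))
}

#' Expected accumulated impulse rewards (step counts)
#'
#' The impulse reward of every stepping transition is one; loop, block
#' and fail transitions carry no reward.  Reported are the expected
#' accumulated rewards up to the time horizon for all steps together and
#' for each of the 12 transition classes, averaged uniformly over input
#' assignments.  By construction the class expectations sum exactly to
#' the total within one simulation.
#'
#' @param sim a \code{walker_sim}.
#' @return list with \code{total} (mean, se), \code{by_class} (named
#'   means), \code{by_class_se}, and \code{table} (4 x 4 matrix in the
#'   Track/Fork/Join/Leak x Short/Medium/Long/Sigma layout).
#' @export
expected_rewards <- function(sim) {
  per_tot <- t(vapply(sim$runs, function(r) mean_se(r$total_steps),
                      numeric(2)))
  per_cls <- lapply(sim$runs, function(r) {
    m <- colMeans(r$class_steps)
    s <- apply(r$class_steps, 2, stats::sd) / sqrt(nrow(r$class_steps))
    rbind(m, s)
  })
  a <- length(sim$runs)
  cls_mean <- Reduce(`+`, lapply(per_cls, function(x) x[1, ])) / a
  cls_se <- sqrt(Reduce(`+`, lapply(per_cls, function(x) x[2, ]^2))) / a
  tab <- matrix(0, 4, 4,
                dimnames = list(c("Track", "Fork", "Join", "Leak"),
                                c("Short", "Medium", "Long", "Sigma")))
  for (s in STRUCTURAL_TYPES)
    for (b in STEP_BANDS) {
      r <- c(TRACK = "Track", FORK = "Fork", JOIN = "Join", LEAK = "Leak")[[s]]
      cc <- c(SHORT = "Short", MEDIUM = "Medium", LONG = "Long")[[b]]
      tab[r, cc] <- cls_mean[[paste(s, b, sep = "-")]]
    }
  tab[, "Sigma"] <- rowSums(tab[, 1:3])
  list(total = c(mean = mean(per_tot[, 1]),
                 se = sqrt(sum(per_tot[, 2]^2)) / a),
       by_class = cls_mean, by_class_se = cls_se, table = tab)
}

#' Performability: distribution of the accumulated step count
#'
#' Empirical probability mass and cumulative distribution of the number
#' of (classified) steps taken by runs that reach a final anchorage
#' within the horizon, averaged over assignments.  Mass of runs that do
#' not finish is excluded, so the CDF converges to the FINAL probability,
#' not to one.
#'
#' @param sim a \code{walker_sim}.
#' @param reward \code{"steps"} for the total, or one of the class names
#'   (e.g. \code{"LEAK-SHORT"}).
#' @param n_max largest step count reported.
#' @return data.frame with columns \code{n}, \code{pmf}, \code{cdf}.
#' @export
step_distribution <- function(sim, reward = "steps", n_max = 60) {
  stopifnot(n_max >= 0)
  vals <- lapply(sim$runs, function(r) {
    x <- if (identical(reward, "steps")) r$total_steps
         else r$class_steps[, reward]
    x[r$status == "FINAL"]
  })
  n_runs <- vapply(sim$runs, function(r) length(r$status), 1L)
  counts <- Reduce(`+`, lapply(vals, function(x)
    tabulate(x + 1L, nbins = n_max + 1L)))
  pmf <- counts / sum(n_runs)
  data.frame(n = 0:n_max, pmf = pmf, cdf = cumsum(pmf))
}

# ---------------------------------------------------------------------------
# Exact CTMC oracle (uniformisation)

#' Exact transient and reward analysis of a small walker net
#'
#' Builds, for one input assignment, the continuous-time Markov chain
#' over the post-immediate markings of the programmed net (walker
#' position plus anchorage availability), branching analytically over the
#' blocking outcomes as independent Bernoulli trials, and computes by
#' uniformisation the exact probabilities of FINAL / CORRECT / DEADLOCK
#' at the horizon and the exact expected accumulated impulse rewards per
#' transition class (via the cumulative sojourn times).  Intended as a
#' numerically exact oracle for validating the simulator on nets whose
#' state space is small.
#'
#' @param c a \code{walker_circuit}.
#' @param a named logical assignment.
#' @param tau time horizon in seconds.
#' @param params distance/rate parameters.
#' @param semantics stepping semantics.
#' @param block_weight blocking success probability.
#' @param state_limit maximum number of CTMC states per blocking outcome.
#' @param tol truncation tolerance of the uniformisation sums.
#' @return named list: \code{FINAL}, \code{CORRECT}, \code{DEADLOCK},
#'   \code{IN_TRANSIT}, \code{expected_steps}, \code{by_class},
#'   \code{n_states} (largest chain built).
#' @export
exact_transient <- function(c, a, tau, params = distance_params(),
                            semantics = "BURNT_BRIDGES",
                            block_weight = 0.7,
                            state_limit = 1e4, tol = 1e-12) {
  model <- compile_sim_model(c, params, semantics, block_weight)
  v <- c$vertices
  blocked <- match(blocked_vertices(c, a), v$id)
  b <- length(blocked)
  want_true <- evaluate_function(c, a)
  agg <- c(FINAL = 0, CORRECT = 0, DEADLOCK = 0, IN_TRANSIT = 0,
           expected_steps = 0)
  cls <- stats::setNames(numeric(length(STEP_CLASSES)), STEP_CLASSES)
  max_states <- 0L
  outcomes <- if (b == 0) list(integer(0)) else {
    lapply(0:(2^b - 1), function(k)
      blocked[as.logical(bitwAnd(k, 2^(seq_len(b) - 1)) > 0)])
  }
  for (succ in outcomes) {
    pr <- block_weight^length(succ) * (1 - block_weight)^(b - length(succ))
    res <- ctmc_transient(model, succ, tau, state_limit, tol)
    max_states <- max(max_states, res$n_states)
    agg["FINAL"] <- agg["FINAL"] + pr * res$final
    agg["CORRECT"] <- agg["CORRECT"] +
      pr * (if (want_true) res$final_true else res$final_false)
    agg["DEADLOCK"] <- agg["DEADLOCK"] + pr * res$dead
    agg["IN_TRANSIT"] <- agg["IN_TRANSIT"] + pr * res$transit
    agg["expected_steps"] <- agg["expected_steps"] + pr * res$steps
    cls <- cls + pr * res$by_class
  }
  c(as.list(agg), list(by_class = cls, n_states = max_states))
}

# CTMC over (position, availability) states for one fixed blocking outcome.
ctmc_transient <- function(model, blocked_success, tau, state_limit, tol) {
  v <- model$circuit$vertices
  n <- nrow(v)
  avail0 <- rep(1L, n)
  avail0[blocked_success] <- 0L
  burnt <- model$semantics == "BURNT_BRIDGES"
  enc <- function(pos, avail) paste(pos, paste(avail, collapse = ""))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  states <- list(list(pos = model$init, avail = avail0))
  assign(enc(model$init, avail0), 1L, envir = seen)
  kind <- integer(0)   # 0 live, 1 final, 2 dead (per state, filled below)
  edges_from <- integer(0); edges_to <- integer(0)
  edges_rate <- numeric(0); edges_class <- integer(0)
  head <- 1L
  while (head <= length(states)) {
    s <- states[[head]]
    if (model$is_final[s$pos]) {
      kind[head] <- 1L
    } else {
      sel <- which(model$step_from == s$pos & s$avail[model$step_to] == 1L)
      if (!length(sel)) {
        kind[head] <- 2L
      } else {
        kind[head] <- 0L
        for (k in sel) {
          avail2 <- s$avail
          if (burnt) avail2[s$pos] <- 0L
          pos2 <- model$step_to[k]
          key <- enc(pos2, avail2)
          j <- seen[[key]]
          if (is.null(j)) {
            states[[length(states) + 1L]] <- list(pos = pos2, avail = avail2)
            if (length(states) > state_limit)
              stop("exact_transient: state limit exceeded", call. = FALSE)
            j <- length(states)
            assign(key, j, envir = seen)
          }
          edges_from <- c(edges_from, head); edges_to <- c(edges_to, j)
          edges_rate <- c(edges_rate, model$step_rate[k])
          edges_class <- c(edges_class, model$step_class[k])
        }
      }
    }
    head <- head + 1L
  }
  ns <- length(states)
  exit <- rep(0, ns)
  if (length(edges_from)) {
    ex <- rowsum(edges_rate, edges_from)
    exit[as.integer(rownames(ex))] <- ex[, 1]
  }
  lam <- max(exit, model$params$k_s)     # uniformisation rate
  # P = I + Q/lam as sparse matrix
  P <- Matrix::sparseMatrix(
    i = c(edges_from, seq_len(ns)),
    j = c(edges_to, seq_len(ns)),
    x = c(edges_rate / lam, 1 - exit / lam),
    dims = c(ns, ns))
  K <- stats::qpois(1 - tol, lam * tau) + 10L
  pk <- stats::dpois(0:K, lam * tau)
  tail_gt <- 1 - stats::ppois(0:K, lam * tau)  # P(N > k)
  pi_k <- rep(0, ns); pi_k[1] <- 1
  pt <- pk[1] * pi_k
  soj <- tail_gt[1] * pi_k
  for (k in seq_len(K)) {
    pi_k <- as.numeric(Matrix::crossprod(P, pi_k))
    pt <- pt + pk[k + 1] * pi_k
    soj <- soj + tail_gt[k + 1] * pi_k
  }
  soj <- soj / lam                        # cumulative sojourn times in [0, tau]
  fin <- kind == 1L
  out_true_state <- vapply(states, function(s) model$out_true[s$pos], logical(1))
  by_class <- stats::setNames(numeric(length(STEP_CLASSES)), STEP_CLASSES)
  if (length(edges_from)) {
    contrib <- edges_rate * soj[edges_from]
    for (cl in seq_along(STEP_CLASSES)) {
      selc <- edges_class == cl
      if (any(selc)) by_class[cl] <- sum(contrib[selc])
    }
  }
  list(final = sum(pt[fin]),
       final_true = sum(pt[fin & out_true_state]),
       final_false = sum(pt[fin & !out_true_state]),
       dead = sum(pt[kind == 2L]),
       transit = sum(pt[kind == 0L]),
       steps = sum(by_class),
       by_class = by_class,
       n_states = ns)
}

#' Exact estimates averaged over all assignments
#'
#' Runs \code{\link{exact_transient}} for every input assignment and
#' averages uniformly, mirroring \code{\link{transient_estimates}} /
#' \code{\link{expected_rewards}} for small nets.
#'
#' @inheritParams exact_transient
#' @return as \code{\link{exact_transient}} plus \code{CONDITION}.
#' @export
exact_estimates <- function(c, tau, params = distance_params(),
                            semantics = "BURNT_BRIDGES", block_weight = 0.7,
                            state_limit = 1e4) {
  assigns <- all_assignments(c)
  res <- lapply(assigns, function(a)
    exact_transient(c, a, tau, params, semantics, block_weight, state_limit))
  avg <- function(f) mean(vapply(res, function(r) r[[f]], 1.0))
  by_class <- Reduce(`+`, lapply(res, `[[`, "by_class")) / length(res)
  out <- list(FINAL = avg("FINAL"), CORRECT = avg("CORRECT"),
              DEADLOCK = avg("DEADLOCK"), IN_TRANSIT = avg("IN_TRANSIT"),
              expected_steps = avg("expected_steps"), by_class = by_class)
  out$CONDITION <- if (out$FINAL > 0) out$CORRECT / out$FINAL else NA_real_
  out
}
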