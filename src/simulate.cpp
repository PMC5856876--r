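#include <Rcpp.h>
using namespace Rcpp;

// Continuous-time jump-process simulation of a walker net after the
// immediate blocking phase.  States are (walker position, availability
// vector); stepping transitions are given as an edge list sorted by
// source vertex with [start, end) index ranges per vertex.  Blocking
// outcomes are independent Bernoulli draws per blocked vertex (the
// immediate block/fail conflicts are local to each vertex).  Uses R's
// RNG so results are reproducible under set.seed().
//
// status codes: 0 = FINAL, 1 = DEAD, 2 = IN_TRANSIT
// [[Rcpp::export]]
List simulate_runs_cpp(int n_vertices,
                       IntegerVector step_from,   // 1-based source vertex
                       IntegerVector step_to,     // 1-based target vertex
                       NumericVector step_rate,
                       IntegerVector step_class,  // 1..n_classes
                       int n_classes,
                       IntegerVector range_start, // per-vertex [start,end)
                       IntegerVector range_end,   // 0-based into step arrays
                       int init,                  // 1-based
                       LogicalVector is_final,
                       IntegerVector blocked,     // 1-based vertex ids
                       double block_prob,
                       double tau,
                       int n_runs,
                       bool burnt_bridges) {
  IntegerVector status(n_runs);
  IntegerVector final_vertex(n_runs);
  NumericVector arrival(n_runs);
  IntegerMatrix class_steps(n_runs, n_classes);
  IntegerVector total_steps(n_runs);

  std::vector<int> avail(n_vertices);

  for (int r = 0; r < n_runs; ++r) {
    std::fill(avail.begin(), avail.end(), 1);
    for (int b = 0; b < blocked.size(); ++b)
      if (unif_rand() < block_prob) avail[blocked[b] - 1] = 0;

    int pos = init - 1;
    double t = 0.0;
    int st = 2;            // IN_TRANSIT unless decided otherwise
    double arr = NA_REAL;
    int fv = NA_INTEGER;

    for (;;) {
      if (is_final[pos]) { st = 0; arr = t; fv = pos + 1; break; }
      double total = 0.0;
      int s0 = range_start[pos], s1 = range_end[pos];
      for (int k = s0; k < s1; ++k)
        if (avail[step_to[k] - 1] == 1) total += step_rate[k];
      if (total <= 0.0) { st = 1; break; }     // DEAD
      double dt = exp_rand() / total;
      if (t + dt > tau) { st = 2; break; }     // horizon reached
      t += dt;
      double u = unif_rand() * total;
      double acc = 0.0;
      int chosen = -1, last_avail = -1;
      for (int k = s0; k < s1; ++k) {
        if (avail[step_to[k] - 1] != 1) continue;
        last_avail = k;
        acc += step_rate[k];
        if (u <= acc) { chosen = k; break; }
      }
      if (chosen < 0) chosen = last_avail;     // numerical guard
      if (burnt_bridges) avail[pos] = 0;       // source burnt on departure
      pos = step_to[chosen] - 1;
      class_steps(r, step_class[chosen] - 1) += 1;
      total_steps[r] += 1;
    }
    status[r] = st;
    arrival[r] = arr;
    final_vertex[r] = fv;
  }
  return List::create(_["status"] = status,
                      _["final_vertex"] = final_vertex,
                      _["arrival_time"] = arrival,
                      _["class_steps"] = class_steps,
                      _["total_steps"] = total_steps);
}
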