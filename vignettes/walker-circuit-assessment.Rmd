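---
title: "Assessing 2D DNA walker circuit designs with stochastic Petri nets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing 2D DNA walker circuit designs with stochastic Petri nets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walkernet)
```

## The system being modelled

In localised DNA computation, single-stranded anchorages are tethered to
an origami lattice and a walker strand moves between them by strand
displacement.  Arranged as a binary decision graph — linear tracks,
forking gates that test an input variable, joining gates that merge
branches, and final anchorages that report a truth value — the assembly
computes a Boolean function: the circuit is *programmed* by blocking
every anchorage whose label literal is false under the chosen inputs,
and the walker, released at the unique initial anchorage, performs a
random walk over the unblocked anchorages until it is absorbed at a
final one.

Two physical facts make such circuits unreliable.  First, a walker can
step to *any* anchorage within interaction range, not only to intended
neighbours; a step that crosses between branches of the decision graph
is a *leakage transition* and can deliver a wrong answer.  Second,
blocking itself is a chemical process that fails with appreciable
probability, letting the walker enter branches that should have been
closed.  This package quantifies both effects for a candidate layout
before it is synthesised.

## From a grid layout to a stochastic Petri net

A circuit is specified by integer grid coordinates (1-based, `x` = row,
`y` = column), a vertex type (`INIT`, `NORM`, `FORK`, `JOIN`, `FINAL`),
a label (a literal such as `x` or `!x`, or `eps` for unblockable
anchorages), an output value for finals, and the target Boolean
expression, which is stored with the circuit because correctness of a
run cannot be judged from the graph alone.

`unfold_gspn()` turns this into a generalised stochastic Petri net.
Every anchorage becomes a place holding one availability token; the
initial place holds a second token representing the walker.  For every
ordered pair of vertices within interaction range a timed stepping
transition is created.  Its rate is a piecewise function of the lattice
Euclidean distance $d$ between the two grid positions:

$$k(d) = \begin{cases} k_s & 0 < d \le d_S\\ k_s/50 & d_S < d \le d_M\\
k_s/100 & d_M < d \le d_L\\ 0 & \text{otherwise},\end{cases}$$

with defaults $d_S = 3$, $d_M = 5$, $d_L = 8$ grid units and
$k_s = 0.009\,\mathrm{s}^{-1}$.  One grid unit corresponds to half the
average anchorage spacing of $6.2\,\mathrm{nm}$, so the discrete
cutoffs sit exactly at $1.5$ and $2.5$ times the average spacing, and
$d_L = 8$ (i.e. $24.8\,\mathrm{nm}$) approximates the
$24\,\mathrm{nm}$ maximum interaction distance.  Band membership is
decided entirely in integer arithmetic ($d \le r \iff d^2 \le r^2$), so
classification is bit-exact; for the short band this lattice-$L_2$ ball
coincides with the union of the Manhattan ball of radius 3 and the
Chebyshev ball of radius 2, an identity the test suite verifies by
enumeration.  The same lattice-$L_2$ rule is applied to the medium and
long radii: a combination of $L_1$/$L_\infty$ balls is only a device for
realising lattice-$L_2$ membership, so we use the latter directly at
every radius.

Arc weights encode the stepping semantics.  Under *burnt bridges* (the
default, and the chemistry that is easiest to realise) a step consumes
both tokens of the source — the walker and the availability token — so
an anchorage can never be revisited; under the *unguided* semantics one
token is returned to the source.  Both variants keep the net 2-bounded:
a place holds at most the availability token plus the walker.  Steps
out of final anchorages are never generated, and every final place
carries a self-loop transition so that a walker resting on a final is
never a dead state; dead states therefore always mean a genuinely
trapped walker.  The self-loop needs a positive rate and carries no
reward, so its value is immaterial; we use $k_s$.

Blocking is modelled as in the standard fault model: every labelled
anchorage starts available, and an immediate (zero-delay,
highest-priority) conflict pair resolves its fate at time zero —
`block` (weight 0.7) removes the availability token, `fail` (weight
0.3) leaves the anchorage open.  Because each conflict touches only its
own anchorage, the joint outcome is a product of independent
Bernoulli(0.7) draws, an equivalence both the simulator and the exact
oracle exploit.

## Identifying leakage transitions

The short-band sub-graph of a well-designed layout is exactly the
intended decision DAG.  `index_places()` recovers that DAG by a
breadth-first search from the initial place, which receives index 1,
borrowing the array embedding of binary trees: a track keeps its index,
the two successors of a fork with index $c$ receive $2c$ and $2c+1$,
and joins merge indices back.  The successor relation excludes
neighbours that share the current index and the fork parent
($\lfloor\text{index}/2\rfloor$, integer division, so both children map
back to their parent).  While indexing, the algorithm records the set
$M$ of *known transition types* — triples (pre-index, post-index, type)
with type `TRACK`, `FORK`, `JOIN` or `LEAK`.

Six situations are distinguished: the initial place (single successor);
forks (two unindexed successors); joins (when two neighbours are still
unindexed the predecessor/successor decision is postponed and both are
treated as successors with the join's index); normal places with two
short neighbours (track continuation, entry into a join, re-encounter
of an indexed join, or an index override when the search backtracks
onto an earlier track); normal places with three short neighbours (the
same sub-cases tracked with a *marked* flag, plus `LEAK` triples for
indexed-but-unmarked successors — these are exactly the cross-branch
proximity pairs); and finals, which terminate branches.  Any other
configuration aborts with an ambiguity error naming the vertex; the
layout is then not an unambiguous embedding of a decision DAG and
should be fixed rather than analysed.

One situation is under-determined in the classic description: in a
fork–join diamond the second incoming track can reach a join whose
index is *larger* than its own.  We generalise the re-encounter case to
"successor is an indexed join with a different index" and record the
join triple; the recorded pair may then violate the usual join
arithmetic (index doubling or decreasing), which is why
`consistency_report()` treats the arithmetic patterns as advisory only
— classification is by lookup in $M$, never by arithmetic.

`classify_transitions()` then labels *every* stepping transition of the
unfolded net: the index pair of its endpoints is looked up in $M$ in
either order; a match inherits the recorded structural type and
everything else is a leak.  Crossed with the three distance bands this
gives the 12-way classification whose 4 × 4 table (rows
Track/Fork/Join/Leak, columns Short/Medium/Long/Σ) is the package's
structural fingerprint of a layout.  Short-distance leaks indicate
direct layout flaws; medium- and long-distance leaks quantify the
pressure that compactness puts on reliability.  Two geometric facts are
worth noting: the two children of a fork are necessarily within
$2 d_S$ of each other, so every layout with forks has at least one
leak-classified sibling pair in the medium or long band — a leak-free
table is achievable only in the short column — and the same holds
around joins.

Determinism: vertices are processed in lexicographic (row, column)
order everywhere — BFS queue, successor lists, net unfolding — so
identical circuits give bit-identical indexings, nets and tables.  The
choice of which fork child receives $2c$ is part of that convention;
the classification table is invariant under swapping it, which the
test suite asserts on generated circuits via
`index_places(fork_order = "swapped")`.

## Qualitative analysis

`build_reachability_graph()` enumerates all reachable markings, either
under GSPN priority semantics (immediates pre-empt timed transitions)
or time-free (both interleavings; the priority graph is a subgraph of
the time-free one).  On the graph we decide the classical behavioural
properties: boundedness (maximum token count), dead states (terminal
markings), reversibility (strong connectivity) and liveness (every
transition occurs in every terminal strongly connected component,
computed with igraph).  Walker nets built by this package are always
2-bounded and, under burnt bridges, neither reversible nor live, and
their time-free graphs are acyclic apart from the final self-loops;
these invariants are checked exhaustively on the packaged fixtures.
Exploration is explicit-state with a configurable limit (default
$5\times10^5$ markings, the practical range of explicit exploration);
exceeding it is a hard error, not a silent truncation.

## Stochastic analysis

All quantitative measures are evaluated at or up to a time horizon
$\tau$, default $12\,000$ s (200 minutes), and averaged uniformly over
all $2^{|In|}$ input assignments unless an explicit list is given.

* **Transient probabilities** (`transient_estimates()`): `FINAL`, the
  probability that the walker has reached any final anchorage by
  $\tau$ (finals are absorbing, so "at" equals "by"); `CORRECT`, that
  it reached a final whose output equals the function value for the
  inputs; `DEADLOCK`, that it is trapped; and the conditional
  `CONDITION = CORRECT / FINAL`, computed as a ratio of the averaged
  estimates and reported as undefined when `FINAL` is zero.
* **Expected impulse rewards** (`expected_rewards()`): every stepping
  transition carries impulse reward one (loops and the immediate
  block/fail pairs carry none), accumulated until $\tau$ — the expected
  number of steps, reported in total and per classification class.
  Class expectations sum to the total exactly because all estimators
  share one set of trajectories.
* **Performability** (`step_distribution()`): the empirical PMF/CDF of
  the number of (classified) steps among runs that reach a final
  within $\tau$; the CDF converges to the `FINAL` probability, not 1.

The simulator resolves the blocking conflicts as Bernoulli draws at
time zero and then runs the exact continuous-time jump process over the
stepping transitions (the race of exponential clocks), stopping at
absorption, at a dead marking, or when the next jump would pass $\tau$.
Runs stop on reaching a final: final self-loops carry no reward and
finals cannot be left, so this is observationally equivalent for every
shipped query.  The core loop is in C++ (Rcpp) and uses R's RNG, so a
`sim_config()` seed makes results bit-reproducible.  Random numbers are
drawn from that single seeded stream in a fixed order (assignment by
assignment, run by run) rather than from per-run counter-based
substreams; since the schedule is deterministic, reproducibility is
unaffected.  Every estimate is reported with a normal-approximation
standard error; the default 20 000 runs per assignment put the standard
error of mid-range probabilities below half a percentage point.

`exact_transient()` is the package's oracle: for one assignment it
enumerates the blocking outcomes analytically (avoiding any
vanishing-marking elimination), builds the continuous-time Markov chain
over (walker position, availability vector) states, and computes
transient probabilities by uniformisation together with expected
accumulated impulse rewards via cumulative sojourn times
$\int_0^\tau \pi_s(u)\,du$.  The Poisson sum is truncated at a
$10^{-12}$ tail with a small safety margin, giving answers exact to
well below simulation resolution on nets up to $10^4$ states.  The test
suite drives the simulator against this oracle on generated circuits
and against closed forms ($1 - e^{-k_s\tau}$ for a single short step,
$1 - e^{-1.08}$ for a blocked line with only a long escape, and a dense
matrix-exponential mixture for the 0.7/0.3 fault model).

## Packaged layouts and the synthetic generator

The package ships two layouts of the disjunction `x | y | z` as a
binary decision DAG (three forks testing x, y, z; the three true
branches merging through two joins into the true final; the all-false
path ending in the false final).  The *naive* layout packs the branches
tightly, the *optimised* layout spreads them.  Both are synthetic
reconstructions, as their file names state: segment lengths were chosen
to balance the BFS depth of each join's two predecessors (which is what
makes the short sub-graph unambiguous for the indexing algorithm), and
coordinates were then fitted by a combinatorial search so that each
layout's 12-cell classification table reproduces the reference profile
for its design style — identical short-band structure (Track 64/66,
Fork 12, Join 8) with 8 versus 2 short leak transitions and a roughly
halved total leak count in the optimised layout.  The fixtures are
data files, so a corrected transcription never requires code changes;
their tables and per-vertex indices are frozen in the test suite and
any edit that changes them fails loudly.

`random_circuit()` generates property-test inputs: full binary decision
trees over $n$ variables, branches diverging diagonally onto disjoint
horizontal bands separated by `branch_separation` rows, track lengths
drawn from a configurable range, leaf outputs computed from the (random
or given) Boolean expression, and the same seed always yielding the
same circuit.  All intended steps have lattice distance 2, so a
separation above $d_S$ makes the short sub-graph exactly the intended
tree — generated circuits are short-leak-free by construction, which
the tests assert.  The generator deliberately emulates only tree
circuits (no joins: join-handling is exercised by the packaged
fixtures), places no anchorage defects, and does not emulate spatial
correlation of blocking failures; passing property tests on generated
circuits therefore says nothing about those real-world effects, only
about the correctness of the algorithms on clean decision trees.

## Numerical and design choices

* Band decisions and index arithmetic are pure integer computations;
  the only floating point is in rates, probabilities and times.
* The declared edge set of a circuit file is optional and used only for
  degree validation; steps are always derived from distances, so the
  intended DAG must be realised geometrically, not declared.
* Steps targeting the initial anchorage are generated like any other;
  under burnt bridges they are harmless (its availability token is
  consumed on departure).
* `exact_transient()` uniformises with the maximum exit rate (at least
  $k_s$) and shares its state enumeration with nothing else — it is an
  independent check on the simulator, not a code path reused by it.
* Simulation sizes in the tests are chosen to keep the whole suite in
  the minutes range: closed-form checks use 3 000–20 000 runs, the
  oracle-versus-simulator comparison uses 21 small circuits at 2 000
  runs per assignment with a four-standard-error band (about one
  comparison in ten thousand fails by chance), and the layout studies
  use 20 000 runs per assignment.
* The time-free reachability graphs of the two packaged layouts are far
  beyond explicit enumeration (the blocking interleavings multiply an
  already large walker state space), so the exhaustive qualitative
  property checks run on the toy fixture, the line fixtures and
  generated single-variable circuits, where full graphs have at most a
  few thousand markings.

## Limitations

Only 2D lattices are supported, though nothing in the stencil design
assumes two coordinates; labels are single literals, not arbitrary
Boolean expressions; there is no layout synthesis or optimisation —
the package assesses and compares given layouts; and the CTMC oracle
is exponential in the number of blocked anchorages per assignment, so
it is a validation tool for small nets, not a replacement for
simulation.
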