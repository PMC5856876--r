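Package: walkernet
Title: Design Assessment of 2D DNA Walker Circuits via Stochastic Petri Nets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the reliability of localised DNA computing
    circuits in which a DNA walker moves across a grid of tethered anchorages
    to evaluate a Boolean function.  A grid-embedded circuit specification is
    unfolded into a generalised stochastic Petri net under burnt-bridges or
    unguided stepping semantics with a probabilistic anchorage-blocking fault
    model.  Unintended (leakage) walker steps are identified automatically by
    a breadth-first place-indexing algorithm and all stepping transitions are
    classified by structural role (track, fork, join, leak) and distance band
    (short, medium, long).  Circuit designs can then be compared by
    qualitative state-space analysis (boundedness, dead states, reversibility,
    liveness) and by stochastic simulation of transient probabilities,
    expected impulse rewards, and step-count performability distributions,
    backed by an exact uniformisation oracle on small state spaces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    yaml,
    igraph,
    Matrix,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
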