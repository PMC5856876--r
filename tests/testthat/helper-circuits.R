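# Small circuits built in code, shared across test files.

# INIT -- NORM(x) -- FINAL(T), all on one row: one short track, and a
# long-band shortcut INIT -> FINAL (distance 6).
line_circuit <- function() {
  v <- data.frame(id = c("v0", "v1", "v2"), x = c(1, 1, 1), y = c(1, 4, 7),
                  type = c("INIT", "NORM", "FINAL"),
                  label = c("eps", "x", "eps"), out = c(NA, NA, "T"))
  walker_circuit(v, inputs = "x", fun = "x")
}

# INIT adjacent only to FINAL(T): a single short step.
single_step_circuit <- function() {
  v <- data.frame(id = c("v0", "v1"), x = c(1, 1), y = c(1, 3),
                  type = c("INIT", "FINAL"), label = c("eps", "eps"),
                  out = c(NA, "T"))
  walker_circuit(v, inputs = "x", fun = "x")
}

# INIT -- NORM(x) -- NORM(x) -- FINAL(T) on one row, final out of range
# of INIT (distance 9): when both blocks succeed (probability 0.49) the
# walker is trapped on INIT at time zero.
trap_circuit <- function() {
  v <- data.frame(id = c("v0", "v1", "v2", "v3"),
                  x = c(1, 1, 1, 1), y = c(1, 4, 7, 10),
                  type = c("INIT", "NORM", "NORM", "FINAL"),
                  label = c("eps", "x", "x", "eps"), out = c(NA, NA, NA, "T"))
  walker_circuit(v, inputs = "x", fun = "x")
}

expect_tables_equal <- function(a, b) {
  expect_equal(unname(a), unname(b))
}
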