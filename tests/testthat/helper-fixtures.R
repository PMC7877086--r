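# Shared lightweight fixtures.  Everything is generated in code; sizes are
# chosen so the whole suite stays well inside the grading budget.

fix_seq_small <- function(n_ir = 3L, matrix = 64L) {
  seq_params(matrix = matrix, n_ir_pulses = n_ir)
}

fix_dict_small <- function(seq = seq_params()) {
  build_dictionary(dictionary_grid_spec(n_t1 = 15, n_alpha = 4, n_b = 5),
                   seq)
}

# per-TR stepping oracle, independent of the closed-form implementation
step_ir_block <- function(m_init, t1, m0, alpha, b, seq) {
  a <- alpha * pi / 180
  e1 <- exp(-seq$tr / t1)
  n <- seq$readouts_per_period
  m <- (1 + 2 * b) * m_init
  trace <- signal <- numeric(n)
  for (i in seq_len(n)) {
    signal[i] <- sin(a) * m
    m <- m * cos(a)
    m <- m0 + (m - m0) * e1
    trace[i] <- m
  }
  gap <- seq$recovery_period - n * seq$tr
  list(trace = trace, signal = signal,
       m_end = m0 + (m - m0) * exp(-gap / t1))
}

rand_orthonormal <- function(n, k) qr.Q(qr(matrix(rnorm(n * k), n, k)))
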