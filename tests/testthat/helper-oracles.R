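# Independent oracle for the cross-type chain: left-multiplication by the
# transition matrix in plain double arithmetic (no shared code with the
# package's dyadic stepper).
chain_oracle <- function(generations, start = c(1, 0, 0, 0)) {
  M <- matrix(c(1 / 2, 1 / 2, 0, 0,
                0, 1 / 2, 1 / 4, 1 / 4,
                0, 1, 0, 0,
                0, 0, 0, 1), nrow = 4, byrow = TRUE)
  out <- matrix(NA_real_, generations + 1L, 4)
  v <- start
  out[1, ] <- v
  for (t in seq_len(generations)) {
    v <- as.vector(v %*% M)
    out[t + 1L, ] <- v
  }
  colnames(out) <- c("A", "B", "C", "D")
  out
}

# Binomial 3-standard-error band check
within_3se <- function(estimate, truth, n) {
  se <- sqrt(truth * (1 - truth) / n)
  abs(estimate - truth) <= 3 * se
}
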