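# Independent oracles used to check the analytical implementations.

# Brute-force Monte-Carlo of tetrad-class probabilities: Poisson(x) exchanges
# per bivalent, each swapping the distal alleles of one uniformly chosen
# chromatid per homolog. Returns the PD/TT/NPD proportions.
mc_tetrad_class_probs <- function(x, n_meioses) {
  k <- stats::rpois(n_meioses, x)
  state <- matrix(rep(c(1L, 1L, 2L, 2L), each = n_meioses), nrow = n_meioses)
  if (max(k) > 0) {
    for (r in seq_len(max(k))) {
      act <- which(k >= r)
      ia <- cbind(act, sample(1:2, length(act), replace = TRUE))
      ib <- cbind(act, sample(3:4, length(act), replace = TRUE))
      tmp <- state[ia]
      state[ia] <- state[ib]
      state[ib] <- tmp
    }
  }
  recomb <- rowSums(state[, 1:2, drop = FALSE] == 2L) +
    rowSums(state[, 3:4, drop = FALSE] == 1L)
  c(PD = mean(recomb == 0L), TT = mean(recomb == 2L), NPD = mean(recomb == 4L))
}

# Exhaustive-enumeration Fisher oracle: sums the probabilities (computed from
# binomial coefficients directly) of all tables sharing the observed margins
# whose probability does not exceed the observed table's.
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  p <- exp(lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(n, c1))
  p_obs <- exp(lchoose(r1, a) + lchoose(r2, c) - lchoose(n, c1))
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}
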