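# Brute-force statistical oracles, independent of the package
# implementations.

# two-sided Mann-Whitney p by full enumeration of rank assignments:
# probability of a deviation of the rank sum from its null mean at least
# as large as observed
bf_mw_p <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  uobs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(r), n1)
  u <- apply(combos, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  mean(abs(u - mu) >= abs(uobs - mu) - 1e-9)
}

# exact conditional probabilities of all 2x2 tables with margins
# (r1, n - r1) x (c1, n - c1), indexed by the top-left cell a
fisher_enumeration <- function(r1, c1, n) {
  av <- max(0, r1 + c1 - n):min(r1, c1)
  data.frame(a = av, prob = stats::dhyper(av, c1, n - c1, r1))
}
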