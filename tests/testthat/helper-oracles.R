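# Independent brute-force oracles used by several test files.

# Exhaustive two-sided exact Mann-Whitney p: enumerate all C(n1+n2, n1)
# group labelings of the pooled data and count how extreme U1 is in each
# tail.
enum_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); N <- length(pooled)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  obs <- u_of(seq_len(n1))
  combos <- utils::combn(N, n1)
  us <- apply(combos, 2, u_of)
  min(1, 2 * min(mean(us <= obs), mean(us >= obs)))
}
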