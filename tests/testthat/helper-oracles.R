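# Independent statistical oracles shared across test files.

# brute-force Fisher oracle: enumerate all tables with the observed margins,
# probabilities from the factorial formula (no dhyper)
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  c2 <- n - c1
  lp <- function(a) {
    b <- r1 - a; c <- c1 - a; d <- r2 - c
    if (b < 0 || c < 0 || d < 0) return(-Inf)
    lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
      lfactorial(n) - lfactorial(a) - lfactorial(b) - lfactorial(c) -
      lfactorial(d)
  }
  as_ <- 0:min(r1, c1)
  probs <- exp(vapply(as_, lp, 0))
  sum(probs[probs <= exp(lp(tab[1, 1])) * (1 + 1e-7)])
}

# full permutation-enumeration oracle for the exact rank-sum p
rank_sum_oracle <- function(a, b) {
  rk <- rank(c(a, b))
  na <- length(a); N <- length(rk)
  W <- sum(rk[seq_len(na)])
  mu <- na * sum(rk) / N
  sets <- utils::combn(N, na)
  sums <- colSums(matrix(rk[sets], nrow = na))
  mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
}
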