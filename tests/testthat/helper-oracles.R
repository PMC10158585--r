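## Independent brute-force oracles shared across test files.

## Signed-rank: enumerate all 2^n sign patterns.
bruteSignedRank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  allW <- grid %*% r
  pGe <- mean(allW >= W - 1e-12)
  pLe <- mean(allW <= W + 1e-12)
  list(W = W, p = min(1, 2 * min(pGe, pLe)))
}

## Manual BH step-up.
bruteBh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= seq_len(m) * q / m)
  out <- rep(FALSE, m)
  if (length(ok)) out[o[seq_len(max(ok))]] <- TRUE
  out
}
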