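# Shared fixtures and independent oracle implementations used across the
# suite. Oracles are written directly from the measure definitions (loops,
# explicit pattern counts) so they share no code with the package.

# Uniformly-labelled recording with given sample count.
makeRecording <- function(n, label = "W", subject = "s1", seed = 1) {
  withr::with_seed(seed,
    AccelRecording(subject, matrix(rnorm(3 * n), ncol = 3),
                   rep(label, n)))
}

# Window matrix helper.
makeWindow <- function(n = 300, seed = 1) {
  withr::with_seed(seed, matrix(rnorm(3 * n), ncol = 3))
}

# --- brute-force diversity oracles (definition-level, loop-based) ----------

oracleDisagreementPair <- function(ci, ck) {
  n11 <- sum(ci == 1 & ck == 1); n00 <- sum(ci == 0 & ck == 0)
  n10 <- sum(ci == 1 & ck == 0); n01 <- sum(ci == 0 & ck == 1)
  (n01 + n10) / (n11 + n10 + n01 + n00)
}

oracleDisagreementAvg <- function(M) {
  L <- nrow(M); tot <- 0; cnt <- 0
  for (i in seq_len(L)) for (k in seq_len(L)) if (i < k) {
    tot <- tot + oracleDisagreementPair(M[i, ], M[k, ]); cnt <- cnt + 1
  }
  tot / cnt
}

oracleEntropy <- function(M) {
  L <- nrow(M); N <- ncol(M)
  s <- 0
  for (i in seq_len(N)) {
    l <- sum(M[, i])
    s <- s + min(l, L - l) / (L - ceiling(L / 2))
  }
  s / N
}

oracleCFD <- function(M) {
  L <- nrow(M); N <- ncol(M)
  fails <- integer(N)
  for (i in seq_len(N)) fails[i] <- sum(M[, i] == 0)
  P0 <- sum(fails == 0) / N
  if (P0 == 1) return(0)
  s <- 0
  for (i in seq_len(L)) s <- s + (L - i) / (L - 1) * (sum(fails == i) / N)
  s / (1 - P0)
}

oracleTheta <- function(M)
  oracleDisagreementAvg(M) + oracleEntropy(M) + oracleCFD(M)

# Greedy ranking oracle, re-derived from the procedure with the oracle
# measures only.
oracleRanking <- function(M, valAcc) {
  T <- nrow(M)
  sel <- which(valAcc == max(valAcc))[1]
  rest <- setdiff(seq_len(T), sel)
  while (length(rest)) {
    th <- sapply(rest, function(e) oracleTheta(M[c(sel, e), , drop = FALSE]))
    best <- rest[which(th == max(th))]
    best <- min(best)
    sel <- c(sel, best)
    rest <- setdiff(rest, best)
  }
  sel
}

# All binary T x N matrices, as a list (T*N <= 12).
allBinaryMatrices <- function(T, N) {
  k <- T * N
  lapply(0:(2^k - 1), function(code) {
    bits <- as.integer(intToBits(code))[seq_len(k)]
    matrix(bits, nrow = T, ncol = N)
  })
}

# Printed 8-activity confusion matrix used as metrics input.
referenceConfusion <- function() {
  as.matrix(read.csv(system.file("extdata", "confusion_kfda_example.csv",
                                 package = "harensemble"),
                     row.names = 1, check.names = FALSE))
}
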