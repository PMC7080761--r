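# Independent oracles used by both the unit and acceptance suites.

# Step-by-step TMM reimplementation (plain loops, no shared code with the
# package's vectorized implementation).
tmm_oracle <- function(x) {
  N <- colSums(x)
  uq <- sapply(seq_len(ncol(x)), function(j) quantile(x[, j], 0.75) / N[j])
  ref <- which.min(abs(uq - mean(uq)))
  f <- numeric(ncol(x))
  for (k in seq_len(ncol(x))) {
    if (k == ref) { f[k] <- 1; next }
    keep0 <- x[, k] > 0 & x[, ref] > 0
    o <- x[keep0, k]; r <- x[keep0, ref]
    m <- log2((o / N[k]) / (r / N[ref]))
    a <- 0.5 * log2((o / N[k]) * (r / N[ref]))
    w <- (N[k] - o) / (N[k] * o) + (N[ref] - r) / (N[ref] * r)
    n <- length(m)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    kp <- rank(m) >= loM & rank(m) <= hiM & rank(a) >= loA & rank(a) <= hiA
    f[k] <- 2^(sum(m[kp] / w[kp]) / sum(1 / w[kp]))
  }
  f / exp(mean(log(f)))
}

# One-sided (enrichment) Fisher p for the 2x2 table (a, b, c, d) by direct
# enumeration of the hypergeometric upper tail on the log scale.
hyper_tail_oracle <- function(a, b, c, d) {
  K <- a + c          # reference-expressed genes
  n <- a + b          # query-expressed genes
  N <- a + b + c + d
  ks <- a:min(K, n)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# Binary query/reference vectors realizing the 2x2 table (a, b, c, d)
table_vectors <- function(a, b, c, d) {
  ids <- sprintf("g%05d", seq_len(a + b + c + d))
  qs <- c(rep(TRUE, a + b), rep(FALSE, c + d))
  rs <- c(rep(TRUE, a), rep(FALSE, b), rep(TRUE, c), rep(FALSE, d))
  list(query = matrix(qs, ncol = 1, dimnames = list(ids, "q")),
       reference = matrix(rs, ncol = 1, dimnames = list(ids, "r")))
}
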