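# Independent brute-force oracles used to validate the package's
# implementations on small instances, plus tiny fixture builders.

# greedy max-min Kennard-Stone, written directly from the definition
ks_oracle <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- as.matrix(dist(X))
  best <- c(1L, 2L); bd <- -Inf
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (D[i, j] > bd) { bd <- D[i, j]; best <- c(i, j) }
  sel <- best
  while (length(sel) < k) {
    cand <- setdiff(seq_len(n), sel)
    md <- sapply(cand, function(c) min(D[c, sel]))
    sel <- c(sel, cand[which.max(md)])
  }
  sel
}

# naive double-loop Relief-F with all samples as anchors, Manhattan diffs on
# min-max scaled features
relieff_oracle <- function(X, y, k) {
  X <- as.matrix(X)
  n <- nrow(X); f <- ncol(X)
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  span <- hi - lo; span[span == 0] <- 1
  Xs <- sweep(sweep(X, 2, lo), 2, span, "/")
  w <- numeric(f)
  for (i in 1:n) {
    d <- numeric(n)
    for (j in 1:n) d[j] <- sum(abs(Xs[i, ] - Xs[j, ]))
    hits <- setdiff(order(d, seq_len(n)), i)
    hits <- hits[y[hits] == y[i]][1:k]
    miss <- setdiff(order(d, seq_len(n)), i)
    miss <- miss[y[miss] != y[i]][1:k]
    for (ff in 1:f) {
      w[ff] <- w[ff] +
        sum(abs(Xs[i, ff] - Xs[miss, ff])) / (n * k) -
        sum(abs(Xs[i, ff] - Xs[hits, ff])) / (n * k)
    }
  }
  w
}

# Mann-Whitney U statistic by direct pair counting
u_statistic_oracle <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  u <- 0
  for (p in pos) for (q in neg) u <- u + (p > q) + 0.5 * (p == q)
  u
}

# exhaustive threshold scan for the best Youden J (lowest cutoff on ties)
youden_oracle <- function(scores, y) {
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, (head(s, -1) + tail(s, -1)) / 2, s[length(s)] + 1)
  j <- sapply(cand, function(t) {
    sens <- mean(scores[y == 1] >= t); spec <- mean(scores[y == 0] < t)
    sens + spec - 1
  })
  cand[which.max(j)]
}

# small spectra_set on an integer grid with given rows
make_set <- function(mat, labels, lo = 1300, analytes = NULL, mmse = NULL) {
  mat <- as.matrix(mat)
  grid <- wavenumber_grid(seq(lo + ncol(mat) - 1, lo, by = -1))
  spectra_set(grid, mat, labels, analytes = analytes, mmse = mmse)
}

# default AD/HC cohort at reduced size for fast pipeline-level tests
small_design <- function(seed = 1, n = 40, ...) {
  cohort_design(n_per_group = n, groups = c("AD", "HC"), seed = seed, ...)
}
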