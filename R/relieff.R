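#' Relief-F feature ranking for a binary contrast
#'
#' Kononenko-style Relief-F with every sample as an anchor. Features are
#' min-max scaled to \[0, 1\] internally; for each anchor the weight of
#' feature `f` accumulates the mean absolute scaled difference to the `k`
#' nearest misses (other class) minus that to the `k` nearest hits (same
#' class), divided by the number of anchors. Neighbour search uses the total
#' Manhattan distance on the scaled features (the same per-feature diff metric
#' the update uses); neighbour ties resolve by lower row index. Weights lie in
#' \[-1, 1\].
#'
#' @param X Numeric samples x features matrix; columns named by wavenumber.
#' @param y Binary label vector (two distinct values).
#' @param k_neighbors Neighbours per class; must be < min class size.
#' @return Object of class `feature_ranking`: data frame with columns
#'   `wavenumber` (numeric column name, or column index if unnamed), `weight`,
#'   `rank`, ordered by descending weight (ties by column order).
#' @export
relieff <- function(X, y, k_neighbors = 10L) {
  X <- as.matrix(X)
  y <- as.vector(y)
  n <- nrow(X); f <- ncol(X)
  classes <- unique(y)
  if (length(classes) != 2L) stop("y must contain exactly two classes")
  k <- as.integer(k_neighbors)
  if (k < 1L || k >= min(table(y)))
    stop("k_neighbors must be >= 1 and < the smaller class size")
  rng <- apply(X, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  span[span == 0] <- 1                       # constant feature -> all diffs 0
  Xs <- sweep(sweep(X, 2L, rng[1L, ]), 2L, span, "/")
  D <- as.matrix(stats::dist(Xs, method = "manhattan"))
  w <- numeric(f)
  for (i in seq_len(n)) {
    same <- which(y == y[i]); same <- same[same != i]
    diff_cl <- which(y != y[i])
    hits <- same[order(D[i, same], same)][seq_len(k)]
    miss <- diff_cl[order(D[i, diff_cl], diff_cl)][seq_len(k)]
    xh <- abs(Xs[hits, , drop = FALSE] -
                rep(Xs[i, ], each = k))
    xm <- abs(Xs[miss, , drop = FALSE] -
                rep(Xs[i, ], each = k))
    w <- w + (colSums(xm) - colSums(xh)) / (n * k)
  }
  wn <- suppressWarnings(as.numeric(colnames(X)))
  if (is.null(colnames(X)) || anyNA(wn)) wn <- seq_len(f)
  o <- order(w, decreasing = TRUE)
  structure(data.frame(wavenumber = wn[o], weight = w[o],
                       rank = seq_len(f)),
            class = c("feature_ranking", "data.frame"))
}

#' @export
print.feature_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("<feature_ranking> %d features; top %d:\n", nrow(x),
              min(n, nrow(x))))
  print.data.frame(utils::head(as.data.frame(x), n), row.names = FALSE)
  invisible(x)
}

#' Relief-F ranking of a spectra set contrast
#'
#' Convenience wrapper running [relieff()] on the rows of `set` belonging to
#' the two labels of `contrast`.
#'
#' @param set A [spectra_set] (typically preprocessed).
#' @param contrast Character pair, e.g. `c("AD", "HC")`.
#' @param k_neighbors Passed to [relieff()].
#' @return A `feature_ranking` with wavenumber columns.
#' @export
rank_features <- function(set, contrast, k_neighbors = 10L) {
  rows <- which(set$labels %in% contrast)
  X <- set$matrix[rows, , drop = FALSE]
  colnames(X) <- format_wn(set$grid$values)
  relieff(X, set$labels[rows], k_neighbors)
}
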