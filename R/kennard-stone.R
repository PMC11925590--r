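#' Kennard-Stone max-min sample selection
#'
#' Deterministic greedy selection of `k` representative samples: the first two
#' are the pair at maximal Euclidean distance; each subsequent pick maximizes
#' its minimum distance to the already-selected set. Ties are broken by lowest
#' row index (for the initial pair, lowest first index then lowest second).
#'
#' @param X Numeric samples x features matrix (no NA).
#' @param k Number of samples to select, `2 <= k <= nrow(X)`.
#' @return Integer vector of length `k`, row indices in selection order.
#' @export
kennard_stone <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (anyNA(X)) stop("X must not contain NA")
  if (k < 2 || k > n) stop("k must lie in [2, nrow(X)]")
  D <- as.matrix(stats::dist(X))
  # initial pair: maximal distance, scanning i<j in index order (keeps the
  # lowest-index pair among ties)
  best <- -Inf; bi <- 1L; bj <- 2L
  for (i in seq_len(n - 1L)) {
    j_rel <- unname(which.max(D[i, (i + 1L):n]))
    d <- D[i, i + j_rel]
    if (d > best) { best <- d; bi <- i; bj <- i + j_rel }
  }
  sel <- c(bi, bj)
  mind <- pmin(D[, bi], D[, bj])
  mind[sel] <- -Inf
  while (length(sel) < k) {
    nxt <- unname(which.max(mind))   # which.max takes the lowest index on ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
    mind[nxt] <- -Inf
  }
  as.integer(sel)
}

#' Kennard-Stone train/validation/test split
#'
#' Partitions a cohort into discovery, validation and test sets with the
#' 7:1.5:1.5 design: KS selects `round(r1 * n)` training samples, KS re-run on
#' the remainder selects `round(r2 * n)` validation samples, and the rest form
#' the test set. With `stratify = TRUE` (default) the procedure runs per
#' diagnosis class and the parts are unioned, so no class can dominate the
#' held-out sets.
#'
#' @param set A [spectra_set] (distances are computed on its matrix, i.e. on
#'   whatever representation — typically the preprocessed second-derivative
#'   spectra — the caller passes in).
#' @param ratios Three positive fractions summing to 1; default
#'   `c(0.70, 0.15, 0.15)`.
#' @param stratify Split per class and union the parts.
#' @return Object of class `split_assignment` with fields `train_idx`,
#'   `val_idx`, `test_idx` (disjoint, union = all rows) and `ratios`.
#' @export
ks_split <- function(set, ratios = c(0.70, 0.15, 0.15), stratify = TRUE) {
  stopifnot(inherits(set, "spectra_set"))
  if (length(ratios) != 3L || any(ratios <= 0) ||
      abs(sum(ratios) - 1) > 1e-8)
    stop("ratios must be three positive fractions summing to 1")
  split_one <- function(rows) {
    n <- length(rows)
    if (n < 7L) stop("class too small for a 3-way split (need >= 7, got ", n, ")")
    X <- set$matrix[rows, , drop = FALSE]
    k_train <- max(2L, as.integer(round(ratios[1L] * n)))
    tr <- kennard_stone(X, k_train)
    rest <- setdiff(seq_len(n), tr)
    k_val <- max(1L, as.integer(round(ratios[2L] * n)))
    k_val <- min(k_val, length(rest) - 1L)
    va <- if (k_val >= 2L)
      rest[kennard_stone(X[rest, , drop = FALSE], k_val)]
    else rest[1L]
    te <- setdiff(rest, va)
    list(train = rows[tr], val = rows[va], test = rows[te])
  }
  if (stratify) {
    parts <- lapply(unique(set$labels),
                    function(g) split_one(which(set$labels == g)))
    out <- list(train_idx = sort(unlist(lapply(parts, `[[`, "train"))),
                val_idx = sort(unlist(lapply(parts, `[[`, "val"))),
                test_idx = sort(unlist(lapply(parts, `[[`, "test"))))
  } else {
    p <- split_one(seq_len(nrow(set$matrix)))
    out <- list(train_idx = sort(p$train), val_idx = sort(p$val),
                test_idx = sort(p$test))
  }
  structure(c(out, list(ratios = ratios, stratified = stratify)),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("<split_assignment> train %d / val %d / test %d (ratios %s%s)\n",
              length(x$train_idx), length(x$val_idx), length(x$test_idx),
              paste(x$ratios, collapse = ":"),
              if (isTRUE(x$stratified)) ", stratified" else ""))
  invisible(x)
}

#' Serialize a split assignment to JSON
#' @param split A `split_assignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_split_json <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
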