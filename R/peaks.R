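#' Detect absorption peaks with a prominence criterion
#'
#' Local maxima of the absorbance trace whose topographic prominence is at
#' least `prominence_frac` of the spectrum's full range, thinned so that
#' retained peaks are at least `min_separation` cm^-1 apart (taller peaks
#' win).
#'
#' @param s A [spectrum].
#' @param prominence_frac Minimum prominence as a fraction of
#'   `max(absorbance) - min(absorbance)`.
#' @param min_separation Minimum distance between reported peaks (cm^-1).
#' @return Object of class `peak_set`: list with `peaks` (ascending
#'   wavenumbers), `heights`, `prominences`, and `protein` (from the spectrum
#'   metadata, or NA).
#' @export
detect_peaks <- function(s, prominence_frac = 0.05, min_separation = 0) {
  stopifnot(inherits(s, "spectrum"))
  y <- s$absorbance
  n <- length(y)
  if (n < 3L) return(structure(list(peaks = numeric(), heights = numeric(),
                                    prominences = numeric(),
                                    protein = if (!is.null(s$meta$protein))
                                      s$meta$protein else NA),
                               class = "peak_set"))
  ii <- 2:(n - 1L)
  cand <- ii[y[ii] > y[ii - 1L] & y[ii] > y[ii + 1L]]
  # topographic prominence: walk out to the nearest higher point on each side,
  # tracking the lowest saddle; prominence = peak - higher of the two saddles
  prom <- vapply(cand, function(i) {
    lo_l <- y[i]; j <- i - 1L
    while (j >= 1L && y[j] <= y[i]) { lo_l <- min(lo_l, y[j]); j <- j - 1L }
    lo_r <- y[i]; j <- i + 1L
    while (j <= n && y[j] <= y[i]) { lo_r <- min(lo_r, y[j]); j <- j + 1L }
    y[i] - max(lo_l, lo_r)
  }, numeric(1L))
  thr <- prominence_frac * (max(y) - min(y))
  keep <- cand[prom >= thr]
  promk <- prom[prom >= thr]
  if (min_separation > 0 && length(keep) > 1L) {
    o <- order(y[keep], decreasing = TRUE)
    chosen <- integer()
    for (i in o) {
      if (!length(chosen) ||
          all(abs(s$grid$values[keep[i]] - s$grid$values[chosen]) >=
                min_separation))
        chosen <- c(chosen, keep[i])
    }
    promk <- promk[match(chosen, keep)]
    keep <- chosen
  }
  o <- order(s$grid$values[keep])
  structure(list(peaks = s$grid$values[keep][o], heights = y[keep][o],
                 prominences = promk[o],
                 protein = if (!is.null(s$meta$protein)) s$meta$protein else NA),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set>%s %d peak(s): %s\n",
              if (!is.na(x$protein)) paste0(" [", x$protein, "]") else "",
              length(x$peaks), paste(round(x$peaks, 1), collapse = ", ")))
  invisible(x)
}

#' Match selected features to purified-protein absorption peaks
#'
#' Intersects a machine-learning-selected feature list with the absorption
#' peaks of the purified pathogenic proteins: a feature enters the panel iff
#' its distance to the nearest peak of any protein is at most `tol` cm^-1
#' (boundary inclusive). Ties across proteins break by smaller distance, then
#' registry order (abeta42, ptau, gfap).
#'
#' @param features Numeric wavenumbers (the ML-preselected markers, in rank
#'   order).
#' @param peaksets List of [detect_peaks()] results (or any list with `peaks`
#'   and `protein` fields), in registry order.
#' @param tol Adjacency tolerance in cm^-1 (default 8, two instrument
#'   resolution elements).
#' @return Object of class `biomarker_panel`: data frame with columns
#'   `wavenumber`, `relieff_rank` (position in `features`), `matched_protein`,
#'   `peak_distance`, one row per panel member (possibly zero rows).
#' @export
match_features_to_peaks <- function(features, peaksets, tol = 8) {
  if (tol < 0) stop("tol must be >= 0")
  rows <- lapply(seq_along(features), function(i) {
    f <- features[i]
    best_d <- Inf; best_p <- NA_character_
    for (ps in peaksets) {
      if (!length(ps$peaks)) next
      d <- min(abs(ps$peaks - f))
      if (d < best_d - 1e-12) { best_d <- d; best_p <- ps$protein }
    }
    if (is.finite(best_d) && best_d <= tol)
      data.frame(wavenumber = f, relieff_rank = i,
                 matched_protein = best_p, peak_distance = best_d)
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(wavenumber = numeric(), relieff_rank = integer(),
                      matched_protein = character(), peak_distance = numeric())
  structure(out, class = c("biomarker_panel", "data.frame"))
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat(sprintf("<biomarker_panel> %d member(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
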