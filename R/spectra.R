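#' Single spectrum
#'
#' One sample's absorbance trace on a [wavenumber_grid].
#'
#' @param grid A [wavenumber_grid].
#' @param absorbance Numeric vector of absorbance (AU), same length as `grid`.
#' @param sample_id Character scalar.
#' @param meta Named list of string metadata.
#' @return Object of class `spectrum`.
#' @export
new_spectrum <- function(grid, absorbance, sample_id = "s1", meta = list()) {
  stopifnot(inherits(grid, "wavenumber_grid"))
  absorbance <- as.numeric(absorbance)
  if (length(absorbance) != length(grid$values))
    stop("absorbance length must equal grid length")
  if (any(!is.finite(absorbance))) stop("absorbance must be finite")
  structure(list(grid = grid, absorbance = absorbance,
                 sample_id = as.character(sample_id), meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> '%s', %d points, %.6g -> %.6g cm^-1\n",
              x$sample_id, length(x$absorbance), x$grid$values[1L],
              x$grid$values[length(x$absorbance)]))
  invisible(x)
}

#' Diagnosis codes understood by the package
#' @export
DIAGNOSIS_CODES <- c("AD", "HC", "MCI", "DLB", "FTD", "PSP")

#' Analyte column names (plasma concentrations, pg/ml)
#' @export
ANALYTE_NAMES <- c("ptau217", "abeta42", "gfap")

#' Aligned set of spectra with labels and optional analytes/MMSE
#'
#' The central cohort container: a samples-by-wavenumbers absorbance matrix on
#' a shared grid, a diagnosis label per row, and optional per-sample plasma
#' analyte concentrations (p-tau217, Abeta42, GFAP; pg/ml) and MMSE scores.
#'
#' @param grid A [wavenumber_grid].
#' @param matrix Numeric samples x wavenumbers matrix (AU).
#' @param labels Character vector of diagnosis codes (one of
#'   `r paste(DIAGNOSIS_CODES, collapse = ", ")`), one per row.
#' @param analytes Optional data.frame with columns among `ptau217`, `abeta42`,
#'   `gfap` (pg/ml, all positive), one row per sample.
#' @param mmse Optional integer vector in \[0, 30\], one per sample (NA allowed).
#' @param meta Named list of metadata.
#' @return Object of class `spectra_set`.
#' @export
spectra_set <- function(grid, matrix, labels, analytes = NULL, mmse = NULL,
                        meta = list()) {
  stopifnot(inherits(grid, "wavenumber_grid"))
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (ncol(matrix) != length(grid$values))
    stop("matrix column count must equal grid length")
  labels <- as.character(labels)
  if (nrow(matrix) != length(labels))
    stop("row count must equal label count")
  bad <- setdiff(unique(labels), DIAGNOSIS_CODES)
  if (length(bad)) stop("unknown label code(s): ", paste(bad, collapse = ", "))
  if (!is.null(analytes)) {
    analytes <- as.data.frame(analytes)
    if (nrow(analytes) != nrow(matrix))
      stop("analyte row count must equal sample count")
    for (a in intersect(names(analytes), ANALYTE_NAMES)) {
      v <- analytes[[a]]
      if (any(!is.na(v) & v <= 0)) stop("analyte '", a, "' must be positive")
    }
  }
  if (!is.null(mmse)) {
    if (length(mmse) != nrow(matrix)) stop("mmse length must equal sample count")
    if (any(!is.na(mmse) & (mmse < 0 | mmse > 30)))
      stop("mmse must lie in [0, 30]")
    mmse <- as.integer(round(mmse))
  }
  colnames(matrix) <- format_wn(grid$values)
  structure(list(grid = grid, matrix = matrix, labels = labels,
                 analytes = analytes, mmse = mmse, meta = meta),
            class = "spectra_set")
}

format_wn <- function(wn) formatC(wn, format = "g", digits = 12)

#' @export
print.spectra_set <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<spectra_set> %d samples x %d wavenumbers (%.6g -> %.6g cm^-1)\n",
              nrow(x$matrix), ncol(x$matrix), x$grid$values[1L],
              x$grid$values[ncol(x$matrix)]))
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(x$analytes))
    cat("  analytes:", paste(names(x$analytes), collapse = ", "), "\n")
  if (!is.null(x$mmse)) cat("  mmse: present\n")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$matrix)

#' Subset a spectra set by sample index
#'
#' @param set A [spectra_set].
#' @param idx Integer vector of row indices.
#' @return A [spectra_set] with the selected rows (labels, analytes and MMSE
#'   subset in step).
#' @export
subset_samples <- function(set, idx) {
  stopifnot(inherits(set, "spectra_set"))
  spectra_set(set$grid, set$matrix[idx, , drop = FALSE], set$labels[idx],
              analytes = if (!is.null(set$analytes)) set$analytes[idx, , drop = FALSE],
              mmse = if (!is.null(set$mmse)) set$mmse[idx],
              meta = set$meta)
}

#' Restrict a spectra set to a wavenumber range
#'
#' Drops all columns outside `[lo, hi]` cm^-1, e.g. to the fingerprint region
#' 950-1800 cm^-1 where the diagnostic analysis concentrates.
#'
#' @param set A [spectra_set].
#' @param lo,hi Range bounds in cm^-1, `lo < hi`.
#' @return A [spectra_set] on the truncated grid.
#' @export
truncate_range <- function(set, lo, hi) {
  stopifnot(inherits(set, "spectra_set"))
  if (!(lo < hi)) stop("lo must be < hi")
  keep <- set$grid$values >= lo & set$grid$values <= hi
  if (sum(keep) < 2L) stop("truncation range [", lo, ", ", hi,
                           "] leaves fewer than 2 grid points")
  spectra_set(wavenumber_grid(set$grid$values[keep]),
              set$matrix[, keep, drop = FALSE], set$labels,
              analytes = set$analytes, mmse = set$mmse, meta = set$meta)
}

#' Resample a spectrum onto a target grid
#'
#' Linear interpolation of the absorbance trace onto `grid`. Used to bring
#' instrument-native spacing (about 1.93 cm^-1 for a 4 cm^-1-resolution
#' interferogram after zero filling) onto the canonical 1 cm^-1 grid.
#'
#' @param s A [spectrum].
#' @param grid Target [wavenumber_grid]; must lie within the source range
#'   (no extrapolation).
#' @return A [spectrum] on `grid`.
#' @export
resample_to_grid <- function(s, grid) {
  stopifnot(inherits(s, "spectrum"), inherits(grid, "wavenumber_grid"))
  src <- s$grid$values
  if (max(grid$values) > max(src) + 1e-9 || min(grid$values) < min(src) - 1e-9)
    stop("target grid requires extrapolation beyond the source range")
  # approx needs ascending x
  y <- stats::approx(rev(src), rev(s$absorbance), xout = grid$values,
                     method = "linear", rule = 1)$y
  new_spectrum(grid, y, s$sample_id, s$meta)
}
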