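#' Savitzky-Golay filter parameters
#'
#' The defaults reproduce the classical second-derivative design for FTIR
#' plasma spectra: a 9-point window with a second-order polynomial
#' (`window = 9`, `polyorder = 2`, `deriv = 2`).
#'
#' @param window Odd window length in points, `window >= polyorder + 1`.
#' @param polyorder Fitted polynomial order.
#' @param deriv Derivative order (0, 1 or 2), `deriv <= polyorder`.
#' @return Object of class `sg_params`.
#' @export
sg_params <- function(window = 9L, polyorder = 2L, deriv = 2L) {
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  deriv <- as.integer(deriv)
  if (window %% 2L != 1L || window < polyorder + 1L)
    stop("window must be odd and >= polyorder + 1")
  if (deriv < 0L || deriv > 2L || deriv > polyorder)
    stop("deriv must be in 0..2 and <= polyorder")
  structure(list(window = window, polyorder = polyorder, deriv = deriv),
            class = "sg_params")
}

#' Savitzky-Golay convolution weights
#'
#' Closed-form least-squares weights: applying them to a window of samples
#' equals evaluating the `deriv`-th derivative, at the window centre, of the
#' `polyorder` polynomial fit to the window, divided by `spacing^deriv` so
#' derivative units follow the wavenumber axis (AU/cm^-1 per order).
#'
#' @param p An [sg_params].
#' @param spacing Grid step in cm^-1 (sign carries axis direction; `deriv = 1`
#'   weights flip sign for a descending axis, even orders are unaffected).
#' @return Numeric weight vector of length `window`, ordered with the stored
#'   data (index order).
#' @export
sg_coefficients <- function(p, spacing = 1) {
  stopifnot(inherits(p, "sg_params"))
  if (spacing == 0) stop("spacing must be nonzero")
  h <- (p$window - 1L) %/% 2L
  A <- outer(seq(-h, h), 0:p$polyorder, `^`)
  # row deriv+1 of (A'A)^-1 A' gives the centre-point polynomial coefficient
  C <- solve(crossprod(A), t(A))
  w <- C[p$deriv + 1L, ] * factorial(p$deriv) / spacing^p$deriv
  # enforce the exact DC response (1 for smoothing, 0 for derivatives), which
  # solve() only delivers to within rounding
  dc <- if (p$deriv == 0L) 1 else 0
  w + (dc - sum(w)) / p$window
}

# convolve each row of mat with weights w, dropping (length(w)-1)/2 points at
# each edge (truncation; no extrapolated edge values). Each window is centred
# on its middle sample before convolving — identical algebra (the centre value
# re-enters scaled by sum(w)) but avoids catastrophic cancellation when the
# absolute signal level dwarfs its within-window variation.
sg_filter_rows <- function(mat, w) {
  n <- ncol(mat); win <- length(w); h <- (win - 1L) %/% 2L
  if (win > n) stop("window exceeds grid length")
  ctr <- mat[, (h + 1L):(n - h), drop = FALSE]
  # DC response of a least-squares polynomial filter is exactly 1 (smoothing)
  # or 0 (derivatives); snap the float residue so the centred form is exact
  sw <- sum(w)
  sw <- if (abs(sw) < 1e-6) 0 else if (abs(sw - 1) < 1e-6) 1 else sw
  out <- sw * ctr
  for (i in seq_len(win))
    out <- out + w[i] * (mat[, i:(n - win + i), drop = FALSE] - ctr)
  out
}

#' Savitzky-Golay second-derivative spectra
#'
#' Applies the SG derivative filter row-wise. Edge handling is truncation: the
#' `(window-1)/2` half-window points at each end are dropped from both the
#' grid and the matrix, so no fabricated edge values can enter feature
#' selection.
#'
#' @param set A [spectra_set].
#' @param p An [sg_params]; default is the 9-point / order-2 / 2nd-derivative
#'   design.
#' @return A [spectra_set] of derivative intensities (AU/cm^-2 for
#'   `deriv = 2`) on the interior grid.
#' @export
second_derivative <- function(set, p = sg_params()) {
  stopifnot(inherits(set, "spectra_set"))
  n <- ncol(set$matrix)
  if (p$window > n) stop("window exceeds grid length")
  # stored order is descending in wavenumber: step along the index axis is
  # -spacing in cm^-1
  w <- sg_coefficients(p, spacing = -set$grid$spacing)
  h <- (p$window - 1L) %/% 2L
  out <- sg_filter_rows(set$matrix, w)
  grid <- wavenumber_grid(set$grid$values[(h + 1L):(n - h)])
  spectra_set(grid, out, set$labels, analytes = set$analytes, mmse = set$mmse,
              meta = set$meta)
}

#' Euclidean vector normalization over a wavenumber region
#'
#' Scales each row so that its L2 norm over `region` equals 1, removing
#' per-sample multiplicative effects (deposited volume, contact pressure)
#' before derivative filtering.
#'
#' @param set A [spectra_set].
#' @param region `(lo, hi)` in cm^-1; defaults to the fingerprint region
#'   950-1800 cm^-1.
#' @return The normalized [spectra_set] (all columns scaled, norm computed on
#'   the region).
#' @export
vector_normalize <- function(set, region = c(950, 1800)) {
  stopifnot(inherits(set, "spectra_set"))
  keep <- set$grid$values >= region[1L] & set$grid$values <= region[2L]
  if (!any(keep)) stop("normalization region does not overlap the grid")
  nrm <- sqrt(rowSums(set$matrix[, keep, drop = FALSE]^2))
  if (any(nrm == 0)) stop("degenerate input: zero-norm row(s) ",
                          paste(which(nrm == 0), collapse = ", "))
  spectra_set(set$grid, set$matrix / nrm, set$labels, analytes = set$analytes,
              mmse = set$mmse, meta = set$meta)
}

#' Standard preprocessing for diagnostic modelling
#'
#' Truncate to the fingerprint region, vector-normalize, then take the SG
#' second derivative. This is the representation used for partitioning,
#' Relief-F ranking and classification; raw absorbance is kept for box-plot
#' style group comparisons and analyte associations.
#'
#' @param set A [spectra_set] on any uniform grid.
#' @param range Analysis range in cm^-1.
#' @param norm_region Region for [vector_normalize()].
#' @param p [sg_params] for the derivative.
#' @return A derivative-domain [spectra_set].
#' @export
preprocess_pipeline <- function(set, range = c(950, 1800),
                                norm_region = c(950, 1800), p = sg_params()) {
  set <- truncate_range(set, range[1L], range[2L])
  set <- vector_normalize(set, norm_region)
  second_derivative(set, p)
}
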