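#' Wavenumber grid
#'
#' A uniformly spaced, strictly descending axis of mid-infrared wavenumbers
#' (cm^-1). All spectra handled by the package live on such a grid; the
#' descending orientation (4000 -> 950) matches conventional FTIR plotting.
#'
#' @param values Numeric vector of wavenumbers in cm^-1. Accepted ascending or
#'   descending; stored descending.
#' @return An object of class `wavenumber_grid` with fields `values` (descending
#'   wavenumbers) and `spacing` (cm^-1 per step, positive).
#' @examples
#' g <- wavenumber_grid(seq(4000, 950, by = -1))
#' length(g$values)
#' @export
wavenumber_grid <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("a wavenumber grid needs at least 2 points")
  if (any(!is.finite(values))) stop("wavenumbers must be finite")
  d <- diff(values)
  if (all(d > 0)) values <- rev(values) else if (!all(d < 0))
    stop("wavenumber axis must be strictly monotone")
  d <- diff(values)
  spacing <- -d[1L]
  if (max(abs(d + spacing)) > 1e-9)
    stop("wavenumber axis must be uniformly spaced (within 1e-9 cm^-1)")
  if (min(values) < 900 || max(values) > 4000)
    stop("wavenumber axis must lie within [900, 4000] cm^-1")
  structure(list(values = values, spacing = spacing), class = "wavenumber_grid")
}

#' Canonical analysis grid
#'
#' The package's internal working grid: descending 1 cm^-1 steps over
#' 4000-950 cm^-1 (3051 points). Instrument files on coarser native spacing are
#' resampled onto (a range of) this grid on load, so that marker wavenumbers
#' are integer cm^-1 positions.
#'
#' @param lo,hi Range bounds in cm^-1.
#' @return A [wavenumber_grid].
#' @export
canonical_grid <- function(lo = 950, hi = 4000) {
  wavenumber_grid(seq(hi, lo, by = -1))
}

#' @export
print.wavenumber_grid <- function(x, ...) {
  cat(sprintf("<wavenumber_grid> %d points, %.6g -> %.6g cm^-1, step %.6g\n",
              length(x$values), x$values[1L], x$values[length(x$values)],
              x$spacing))
  invisible(x)
}

#' @export
length.wavenumber_grid <- function(x) length(x$values)

grid_equal <- function(a, b, tol = 1e-9) {
  length(a$values) == length(b$values) &&
    max(abs(a$values - b$values)) <= tol
}

# nearest grid index for each target wavenumber; error if off by more than half
# a step (strict = TRUE)
grid_index <- function(grid, wn, strict = TRUE) {
  idx <- vapply(wn, function(w) which.min(abs(grid$values - w)), integer(1L))
  if (strict) {
    off <- abs(grid$values[idx] - wn)
    if (any(off > grid$spacing / 2 + 1e-9))
      stop("wavenumber(s) not on grid: ", paste(wn[off > grid$spacing / 2 + 1e-9],
                                                collapse = ", "))
  }
  idx
}
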