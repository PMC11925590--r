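# Post-hoc association statistics between panel absorbances and plasma
# analytes / MMSE, plus baseline-table group comparisons.

assoc_result <- function(x, y, x_name, y_name) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: zero variance")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(x_name = x_name, y_name = y_name,
                 r = unname(stats::cor(x, y)),
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 p = unname(sm$coefficients[2L, 4L]),
                 n = length(x)),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association> %s ~ %s: r = %.3f, slope = %.4g, p = %.3g, n = %d\n",
              x$y_name, x$x_name, x$r, x$slope, x$p, x$n))
  invisible(x)
}

#' Log-linear association between a panel absorbance and an analyte
#'
#' Ordinary least squares of the natural-log analyte concentration on the
#' absorbance at one panel wavenumber (plasma levels are log-transformed to
#' approximate normality). `r` is the Pearson correlation of the pair; `p` is
#' the two-sided t-test on the slope. The log base does not affect `r` or `p`.
#'
#' @param absorbance Numeric absorbance vector (AU) at one wavenumber.
#' @param conc Paired analyte concentrations (pg/ml, > 0).
#' @param marker,analyte Names used in the report.
#' @return An `association_result` (fields `r`, `slope`, `intercept`, `p`, `n`).
#' @export
loglinear_association <- function(absorbance, conc, marker = "absorbance",
                                  analyte = "analyte") {
  if (any(conc <= 0, na.rm = TRUE)) stop("concentrations must be positive")
  assoc_result(absorbance, log(conc), marker, paste0("log(", analyte, ")"))
}

#' Association between a panel absorbance and MMSE score
#'
#' OLS of the (untransformed) MMSE score on absorbance.
#'
#' @param absorbance Numeric absorbance vector (AU).
#' @param mmse Paired MMSE scores (0-30).
#' @param marker Name used in the report.
#' @return An `association_result`.
#' @export
mmse_association <- function(absorbance, mmse, marker = "absorbance") {
  assoc_result(absorbance, as.numeric(mmse), marker, "mmse")
}

#' Two-group comparison for baseline tables
#'
#' Numeric input: two-sided Mann-Whitney U test (normal approximation with tie
#' correction, no continuity correction). Categorical input: Pearson
#' chi-square on the contingency table, uncorrected.
#'
#' @param values Numeric vector, or factor/character for categorical data.
#' @param groups Binary group labels, same length.
#' @return List `statistic` (U for numeric, X-squared for categorical), `p`,
#'   `type`, and `all_tied` (numeric input with every value equal: `p = 1`
#'   with a warning).
#' @export
group_compare <- function(values, groups) {
  g <- as.factor(groups)
  if (nlevels(g) != 2L) stop("groups must have exactly two levels")
  if (any(table(g) == 0L)) stop("both groups must be nonempty")
  if (is.numeric(values)) {
    if (length(unique(values)) == 1L) {
      warning("all values tied; p set to 1")
      return(list(statistic = NA_real_, p = 1, type = "mann-whitney",
                  all_tied = TRUE))
    }
    ht <- suppressWarnings(stats::wilcox.test(values ~ g, exact = FALSE,
                                              correct = FALSE))
    list(statistic = unname(ht$statistic), p = ht$p.value,
         type = "mann-whitney", all_tied = FALSE)
  } else {
    tab <- table(values, g)
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(statistic = unname(ht$statistic), p = ht$p.value,
         type = "chi-square", all_tied = FALSE)
  }
}

#' Panel-analyte association table
#'
#' Runs [loglinear_association()] for each (panel wavenumber, analyte) pair
#' of a cohort, on raw absorbance, restricted to one diagnosis group
#' (associations are reported within patients).
#'
#' @param set A raw-absorbance [spectra_set] with analytes.
#' @param panel Numeric wavenumbers (or `biomarker_panel`).
#' @param group Diagnosis code to restrict to (default `"AD"`).
#' @param pairs Optional named list analyte -> wavenumbers, to restrict which
#'   pairs are tested (default: all panel wavenumbers against all analytes).
#' @return Data frame `marker`, `analyte`, `r`, `slope`, `p`, `n`; the number
#'   of tests run is attached as attribute `n_tests` (no multiplicity
#'   correction is applied).
#' @export
association_table <- function(set, panel, group = "AD", pairs = NULL) {
  stopifnot(inherits(set, "spectra_set"))
  if (inherits(panel, "biomarker_panel")) panel <- panel$wavenumber
  if (is.null(set$analytes)) stop("set carries no analytes")
  rows <- which(set$labels == group)
  if (length(rows) < 3L) stop("fewer than 3 samples in group ", group)
  out <- list()
  for (a in names(set$analytes)) {
    wns <- if (is.null(pairs)) panel else pairs[[a]]
    for (wn in wns) {
      idx <- grid_index(set$grid, wn)
      res <- loglinear_association(set$matrix[rows, idx],
                                   set$analytes[[a]][rows],
                                   marker = format_wn(wn), analyte = a)
      out[[length(out) + 1L]] <- data.frame(
        marker = wn, analyte = a, r = res$r, slope = res$slope, p = res$p,
        n = res$n)
    }
  }
  tab <- do.call(rbind, out)
  attr(tab, "n_tests") <- nrow(tab)
  tab
}
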