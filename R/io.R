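# CSV dialect: comma-separated, '.' decimal, UTF-8. First header field per
# spectral column is the wavenumber; a "label" column is required; optional
# columns: sample_id, ptau217, abeta42, gfap (pg/ml), mmse.

#' Read a cohort spectra CSV
#'
#' Expects a header row whose spectral columns are wavenumbers (either
#' orientation; normalized to descending on load) plus a required `label`
#' column and optional `sample_id`, analyte (`ptau217`, `abeta42`, `gfap`) and
#' `mmse` columns. One row per sample.
#'
#' @param path File path.
#' @return A [spectra_set]. If the file's wavenumber axis ascended, it is
#'   reversed (matrix columns with it) and `meta$reversed_on_load` is set.
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  nm <- names(df)
  wn_col <- suppressWarnings(!is.na(as.numeric(nm)))
  if (!any(wn_col)) stop("format error: no numeric wavenumber columns in header")
  if (!"label" %in% nm) stop("format error: required 'label' column missing")
  wn <- as.numeric(nm[wn_col])
  mat <- as.matrix(df[, wn_col, drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop("format error: missing/non-numeric absorbance values")
  meta <- list()
  if (length(wn) >= 2 && wn[1L] < wn[2L]) {
    wn <- rev(wn)
    mat <- mat[, rev(seq_len(ncol(mat))), drop = FALSE]
    meta$reversed_on_load <- TRUE
  }
  grid <- tryCatch(wavenumber_grid(wn),
                   error = function(e) stop("format error: ", conditionMessage(e)))
  analytes <- NULL
  an <- intersect(ANALYTE_NAMES, nm)
  if (length(an)) analytes <- df[, an, drop = FALSE]
  mmse <- if ("mmse" %in% nm) df$mmse
  set <- spectra_set(grid, mat, df$label, analytes = analytes, mmse = mmse,
                     meta = meta)
  if ("sample_id" %in% nm) set$meta$sample_id <- as.character(df$sample_id)
  set
}

#' Write a cohort spectra CSV
#'
#' Inverse of [read_spectra_csv()]; lossless round trip to better than
#' 1e-12 AU (values written with 17 significant digits).
#'
#' @param set A [spectra_set].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(set, path) {
  stopifnot(inherits(set, "spectra_set"))
  df <- as.data.frame(set$matrix, check.names = FALSE)
  names(df) <- formatC(set$grid$values, format = "g", digits = 17)
  df <- cbind(df, label = set$labels)
  if (!is.null(set$analytes)) df <- cbind(df, set$analytes)
  if (!is.null(set$mmse)) df <- cbind(df, mmse = set$mmse)
  if (!is.null(set$meta$sample_id)) df <- cbind(df, sample_id = set$meta$sample_id)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a JCAMP-DX spectrum (subset)
#'
#' Supports the labelled-data-record subset common for FTIR exchange:
#' `##XYDATA=(X++(Y..Y))` with `XFACTOR`/`YFACTOR`/`DELTAX`, or `##XYPOINTS=(XY..XY)`.
#' `##XUNITS` must be `1/CM`. AFFN numeric form only (no SQZ/DIF compression).
#'
#' @param path File path.
#' @return A [spectrum] in descending-wavenumber orientation; no resampling is
#'   performed (see [resample_to_grid()]).
#' @export
read_jcampdx_subset <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  get_ldr <- function(label) {
    i <- grep(paste0("^##", label, "\\s*="), lines, ignore.case = TRUE)
    if (!length(i)) return(NULL)
    sub(paste0("^##", label, "\\s*="), "", lines[i[1L]], ignore.case = TRUE)
  }
  xunits <- get_ldr("XUNITS")
  if (!is.null(xunits) && toupper(trimws(xunits)) != "1/CM")
    stop("unsupported-unit error: XUNITS must be 1/CM, got ", trimws(xunits))
  xf <- get_ldr("XFACTOR"); xf <- if (is.null(xf)) 1 else as.numeric(xf)
  yf <- get_ldr("YFACTOR"); yf <- if (is.null(yf)) 1 else as.numeric(yf)
  title <- get_ldr("TITLE"); if (is.null(title)) title <- basename(path)

  i_xy <- grep("^##XYDATA\\s*=", lines, ignore.case = TRUE)
  i_xyp <- grep("^##XYPOINTS\\s*=", lines, ignore.case = TRUE)
  block_after <- function(i) {
    j <- i + 1L
    out <- character()
    while (j <= length(lines) && !grepl("^##", lines[j])) {
      out <- c(out, lines[j]); j <- j + 1L
    }
    out
  }
  if (length(i_xy)) {
    body <- block_after(i_xy[1L])
    xs <- ys <- numeric()
    for (ln in body) {
      tok <- as.numeric(strsplit(trimws(ln), "[,;[:space:]]+")[[1L]])
      tok <- tok[!is.na(tok)]
      if (length(tok) < 2L) next
      x0 <- tok[1L] * xf
      yv <- tok[-1L] * yf
      dx <- get_ldr("DELTAX")
      dx <- if (is.null(dx)) {
        # infer from FIRSTX/LASTX/NPOINTS if present
        fx <- as.numeric(get_ldr("FIRSTX")); lx <- as.numeric(get_ldr("LASTX"))
        np <- as.numeric(get_ldr("NPOINTS"))
        if (length(fx) && length(lx) && length(np) && np > 1)
          (lx - fx) / (np - 1) else stop("format error: DELTAX undeterminable")
      } else as.numeric(dx)
      xs <- c(xs, x0 + dx * (seq_along(yv) - 1L))
      ys <- c(ys, yv)
    }
    if (!length(xs)) stop("format error: empty XYDATA block")
  } else if (length(i_xyp)) {
    body <- block_after(i_xyp[1L])
    tok <- as.numeric(strsplit(paste(trimws(body), collapse = " "),
                               "[,;[:space:]]+")[[1L]])
    tok <- tok[!is.na(tok)]
    if (length(tok) < 4L || length(tok) %% 2L != 0L)
      stop("format error: malformed XYPOINTS block")
    xs <- tok[seq(1L, length(tok), by = 2L)] * xf
    ys <- tok[seq(2L, length(tok), by = 2L)] * yf
  } else {
    stop("format error: no ##XYDATA or ##XYPOINTS record found")
  }
  o <- order(xs, decreasing = TRUE)
  new_spectrum(wavenumber_grid(xs[o]), ys[o], sample_id = trimws(title),
               meta = list(source = "jcampdx"))
}
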