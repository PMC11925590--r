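# Containers, CSV / JCAMP-DX I/O, resampling and range truncation.

test_that("wavenumber grids validate monotonicity, spacing and range", {
  g <- wavenumber_grid(seq(4000, 950, by = -1))
  expect_equal(length(g$values), 3051L)
  expect_equal(g$spacing, 1)
  # ascending input is normalized to descending
  g2 <- wavenumber_grid(seq(950, 4000, by = 1))
  expect_equal(g2$values, g$values)
  expect_error(wavenumber_grid(c(4000, 3999, 3999.5)), "monotone")
  expect_error(wavenumber_grid(c(4000, 3999, 3997)), "uniform")
  expect_error(wavenumber_grid(seq(5000, 4500, by = -1)), "900, 4000")
})

test_that("canonical grid has 3051 one-wavenumber points over 950-4000", {
  g <- canonical_grid()
  expect_equal(length(g$values), (4000 - 950) / 1 + 1)
  expect_equal(g$values[1], 4000)
  expect_equal(g$values[3051], 950)
})

test_that("spectra_set enforces label codes, analyte positivity and MMSE range", {
  m <- matrix(runif(20), 2)
  expect_error(make_set(m, c("AD", "XX")), "unknown label")
  expect_error(make_set(m, c("AD", "HC"),
                        analytes = data.frame(ptau217 = c(1, -2))), "positive")
  expect_error(make_set(m, c("AD", "HC"), mmse = c(10, 35)), "0, 30")
  s <- make_set(m, c("AD", "HC"), analytes = data.frame(gfap = c(20, 30)),
                mmse = c(15, 29))
  expect_equal(dim(s), c(2L, 10L))
})

test_that("spectra CSV round trip is lossless and preserves metadata", {
  set.seed(42)
  n <- 5L; p <- 30L
  set <- make_set(matrix(rnorm(n * p), n), c("AD", "AD", "HC", "HC", "MCI"),
                  analytes = data.frame(ptau217 = runif(n, 3, 8),
                                        abeta42 = runif(n, 40, 90),
                                        gfap = runif(n, 10, 60)),
                  mmse = c(12L, 20L, 29L, 30L, 25L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(set, path)
  rt <- read_spectra_csv(path)
  expect_lt(max(abs(rt$matrix - set$matrix)), 1e-12)
  expect_identical(rt$labels, set$labels)
  expect_lt(max(abs(as.matrix(rt$analytes) - as.matrix(set$analytes))), 1e-12)
  expect_identical(rt$mmse, set$mmse)
  expect_equal(rt$grid$values, set$grid$values)
})

test_that("an ascending CSV header is reoriented on load and flagged", {
  m <- matrix(seq_len(12), 2, byrow = TRUE)
  df <- as.data.frame(m)
  names(df) <- as.character(1300:1305)        # ascending header
  df$label <- c("AD", "HC")
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  set <- read_spectra_csv(path)
  expect_true(isTRUE(set$meta$reversed_on_load))
  expect_equal(set$grid$values, 1305:1300)
  # row values must follow the reversed columns
  expect_equal(unname(set$matrix[1, ]), rev(m[1, ]))
  # write/read round trip is stable (orientation normalization is involutive)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(set, p2)
  rt <- read_spectra_csv(p2)
  expect_equal(rt$matrix, set$matrix, ignore_attr = TRUE)
})

test_that("empty and single-sample sets write header-only / 2-line files", {
  g <- wavenumber_grid(1310:1300)
  s0 <- spectra_set(g, matrix(numeric(), 0, 11), character())
  p0 <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(s0, p0)
  expect_equal(length(readLines(p0)), 1L)
  s1 <- spectra_set(g, matrix(1:11, 1), "AD")
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(s1, p1)
  expect_equal(length(readLines(p1)), 2L)
})

test_that("CSV reader rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,label", "1,2,AD"), path)
  expect_error(read_spectra_csv(path), "wavenumber")
  writeLines(c("1302,1301,1300", "1,2,3"), path)
  expect_error(read_spectra_csv(path), "label")
  writeLines(c("1303,1301,1300,label", "1,2,3,AD"), path)
  expect_error(read_spectra_csv(path), "uniform")
})

test_that("JCAMP-DX XYDATA records parse with X/Y factors and orientation", {
  path <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c(
    "##TITLE=fixture", "##JCAMP-DX=4.24", "##XUNITS=1/CM", "##YUNITS=AU",
    "##XFACTOR=1", "##YFACTOR=0.5", "##FIRSTX=1300", "##LASTX=1304",
    "##NPOINTS=5", "##DELTAX=1",
    "##XYDATA=(X++(Y..Y))", "1300 2 4 6 8 10", "##END="), path)
  s <- read_jcampdx_subset(path)
  expect_equal(length(s$absorbance), 5L)
  # descending orientation enforced; YFACTOR applied
  expect_equal(s$grid$values, 1304:1300)
  expect_equal(s$absorbance, c(5, 4, 3, 2, 1))
})

test_that("JCAMP-DX XYPOINTS records parse and unit errors are raised", {
  path <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=p", "##XUNITS=1/CM",
               "##XYPOINTS=(XY..XY)",
               "1300,0.1; 1301,0.2; 1302,0.3; 1303,0.25; 1304,0.15",
               "##END="), path)
  s <- read_jcampdx_subset(path)
  expect_equal(s$grid$values, 1304:1300)
  expect_equal(s$absorbance[5], 0.1)

  writeLines(c("##TITLE=bad", "##XUNITS=MICROMETERS",
               "##XYPOINTS=(XY..XY)", "1,2", "##END="), path)
  expect_error(read_jcampdx_subset(path), "1/CM")
  writeLines(c("##TITLE=bad2", "##XUNITS=1/CM", "##END="), path)
  expect_error(read_jcampdx_subset(path), "format error")
})

test_that("resampling interpolates linearly and refuses extrapolation", {
  g_src <- wavenumber_grid(seq(1400, 1300, by = -2))
  s <- new_spectrum(g_src, 2 * g_src$values)     # A(v) = 2v, linear
  g_tgt <- wavenumber_grid(seq(1399, 1301, by = -2))
  r <- resample_to_grid(s, g_tgt)
  expect_equal(r$absorbance, 2 * g_tgt$values, tolerance = 1e-12)
  # identity on the same grid
  expect_equal(resample_to_grid(s, g_src)$absorbance, s$absorbance)
  expect_error(resample_to_grid(s, wavenumber_grid(seq(1500, 1400, by = -2))),
               "extrapolation")
})

test_that("downsampling a quadratic matches per-point interpolation oracle", {
  g_src <- wavenumber_grid(seq(1400, 1300, by = -0.5))
  f <- function(v) (v - 1350)^2 / 100
  s <- new_spectrum(g_src, f(g_src$values))
  g_tgt <- wavenumber_grid(seq(1399, 1301, by = -1))
  r <- resample_to_grid(s, g_tgt)
  # oracle: direct two-point interpolation at each target
  oracle <- sapply(g_tgt$values, function(v) {
    lo <- max(g_src$values[g_src$values <= v]); hi <- lo + 0.5
    w <- (v - lo) / 0.5
    (1 - w) * f(lo) + w * f(hi)
  })
  expect_equal(r$absorbance, oracle, tolerance = 1e-12)
})

test_that("truncate_range keeps expected columns and is idempotent", {
  g <- canonical_grid()
  set <- spectra_set(g, matrix(rnorm(2 * 3051), 2), c("AD", "HC"))
  expect_equal(dim(truncate_range(set, 950, 4000)), dim(set))
  fp <- truncate_range(set, 950, 1800)
  expect_equal(ncol(fp$matrix), 1800 - 950 + 1)
  expect_equal(truncate_range(fp, 950, 1800)$matrix, fp$matrix)
  expect_error(truncate_range(set, 5000, 6000), "2 grid points|overlap")
  expect_error(truncate_range(set, 1800, 950))
})
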