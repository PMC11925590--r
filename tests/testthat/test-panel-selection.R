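# Relief-F ranking, peak detection, feature-peak matching, iterative search.

test_that("relieff matches the naive double-loop oracle to 1e-12", {
  set.seed(41)
  for (rep in 1:6) {
    n <- sample(10:40, 1); f <- sample(2:10, 1); k <- sample(1:3, 1)
    y <- rep(c(0, 1), length.out = n)
    X <- matrix(rnorm(n * f), n)
    colnames(X) <- as.character(seq(1300, by = 1, length.out = f))
    r <- relieff(X, y, k_neighbors = k)
    w_oracle <- relieff_oracle(X, y, k)
    expect_equal(r$weight, sort(w_oracle, decreasing = TRUE),
                 tolerance = 1e-12)
    expect_equal(r$wavenumber,
                 as.numeric(colnames(X))[order(w_oracle, decreasing = TRUE)],
                 info = sprintf("rep %d", rep))
  }
})

test_that("constant features score zero; a label-copy feature ranks first", {
  set.seed(43)
  y <- rep(c(0, 1), 15)
  X <- cbind(const = rep(2, 30), label = y, noise = rnorm(30))
  colnames(X) <- c("1300", "1301", "1302")
  r <- relieff(X, y, k_neighbors = 1)
  expect_equal(r$weight[r$wavenumber == 1300], 0)
  expect_equal(r$wavenumber[1], 1301)
  expect_gt(r$weight[1], 0)
})

test_that("adding a constant feature leaves other weights unchanged and a
           duplicated feature scores exactly like its original", {
  set.seed(47)
  y <- rep(c(0, 1), 10)
  X <- matrix(rnorm(20 * 3), 20)
  colnames(X) <- c("1300", "1301", "1302")
  r1 <- relieff(X, y, 2)
  # constant features contribute zero to every distance and diff
  X2 <- cbind(X, rep(4, 20)); colnames(X2) <- c(colnames(X), "1303")
  r2 <- relieff(X2, y, 2)
  for (wn in c(1300, 1301, 1302))
    expect_equal(r2$weight[r2$wavenumber == wn],
                 r1$weight[r1$wavenumber == wn], tolerance = 1e-12)
  expect_equal(r2$weight[r2$wavenumber == 1303], 0)
  # an exact copy receives exactly the weight of its original
  X3 <- cbind(X, X[, 2]); colnames(X3) <- c(colnames(X), "1303")
  r3 <- relieff(X3, y, 2)
  expect_equal(r3$weight[r3$wavenumber == 1303],
               r3$weight[r3$wavenumber == 1301], tolerance = 1e-12)
})

test_that("relieff validates its inputs", {
  X <- matrix(rnorm(20), 10); colnames(X) <- c("1300", "1301")
  expect_error(relieff(X, rep(1, 10), 2), "two classes")
  expect_error(relieff(X, rep(c(0, 1), 5), 5), "k_neighbors")
})

test_that("detect_peaks finds prominent maxima and honours separation", {
  g <- wavenumber_grid(seq(1700, 1300, by = -1))
  two <- gaussian_band(g, 1400, 1, 30) + gaussian_band(g, 1600, 0.5, 30)
  s <- new_spectrum(g, two)
  pk <- detect_peaks(s, prominence_frac = 0.05)
  expect_equal(pk$peaks, c(1400, 1600))
  # monotone ramp: no local maxima
  ramp <- new_spectrum(g, seq(0, 1, length.out = 401))
  expect_equal(length(detect_peaks(ramp)$peaks), 0L)
  # two gaussians 3 cm-1 apart with min_separation 10 -> only the taller
  close2 <- gaussian_band(g, 1500, 1, 8) + gaussian_band(g, 1503, 0.6, 8)
  # oracle: exhaustive scan of the generated vector for its global maximum
  oracle_top <- g$values[which.max(close2)]
  pks <- detect_peaks(new_spectrum(g, close2), 0.01, min_separation = 10)
  expect_equal(length(pks$peaks), 1L)
  expect_equal(pks$peaks, oracle_top)
})

test_that("low-prominence shoulders are suppressed", {
  g <- wavenumber_grid(seq(1700, 1300, by = -1))
  y <- gaussian_band(g, 1500, 1, 60) + gaussian_band(g, 1530, 0.02, 10)
  pk <- detect_peaks(new_spectrum(g, y), prominence_frac = 0.05)
  expect_equal(pk$peaks, 1500)
})

test_that("feature-peak matching honours tolerance, ties and ordering", {
  ps <- list(list(peaks = c(1396, 1636), protein = "ptau"))
  pan <- match_features_to_peaks(c(1396, 2000), ps, tol = 8)
  expect_equal(nrow(pan), 1L)
  expect_equal(pan$wavenumber, 1396)
  expect_equal(pan$matched_protein, "ptau")
  expect_equal(pan$peak_distance, 0)

  expect_equal(nrow(match_features_to_peaks(numeric(), ps, tol = 8)), 0L)

  ps2 <- list(list(peaks = 1547, protein = "abeta42"))
  expect_equal(nrow(match_features_to_peaks(1545, ps2, tol = 4)), 1L)  # d = 2
  expect_equal(nrow(match_features_to_peaks(1545, ps2, tol = 1)), 0L)
  # boundary inclusive
  expect_equal(nrow(match_features_to_peaks(1543, ps2, tol = 4)), 1L)

  # tie across proteins: registry order wins at equal distance
  ps3 <- list(list(peaks = 1500, protein = "abeta42"),
              list(peaks = 1504, protein = "ptau"))
  pan3 <- match_features_to_peaks(1502, ps3, tol = 8)
  expect_equal(pan3$matched_protein, "abeta42")
  # match is invariant to feature ordering (set-wise)
  pa <- match_features_to_peaks(c(1502, 1396), list(ps3[[1]], ps3[[2]],
                                                    list(peaks = 1396, protein = "gfap")), tol = 8)
  pb <- match_features_to_peaks(c(1396, 1502), list(ps3[[1]], ps3[[2]],
                                                    list(peaks = 1396, protein = "gfap")), tol = 8)
  expect_setequal(pa$wavenumber, pb$wavenumber)
})

test_that("search stops immediately on a perfectly separating top feature", {
  set.seed(53)
  n <- 60
  x1 <- c(rnorm(n / 2, 5, 0.1), rnorm(n / 2, 0, 0.1))  # separates classes
  X <- cbind(x1, matrix(rnorm(n * 3), n))
  labs <- rep(c("AD", "HC"), each = n / 2)
  tr_set <- make_set(X[seq(1, n, 2), ], labs[seq(1, n, 2)])
  va_set <- make_set(X[seq(2, n, 2), ], labs[seq(2, n, 2)])
  rk <- rank_features(tr_set, c("AD", "HC"), k_neighbors = 3)
  res <- iterative_panel_search(rk, tr_set, va_set, seed = 1)
  expect_true(res$stopped)
  expect_equal(length(res$features), 1L)
  expect_equal(res$features, rk$wavenumber[1])
})

test_that("pure-noise search runs to the cap with a full trace and no stop", {
  set.seed(59)
  n <- 40
  X <- matrix(rnorm(n * 50), n)
  labs <- rep(c("AD", "HC"), n / 2)
  tr_set <- make_set(X[1:24, ], labs[1:24])
  va_set <- make_set(X[25:40, ], labs[25:40])
  rk <- rank_features(tr_set, c("AD", "HC"), k_neighbors = 3)
  res <- iterative_panel_search(rk, tr_set, va_set, cap = 15, seed = 1)
  expect_false(res$stopped)
  expect_equal(length(res$features), 15L)
  expect_equal(nrow(res$trace), 15L)
  expect_equal(res$features, rk$wavenumber[1:15])
  # trace is monotone in feature-set size; the selected set is a ranking prefix
  expect_equal(res$trace$size, 1:15)
})

test_that("search rejects an empty ranking", {
  rk <- structure(data.frame(wavenumber = numeric(), weight = numeric(),
                             rank = integer()),
                  class = c("feature_ranking", "data.frame"))
  set <- make_set(matrix(rnorm(40), 10), rep(c("AD", "HC"), 5))
  expect_error(iterative_panel_search(rk, set, set), "nonempty")
})
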