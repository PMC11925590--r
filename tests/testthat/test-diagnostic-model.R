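# Classifier harness, AUC/threshold/sens-spec machinery and the DeLong test.

test_that("auc scores perfect and hand-counted rankings correctly", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc(c(0.8, 0.7, 0.6, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc(c(0.5, 0.5), c(1, 0)), 0.5)        # tie counts half
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("auc equals the rank-sum U statistic on large random data", {
  set.seed(61)
  sc <- c(rnorm(100, 0.3), rnorm(100))
  y <- rep(c(1, 0), each = 100)
  expect_equal(auc(sc, y), u_statistic_oracle(sc, y) / (100 * 100),
               tolerance = 1e-12)
  # with heavy ties
  sc2 <- sample(1:5, 200, replace = TRUE)
  expect_equal(auc(sc2, y), u_statistic_oracle(sc2, y) / (100 * 100),
               tolerance = 1e-12)
})

test_that("auc complements under score negation and survives monotone maps", {
  set.seed(67)
  sc <- rnorm(50); y <- rep(c(0, 1), 25)
  expect_equal(auc(sc, y) + auc(-sc, y), 1, tolerance = 1e-12)
  expect_equal(auc(exp(2 * sc) + 1, y), auc(sc, y), tolerance = 1e-12)
})

test_that("ROC curves are valid and their trapezoid area equals the AUC", {
  set.seed(71)
  for (rep in 1:5) {
    sc <- sample(seq(0, 1, 0.05), 60, replace = TRUE)  # forces ties
    y <- rbinom(60, 1, 0.4 + 0.3 * sc)
    if (length(unique(y)) < 2) next
    roc <- roc_points(sc, y)
    expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
    expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    area <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
    expect_equal(area, auc(sc, y), tolerance = 1e-12)
  }
})

test_that("sens_spec tabulates the 2x2 confusion table at >= threshold", {
  sc <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1, 0.05)
  y  <- c(1,   1,   0,   1,   0,   1,   0,   0,   1,   0)
  # hand tabulation at t = 0.45: predicted+ = top 5 scores -> TP 3 of 5
  # positives; negatives 0.3/0.2/0.05 stay below -> TN 3 of 5
  ss <- sens_spec(sc, y, 0.45)
  expect_equal(unname(ss), c(3 / 5, 3 / 5))
  expect_equal(unname(sens_spec(sc, y, 0)), c(1, 0))
  expect_equal(unname(sens_spec(sc, y, 2)), c(0, 1))
})

test_that("youden_threshold agrees with the exhaustive-scan oracle", {
  # 6-point fixture: the optimum lies between .4 and .5 (sens 1, spec 2/3)
  sc <- c(0.9, 0.8, 0.6, 0.5, 0.4, 0.1); y <- c(1, 1, 0, 1, 0, 0)
  thr <- youden_threshold(sc, y)
  expect_equal(thr, youden_oracle(sc, y))
  expect_equal(thr, 0.45)
  expect_equal(unname(sens_spec(sc, y, thr)), c(1, 2 / 3))
  # perfectly separated scores: lowest midpoint of the gap, J = 1
  sc2 <- c(0.9, 0.8, 0.3, 0.2); y2 <- c(1, 1, 0, 0)
  expect_equal(youden_threshold(sc2, y2), 0.55)
  set.seed(73)
  for (rep in 1:10) {
    sc3 <- round(rnorm(30), 1); y3 <- rbinom(30, 1, 0.5)
    if (length(unique(y3)) < 2) next
    expect_equal(youden_threshold(sc3, y3), youden_oracle(sc3, y3))
  }
})

test_that("independent scores give near-zero J on large samples", {
  set.seed(79)
  sc <- rnorm(4000); y <- rbinom(4000, 1, 0.5)
  thr <- youden_threshold(sc, y)
  ss <- sens_spec(sc, y, thr)
  expect_lt(ss[1] + ss[2] - 1, 0.1)
})

test_that("delong_paired is exact for identical or monotone-equivalent scores", {
  set.seed(83)
  sc <- rnorm(60); y <- rep(c(0, 1), 30)
  d1 <- delong_paired(sc, sc, y)
  expect_equal(d1$z, 0); expect_equal(d1$p, 1)
  d2 <- delong_paired(sc, exp(sc) + 5, y)       # monotone transform
  expect_equal(d2$z, 0); expect_equal(d2$p, 1)
  expect_equal(d2$auc_a, d2$auc_b, tolerance = 1e-12)
})

test_that("delong variance matches a 10,000-replicate paired bootstrap", {
  set.seed(89)
  n <- 100
  y <- rep(c(1, 0), each = n / 2)
  latent <- rnorm(n) + y
  sa <- latent + rnorm(n, sd = 0.8)
  sb <- 0.6 * latent + rnorm(n, sd = 1.0)
  dl <- delong_paired(sa, sb, y)
  B <- 10000
  boots <- replicate(B, {
    i <- c(sample(which(y == 1), n / 2, TRUE), sample(which(y == 0), n / 2, TRUE))
    auc(sa[i], y[i]) - auc(sb[i], y[i])
  })
  expect_lt(abs(dl$var_diff - var(boots)) / var(boots), 0.10)
})

test_that("delong agrees with pROC's implementation", {
  skip_if_not_installed("pROC")
  set.seed(97)
  y <- rep(c(1, 0), 40)
  sa <- rnorm(80) + 0.8 * y; sb <- rnorm(80) + 0.5 * y
  dl <- delong_paired(sa, sb, y)
  ref <- pROC::roc.test(pROC::roc(y, sa, quiet = TRUE),
                        pROC::roc(y, sb, quiet = TRUE), method = "delong")
  expect_equal(dl$p, unname(ref$p.value), tolerance = 1e-9)
  expect_equal(dl$auc_a, unname(as.numeric(ref$estimate[1])), tolerance = 1e-12)
})

test_that("degenerate DeLong variance with unequal AUCs warns and returns NaN", {
  y <- rep(c(1, 0), each = 3)
  sa <- c(10, 9, 8, 1, 2, 3)      # AUC 1, zero variance
  sb <- c(1, 2, 3, 10, 9, 8)      # AUC 0, zero variance
  expect_warning(d <- delong_paired(sa, sb, y), "degenerate")
  expect_true(is.nan(d$p))
  expect_true(d$degenerate)
})

test_that("every classifier family separates a separable 1-feature problem", {
  set.seed(103)
  n <- 60
  X <- matrix(c(rnorm(n / 2, 4, 0.3), rnorm(n / 2, 0, 0.3)), ncol = 1)
  X <- cbind(X, rnorm(n))
  set <- make_set(X, rep(c("AD", "HC"), each = n / 2))
  for (kind in c("RF", "SVM", "KNN", "LR", "LDA", "BP")) {
    m <- train_classifier(set, c(1300, 1301), kind = kind, seed = 1)
    sc <- predict_scores(m, set)
    expect_equal(auc(sc, set$labels == "AD"), 1.0, info = kind)
  }
  expect_error(train_classifier(set, c(1300), kind = "GBM"), "unknown model")
  one <- subset_samples(set, 1:(n / 2))
  expect_error(train_classifier(one, 1300), "two classes")
  expect_error(train_classifier(set, numeric()), "nonempty")
})

test_that("fits are deterministic under a fixed seed", {
  set.seed(107)
  set <- simulate_cohort(small_design(seed = 9, n = 25))
  prep <- preprocess_pipeline(set)
  probe <- subset_samples(prep, 1:10)
  train <- subset_samples(prep, 11:50)
  for (kind in c("RF", "BP")) {
    m1 <- train_classifier(train, c(1396, 1547, 1636), kind = kind, seed = 42)
    m2 <- train_classifier(train, c(1396, 1547, 1636), kind = kind, seed = 42)
    expect_identical(predict_scores(m1, probe), predict_scores(m2, probe),
                     info = kind)
  }
})

test_that("compare_models produces one row per kind x seed with sane metrics", {
  set.seed(109)
  n <- 80
  X <- cbind(matrix(rnorm(n * 2), n),
             c(rnorm(n / 2, 3), rnorm(n / 2)))  # separable third feature
  labs <- rep(c("AD", "HC"), each = n / 2)
  idx <- sample(n)
  tr <- make_set(X[idx[1:50], ], labs[idx[1:50]])
  va <- make_set(X[idx[51:80], ], labs[idx[51:80]])
  tab <- compare_models(tr, va, panel = c(1300, 1301, 1302),
                        kinds = c("RF", "LR"), seeds = c(1, 2))
  expect_equal(nrow(tab), 4L)
  expect_true(all(tab$val_auc > 0.9))
  smry <- summarize_comparison(tab)
  expect_equal(nrow(smry), 2L)
  expect_true(all(c("val_auc_median", "val_auc_iqr") %in% names(smry)))
})

test_that("evaluate_model freezes the threshold and reports a coherent report", {
  set.seed(113)
  set <- simulate_cohort(small_design(seed = 4, n = 30))
  prep <- preprocess_pipeline(set)
  sp <- ks_split(prep)
  tr <- subset_samples(prep, sp$train_idx)
  va <- subset_samples(prep, sp$val_idx)
  te <- subset_samples(prep, sp$test_idx)
  m <- train_classifier(tr, c(1358, 1396, 1547, 1628, 1636, 1649), seed = 1)
  thr <- youden_threshold(predict_scores(m, va), va$labels == "AD")
  rep <- evaluate_model(m, te, thr)
  expect_equal(rep$threshold, thr)
  expect_equal(rep$n_pos + rep$n_neg, nrow(te$matrix))
  area <- sum(diff(rep$roc$fpr) *
                (head(rep$roc$tpr, -1) + tail(rep$roc$tpr, -1)) / 2)
  expect_equal(area, rep$auc, tolerance = 1e-12)
})
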