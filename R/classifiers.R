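# Classifier harness: six standard binary classifiers behind one fit/score
# interface. All models see only the panel's wavenumber columns and return a
# score increasing with the probability of the positive (disease) class.

MODEL_KINDS <- c("RF", "SVM", "KNN", "LR", "LDA", "BP")

extract_features <- function(set, features) {
  idx <- grid_index(set$grid, features)
  X <- set$matrix[, idx, drop = FALSE]
  colnames(X) <- paste0("wn", format_wn(set$grid$values[idx]))
  X
}

#' Train a diagnostic classifier on a feature panel
#'
#' Fits one of six classifier families on the panel columns of a (typically
#' preprocessed) training set: random forest (`RF`, the reference model),
#' support vector machine (`SVM`, RBF kernel, decision-value scores), k-nearest
#' neighbours (`KNN`, score = fraction of positive neighbours), logistic
#' regression (`LR`), linear discriminant analysis (`LDA`) and a single-hidden-
#' layer back-propagation network (`BP`, 16 units). Deterministic under `seed`.
#'
#' @param train A [spectra_set] restricted to two classes.
#' @param panel Numeric wavenumbers, or a `biomarker_panel`.
#' @param kind One of `r paste(MODEL_KINDS, collapse = ", ")`.
#' @param positive Label treated as the disease class; default the first
#'   non-"HC" label present.
#' @param seed Integer seed for the stochastic fitters.
#' @param rf_ntree,knn_k,bp_size Hyperparameters of the respective families.
#' @return Object of class `diagnostic_model`. Score new data with
#'   [predict_scores()].
#' @export
train_classifier <- function(train, panel, kind = "RF", positive = NULL,
                             seed = 1L, rf_ntree = 500L, knn_k = 5L,
                             bp_size = 16L) {
  stopifnot(inherits(train, "spectra_set"))
  if (inherits(panel, "biomarker_panel")) panel <- panel$wavenumber
  if (!length(panel)) stop("panel must be nonempty")
  if (!kind %in% MODEL_KINDS)
    stop("unknown model kind '", kind, "'; expected one of ",
         paste(MODEL_KINDS, collapse = ", "))
  labs <- unique(train$labels)
  if (length(labs) != 2L) stop("training set must contain exactly two classes")
  if (is.null(positive)) {
    positive <- setdiff(labs, "HC")[1L]
    if (is.na(positive)) positive <- labs[1L]
  }
  if (!positive %in% labs) stop("positive class '", positive, "' absent")
  X <- extract_features(train, panel)
  y <- factor(ifelse(train$labels == positive, "pos", "neg"),
              levels = c("neg", "pos"))
  set.seed(seed)
  fit <- switch(kind,
    RF = randomForest::randomForest(
      x = X, y = y, ntree = rf_ntree,
      mtry = max(1L, floor(sqrt(ncol(X))))),
    SVM = e1071::svm(x = X, y = y, kernel = "radial", scale = TRUE),
    KNN = list(X = X, y = y, k = knn_k,
               mu = colMeans(X), sd = pmax(apply(X, 2L, stats::sd), 1e-12)),
    LR = suppressWarnings(stats::glm.fit(cbind(1, scale(X)),
                                         y == "pos",
                                         family = stats::binomial())),
    LDA = MASS::lda(X, grouping = y),
    BP = {
      Xs <- scale(X)
      nnet::nnet(Xs, as.numeric(y == "pos"), size = bp_size, decay = 0.01,
                 maxit = 300, trace = FALSE)
    })
  scaling <- if (kind %in% c("LR", "BP"))
    list(mu = colMeans(X), sd = pmax(apply(X, 2L, stats::sd), 1e-12))
  structure(list(kind = kind, panel = panel, positive = positive, fit = fit,
                 scaling = scaling, seed = seed, threshold = NA_real_),
            class = "diagnostic_model")
}

#' Score samples with a fitted diagnostic model
#'
#' @param model A [train_classifier()] result.
#' @param set A [spectra_set] on a grid containing the panel wavenumbers.
#' @return Numeric score per row, increasing with evidence for the positive
#'   class (class probability for RF/LR/LDA/BP/KNN; decision value for SVM).
#' @export
predict_scores <- function(model, set) {
  stopifnot(inherits(model, "diagnostic_model"))
  X <- extract_features(set, model$panel)
  switch(model$kind,
    RF = unname(stats::predict(model$fit, X, type = "prob")[, "pos"]),
    SVM = {
      dv <- attr(stats::predict(model$fit, X, decision.values = TRUE),
                 "decision.values")
      v <- dv[, 1L]
      # orient so positive class scores high
      if (grepl("^pos/", colnames(dv)[1L])) v else -v
    },
    KNN = {
      Xs <- sweep(sweep(X, 2L, model$fit$mu), 2L, model$fit$sd, "/")
      Ts <- sweep(sweep(model$fit$X, 2L, model$fit$mu), 2L, model$fit$sd, "/")
      pos <- model$fit$y == "pos"
      apply(Xs, 1L, function(r) {
        d <- sqrt(colSums((t(Ts) - r)^2))
        nb <- order(d, seq_along(d))[seq_len(model$fit$k)]
        mean(pos[nb])
      })
    },
    LR = {
      Xs <- sweep(sweep(X, 2L, model$scaling$mu), 2L, model$scaling$sd, "/")
      b <- model$fit$coefficients
      b[is.na(b)] <- 0                 # dropped collinear columns
      eta <- cbind(1, Xs) %*% b
      as.vector(1 / (1 + exp(-eta)))
    },
    LDA = unname(stats::predict(model$fit, X)$posterior[, "pos"]),
    BP = {
      Xs <- sweep(sweep(X, 2L, model$scaling$mu), 2L, model$scaling$sd, "/")
      as.vector(stats::predict(model$fit, Xs))
    })
}

#' @export
print.diagnostic_model <- function(x, ...) {
  cat(sprintf("<diagnostic_model> %s on %d feature(s), positive = %s%s\n",
              x$kind, length(x$panel), x$positive,
              if (!is.na(x$threshold))
                sprintf(", threshold = %.4g", x$threshold) else ""))
  invisible(x)
}
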