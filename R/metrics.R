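# ROC/AUC machinery, operating-point selection and the paired DeLong test.

binary01 <- function(labels, positive = NULL) {
  u <- unique(labels)
  if (length(u) < 2L) stop("both classes must be present")
  if (length(u) > 2L) stop("labels must be binary")
  if (is.null(positive))
    positive <- if (is.logical(labels)) TRUE
      else if (is.numeric(labels)) max(u)
      else (if ("HC" %in% u) setdiff(u, "HC") else sort(as.character(u)))[1L]
  as.integer(labels == positive)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a random positive outscores a random negative, ties
#' counted one half; identical to the trapezoidal area under the empirical ROC
#' curve.
#'
#' @param scores Numeric score vector.
#' @param labels Binary labels (0/1, logical, or two codes; see `positive`).
#' @param positive Which label is the positive class (default: 1/TRUE, the
#'   non-"HC" code, or first sorted code).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels, positive = NULL) {
  y <- binary01(labels, positive)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @inheritParams auc
#' @return Data frame `fpr`, `tpr`, starting at (0,0) and ending at (1,1),
#'   nondecreasing in both coordinates (tied scores collapse to one point, so
#'   trapezoidal area equals the Mann-Whitney AUC exactly).
#' @export
roc_points <- function(scores, labels, positive = NULL) {
  y <- binary01(labels, positive)
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  keep <- c(diff(ss) != 0, TRUE)       # last index of each tied block
  tp <- cumsum(ys)[keep]; fp <- cumsum(1 - ys)[keep]
  data.frame(fpr = c(0, fp / sum(1 - y)), tpr = c(0, tp / sum(y)))
}

trapezoid_area <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Sensitivity and specificity at a score threshold
#'
#' A sample is called positive iff its score is `>= threshold`.
#'
#' @inheritParams auc
#' @param threshold Score cutoff.
#' @return Named numeric `c(sensitivity, specificity)`.
#' @export
sens_spec <- function(scores, labels, threshold, positive = NULL) {
  y <- binary01(labels, positive)
  pred <- as.integer(scores >= threshold)
  c(sensitivity = sum(pred == 1L & y == 1L) / sum(y == 1L),
    specificity = sum(pred == 0L & y == 0L) / sum(y == 0L))
}

#' Operating threshold by Youden's J
#'
#' Scans the midpoints between adjacent distinct scores (plus one candidate
#' below the minimum and one above the maximum) and returns the cutoff
#' maximizing J = sensitivity + specificity - 1 on the given data; ties go to
#' the lower cutoff. Intended to be run on the validation set, then frozen for
#' test-set evaluation.
#'
#' @inheritParams auc
#' @return The selected score cutoff.
#' @export
youden_threshold <- function(scores, labels, positive = NULL) {
  y <- binary01(labels, positive)
  s <- sort(unique(scores))
  cand <- c(s[1L] - 1, if (length(s) > 1L) (s[-length(s)] + s[-1L]) / 2,
            s[length(s)] + 1)
  j <- vapply(cand, function(t) {
    ss <- sens_spec(scores, y, t, positive = 1L)
    unname(ss[1L] + ss[2L] - 1)
  }, numeric(1L))
  cand[which.max(j)]                    # which.max -> lowest cutoff on ties
}

#' Paired DeLong test for two correlated AUCs
#'
#' Fast placement-value implementation: per-class placement values give each
#' model's AUC and the structural covariance components; the difference
#' `auc_a - auc_b` is referred to a normal with the DeLong variance, two-sided.
#'
#' @param scores_a,scores_b Scores of the two models on the same samples.
#' @param labels Binary labels (see [auc()]).
#' @param positive Positive class.
#' @return List with `auc_a`, `auc_b`, `z`, `p`, `var_diff`, and `degenerate`
#'   (TRUE when the variance vanishes with unequal AUCs, in which case `p` is
#'   NaN and a warning is raised; identical AUCs with zero variance give
#'   `z = 0`, `p = 1`).
#' @export
delong_paired <- function(scores_a, scores_b, labels, positive = NULL) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("scores_a, scores_b and labels must have equal length")
  y <- binary01(labels, positive)
  pos <- y == 1L; neg <- !pos
  n1 <- sum(pos); n0 <- sum(neg)
  placements <- function(s) {
    r_all <- rank(s)
    v10 <- (r_all[pos] - rank(s[pos])) / n0       # placement of each positive
    v01 <- 1 - (r_all[neg] - rank(s[neg])) / n1   # placement of each negative
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  a <- placements(scores_a); b <- placements(scores_b)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  d <- a$auc - b$auc
  if (var_diff <= .Machine$double.eps) {
    if (abs(d) <= .Machine$double.eps^0.5) {
      z <- 0; p <- 1; degen <- FALSE
    } else {
      warning("degenerate DeLong variance with unequal AUCs")
      z <- NaN; p <- NaN; degen <- TRUE
    }
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
    degen <- FALSE
  }
  list(auc_a = a$auc, auc_b = b$auc, z = z, p = p, var_diff = var_diff,
       degenerate = degen)
}

#' Evaluate a fitted model on a spectra set
#'
#' Scores `set`, applies the frozen threshold (chosen beforehand on validation
#' data and passed in, so test labels are never consulted before scoring), and
#' assembles the evaluation report.
#'
#' @param model A [train_classifier()] result.
#' @param set A [spectra_set] containing the contrast's two classes.
#' @param threshold Frozen score cutoff (e.g. from [youden_threshold()] on the
#'   validation scores).
#' @return Object of class `eval_report`: `contrast`, `auc`, `sensitivity`,
#'   `specificity`, `roc` (fpr/tpr data frame), `n_pos`, `n_neg`, `threshold`,
#'   `scores`, `labels`.
#' @export
evaluate_model <- function(model, set, threshold) {
  stopifnot(inherits(model, "diagnostic_model"))
  sc <- predict_scores(model, set)
  y <- binary01(set$labels, model$positive)
  ss <- sens_spec(sc, y, threshold, positive = 1L)
  roc <- roc_points(sc, y, positive = 1L)
  structure(list(contrast = c(model$positive,
                              setdiff(unique(set$labels), model$positive)[1L]),
                 auc = auc(sc, y, positive = 1L),
                 sensitivity = unname(ss[1L]), specificity = unname(ss[2L]),
                 roc = roc, n_pos = sum(y == 1L), n_neg = sum(y == 0L),
                 threshold = threshold, scores = sc, labels = set$labels),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %s vs %s: AUC %.3f, sens %.3f, spec %.3f (n+ %d, n- %d)\n",
    x$contrast[1L], x$contrast[2L], x$auc, x$sensitivity, x$specificity,
    x$n_pos, x$n_neg))
  invisible(x)
}

#' Compare classifier families on a train/validation pair
#'
#' Fits each requested model kind under each seed on the training set and
#' reports sensitivity/specificity (at the validation Youden threshold) and
#' AUC on both sets.
#'
#' @param train,val [spectra_set]s sharing a grid and a two-class contrast.
#' @param panel Feature wavenumbers (or `biomarker_panel`).
#' @param kinds Character vector of model kinds.
#' @param seeds Integer vector of seeds.
#' @param positive Positive class label.
#' @return Data frame, one row per kind x seed, with train/val AUC, sens and
#'   spec; see [summarize_comparison()].
#' @export
compare_models <- function(train, val, panel, kinds = MODEL_KINDS,
                           seeds = 1L, positive = NULL) {
  rows <- list()
  for (kind in kinds) for (seed in seeds) {
    m <- train_classifier(train, panel, kind = kind, positive = positive,
                          seed = seed)
    sc_tr <- predict_scores(m, train)
    sc_va <- predict_scores(m, val)
    y_tr <- binary01(train$labels, m$positive)
    y_va <- binary01(val$labels, m$positive)
    thr <- youden_threshold(sc_va, y_va, positive = 1L)
    st <- sens_spec(sc_tr, y_tr, thr, positive = 1L)
    sv <- sens_spec(sc_va, y_va, thr, positive = 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      kind = kind, seed = seed,
      train_auc = auc(sc_tr, y_tr, positive = 1L),
      train_sens = unname(st[1L]), train_spec = unname(st[2L]),
      val_auc = auc(sc_va, y_va, positive = 1L),
      val_sens = unname(sv[1L]), val_spec = unname(sv[2L]))
  }
  do.call(rbind, rows)
}

#' Median/IQR summary of a model-comparison table
#'
#' @param tab Result of [compare_models()].
#' @return Data frame with one row per kind: median and IQR of validation AUC,
#'   sensitivity and specificity across seeds.
#' @export
summarize_comparison <- function(tab) {
  agg <- function(v) c(median = stats::median(v), iqr = stats::IQR(v))
  out <- do.call(rbind, lapply(split(tab, tab$kind), function(d) {
    data.frame(kind = d$kind[1L],
               val_auc_median = stats::median(d$val_auc),
               val_auc_iqr = stats::IQR(d$val_auc),
               val_sens_median = stats::median(d$val_sens),
               val_sens_iqr = stats::IQR(d$val_sens),
               val_spec_median = stats::median(d$val_spec),
               val_spec_iqr = stats::IQR(d$val_spec))
  }))
  rownames(out) <- NULL
  out
}
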