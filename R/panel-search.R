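#' Iterative marker extraction down a Relief-F ranking
#'
#' Grows the feature set one ranked feature at a time; after each addition the
#' reference classifier (seeded RF by default) is trained on the discovery set
#' and its sensitivity/specificity evaluated on the validation set at the
#' validation Youden threshold. The search stops at the first set where both
#' strictly exceed the targets ("exceeded 80%"); if no prefix within `cap`
#' does, the full cap-limited set is returned (the subsequent peak-matching
#' step prunes it), with the best-performing prefix size recorded in
#' `best_size`. The full trace is recorded.
#'
#' @param ranking A `feature_ranking` (see [relieff()]/[rank_features()]).
#' @param train,val [spectra_set]s of the contrast on the ranking's grid.
#' @param target_sens,target_spec Stopping targets (strict inequalities).
#' @param cap Maximum number of features to consider.
#' @param kind Reference classifier family (default `"RF"`).
#' @param positive Positive class label.
#' @param seed Seed for the reference classifier (fixed across iterations so
#'   the stopping rule is reproducible).
#' @param threshold Operating threshold for the in-loop sensitivity/
#'   specificity evaluation: a fixed score cutoff (default 0.5, the natural
#'   operating point of the probability scorers, immune to per-iteration
#'   threshold-selection optimism on the small validation set) or `"youden"`
#'   to re-derive the Youden cutoff from the validation scores each iteration.
#' @return List of class `panel_search`: `features` (selected wavenumbers, a
#'   prefix of the ranking), `stopped` (TRUE if the targets fired),
#'   `best_size` (prefix with the best `min(sens, spec)` seen), `trace`
#'   (data frame: size, wavenumber added, val sens/spec/AUC).
#' @export
iterative_panel_search <- function(ranking, train, val, target_sens = 0.80,
                                   target_spec = 0.80, cap = 40L,
                                   kind = "RF", positive = NULL, seed = 1L,
                                   threshold = 0.5) {
  if (!nrow(ranking)) stop("ranking must be nonempty")
  cap <- min(as.integer(cap), nrow(ranking))
  trace <- vector("list", cap)
  stopped <- FALSE
  best_size <- 1L; best_val <- -Inf
  for (s in seq_len(cap)) {
    feats <- ranking$wavenumber[seq_len(s)]
    m <- train_classifier(train, feats, kind = kind, positive = positive,
                          seed = seed)
    sc <- predict_scores(m, val)
    y <- binary01(val$labels, m$positive)
    thr <- if (identical(threshold, "youden"))
      youden_threshold(sc, y, positive = 1L) else threshold
    ss <- sens_spec(sc, y, thr, positive = 1L)
    trace[[s]] <- data.frame(size = s, wavenumber = ranking$wavenumber[s],
                             val_sens = unname(ss[1L]),
                             val_spec = unname(ss[2L]),
                             val_auc = auc(sc, y, positive = 1L),
                             threshold = thr)
    if (min(ss) > best_val) { best_val <- min(ss); best_size <- s }
    if (ss[1L] > target_sens && ss[2L] > target_spec) { stopped <- TRUE; break }
  }
  trace <- do.call(rbind, trace[!vapply(trace, is.null, logical(1L))])
  size <- if (stopped) nrow(trace) else cap
  structure(list(features = ranking$wavenumber[seq_len(size)],
                 stopped = stopped, best_size = best_size, trace = trace),
            class = "panel_search")
}

#' @export
print.panel_search <- function(x, ...) {
  n <- nrow(x$trace)
  cat(sprintf(
    "<panel_search> %d feature(s) selected (%s); last val sens %.3f / spec %.3f\n",
    length(x$features),
    if (x$stopped) "targets exceeded" else "cap reached, best min(sens,spec)",
    x$trace$val_sens[n], x$trace$val_spec[n]))
  invisible(x)
}
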