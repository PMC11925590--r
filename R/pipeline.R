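#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end procedure: data source (a
#' [cohort_design()] to simulate, or a CSV path), analysis range and SG
#' parameters, split ratios, Relief-F neighbours, search targets and cap,
#' peak-match tolerance, model family and seed, and the contrasts to run.
#'
#' @param design A [cohort_design()] (used when `csv` is NULL).
#' @param csv Optional path to a cohort spectra CSV.
#' @param range,norm_region Analysis / normalization range in cm^-1.
#' @param sg [sg_params()] for the derivative.
#' @param ratios Split ratios (train, validation, test).
#' @param stratify Stratify the KS split by class.
#' @param k_neighbors Relief-F neighbours.
#' @param target_sens,target_spec,cap Iterative-search stopping targets and cap.
#' @param peak_tol Feature-to-peak adjacency tolerance (cm^-1).
#' @param intersect_contrasts Contrasts (as "POS-NEG" strings) whose panel is
#'   intersected with the purified-protein peaks; default only AD-HC.
#' @param model Reference classifier family.
#' @param contrasts List of label pairs `c(positive, negative)`.
#' @param seed Master seed for model fitting (the cohort seed lives in
#'   `design`).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(design = cohort_design(), csv = NULL,
                            range = c(950, 1800), norm_region = c(950, 1800),
                            sg = sg_params(), ratios = c(0.70, 0.15, 0.15),
                            stratify = TRUE, k_neighbors = 15L,
                            target_sens = 0.80, target_spec = 0.80, cap = 80L,
                            peak_tol = 8, intersect_contrasts = "AD-HC",
                            model = "RF",
                            contrasts = list(c("AD", "HC")), seed = 1L) {
  if (target_sens <= 0 || target_sens >= 1 || target_spec <= 0 ||
      target_spec >= 1)
    stop("targets must lie in (0, 1)")
  structure(list(design = design, csv = csv, range = range,
                 norm_region = norm_region, sg = sg, ratios = ratios,
                 stratify = stratify, k_neighbors = k_neighbors,
                 target_sens = target_sens, target_spec = target_spec,
                 cap = cap, peak_tol = peak_tol,
                 intersect_contrasts = intersect_contrasts, model = model,
                 contrasts = contrasts, seed = as.integer(seed)),
            class = "pipeline_config")
}

contrast_id <- function(ct) paste(ct, collapse = "-")

#' Run the digital-biomarker pipeline
#'
#' Executes, per configured contrast: simulate/load -> preprocess (truncate,
#' vector-normalize, SG second derivative) -> stratified Kennard-Stone
#' 7:1.5:1.5 split -> Relief-F ranking on the discovery set -> iterative
#' marker search against the validation set -> (for configured contrasts,
#' default AD-HC) intersection with purified-protein absorption peaks ->
#' final classifier on the discovery set, threshold frozen on validation ->
#' held-out test evaluation -> analyte/MMSE associations on raw absorbance.
#' Deterministic: re-running the same configuration reproduces every number.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional directory; when given, panels/reports/traces and a
#'   run manifest are written there (JSON/CSV).
#' @return Object of class `pipeline_run`: list with `cohort` (raw), `prep`
#'   (derivative set), and per-contrast results (`split`, `ranking`, `search`,
#'   `panel`, `model`, `threshold`, `val_report`, `test_report`,
#'   `associations`, `mmse_assoc`), plus `manifest`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  cohort <- if (!is.null(cfg$csv)) read_spectra_csv(cfg$csv)
            else simulate_cohort(cfg$design)
  prep <- preprocess_pipeline(cohort, range = cfg$range,
                              norm_region = cfg$norm_region, p = cfg$sg)
  raw_trunc <- truncate_range(cohort, cfg$range[1L], cfg$range[2L])

  peaksets <- lapply(names(protein_registry()), function(pr) {
    sp <- simulate_protein_spectrum(pr, grid = prep$grid, noise_sd = 0)
    detect_peaks(sp, prominence_frac = 0.05, min_separation = 4)
  })

  results <- list()
  for (ct in cfg$contrasts) {
    id <- contrast_id(ct)
    rows <- which(prep$labels %in% ct)
    sub_prep <- subset_samples(prep, rows)
    sub_raw <- subset_samples(raw_trunc, rows)
    split <- ks_split(sub_prep, ratios = cfg$ratios, stratify = cfg$stratify)
    tr <- subset_samples(sub_prep, split$train_idx)
    va <- subset_samples(sub_prep, split$val_idx)
    te <- subset_samples(sub_prep, split$test_idx)

    ranking <- rank_features(tr, ct, k_neighbors = cfg$k_neighbors)
    search <- iterative_panel_search(ranking, tr, va,
                                     target_sens = cfg$target_sens,
                                     target_spec = cfg$target_spec,
                                     cap = cfg$cap, kind = cfg$model,
                                     positive = ct[1L], seed = cfg$seed)
    fallback <- FALSE
    if (id %in% cfg$intersect_contrasts) {
      panel <- match_features_to_peaks(search$features, peaksets,
                                       tol = cfg$peak_tol)
      if (!nrow(panel)) {            # no feature near any protein peak: keep
        fallback <- TRUE             # the ML-selected markers unmatched
        panel <- match_features_to_peaks(search$features, peaksets, tol = Inf)
      }
    } else {
      panel <- match_features_to_peaks(search$features, peaksets, tol = Inf)
    }

    model <- train_classifier(tr, panel, kind = cfg$model, positive = ct[1L],
                              seed = cfg$seed)
    thr <- youden_threshold(predict_scores(model, va),
                            binary01(va$labels, ct[1L]), positive = 1L)
    model$threshold <- thr
    val_report <- evaluate_model(model, va, thr)
    test_report <- evaluate_model(model, te, thr)

    assoc <- if (!is.null(sub_raw$analytes) && sum(sub_raw$labels == ct[1L]) >= 3)
      tryCatch(association_table(sub_raw, panel, group = ct[1L]),
               error = function(e) NULL)
    mmse_assoc <- NULL
    if (!is.null(sub_raw$mmse) && "MCI" %in% ct) {
      rows_m <- which(sub_raw$labels == "MCI")
      if (length(rows_m) >= 3) {
        wn <- panel$wavenumber[1L]
        mmse_assoc <- mmse_association(
          sub_raw$matrix[rows_m, grid_index(sub_raw$grid, wn)],
          sub_raw$mmse[rows_m], marker = format_wn(wn))
      }
    }
    results[[id]] <- list(contrast = ct, split = split, ranking = ranking,
                          search = search, panel = panel,
                          panel_fallback = fallback, model = model,
                          threshold = thr, val_report = val_report,
                          test_report = test_report, associations = assoc,
                          mmse_assoc = mmse_assoc)
  }

  manifest <- list(
    contrasts = vapply(cfg$contrasts, contrast_id, character(1L)),
    n_samples = nrow(cohort$matrix),
    grid = list(min = min(prep$grid$values), max = max(prep$grid$values),
                spacing = prep$grid$spacing),
    seed = cfg$seed,
    cohort_seed = if (is.null(cfg$csv)) cfg$design$seed else NA,
    panels = lapply(results, function(r) r$panel$wavenumber),
    test_auc = vapply(results, function(r) r$test_report$auc, numeric(1L)),
    leakage_check = vapply(results, function(r)
      length(intersect(r$split$test_idx,
                       c(r$split$train_idx, r$split$val_idx))) == 0L,
      logical(1L))
  )
  run <- structure(list(cohort = cohort, prep = prep, results = results,
                        manifest = manifest, config = cfg),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_run_artifacts(run, out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d sample(s), %d contrast(s)\n",
              x$manifest$n_samples, length(x$results)))
  for (id in names(x$results)) {
    r <- x$results[[id]]
    cat(sprintf("  %s: panel %d feature(s)%s, test AUC %.3f (sens %.3f, spec %.3f)\n",
                id, nrow(r$panel),
                if (r$panel_fallback) " [no peak match; ML set kept]" else "",
                r$test_report$auc, r$test_report$sensitivity,
                r$test_report$specificity))
  }
  invisible(x)
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(run$results)) {
    r <- run$results[[id]]
    jsonlite::write_json(
      list(contrast = r$contrast, panel = as.data.frame(r$panel),
           stopped = r$search$stopped, threshold = r$threshold),
      file.path(out_dir, paste0("panel_", id, ".json")),
      auto_unbox = TRUE, digits = NA, dataframe = "columns")
    utils::write.csv(r$search$trace,
                     file.path(out_dir, paste0("trace_", id, ".csv")),
                     row.names = FALSE)
    utils::write.csv(r$test_report$roc,
                     file.path(out_dir, paste0("roc_", id, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(
      list(contrast = r$contrast, auc = r$test_report$auc,
           sensitivity = r$test_report$sensitivity,
           specificity = r$test_report$specificity,
           n_pos = r$test_report$n_pos, n_neg = r$test_report$n_neg),
      file.path(out_dir, paste0("report_", id, ".json")),
      auto_unbox = TRUE, digits = NA)
    if (!is.null(r$associations))
      utils::write.csv(r$associations,
                       file.path(out_dir, paste0("associations_", id, ".csv")),
                       row.names = FALSE)
    write_split_json(r$split, file.path(out_dir, paste0("split_", id, ".json")))
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
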