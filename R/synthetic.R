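# Synthetic cohort generator: Gaussian-band plasma spectra with planted
# group-dependent band-depth effects, analyte concentrations negatively coupled
# to band depth, and MMSE scores. Stands in for patient cohorts that are not
# publicly available; the planted truth doubles as the oracle for panel
# recovery tests.

#' Gaussian absorption band
#'
#' @param grid A [wavenumber_grid].
#' @param center Band centre in cm^-1 (within the grid).
#' @param height Peak absorbance (AU), > 0.
#' @param fwhm Full width at half maximum in cm^-1, in \[4, 200\].
#' @return Numeric vector over the grid:
#'   `height * exp(-4 log(2) (v - center)^2 / fwhm^2)`.
#' @export
gaussian_band <- function(grid, center, height, fwhm) {
  stopifnot(inherits(grid, "wavenumber_grid"))
  if (height <= 0) stop("band height must be > 0")
  if (fwhm < 4 || fwhm > 200) stop("band fwhm must lie in [4, 200] cm^-1")
  if (center < min(grid$values) || center > max(grid$values))
    stop("band center outside the grid")
  height * exp(-4 * log(2) * (grid$values - center)^2 / fwhm^2)
}

#' Default shared plasma background bands
#'
#' Amide A, CH stretch, amide I/II, CH bend, fingerprint (1400/1360 region),
#' PO2- and C-O bands, so both the 1750-1200 and 1200-900 cm^-1 regions carry
#' signal.
#'
#' @return Data frame `center`, `height`, `fwhm`.
#' @export
default_base_bands <- function() {
  data.frame(
    center = c(3290, 2930, 1650, 1545, 1455, 1400, 1360, 1240, 1080),
    height = c(0.45, 0.20, 0.85, 0.52, 0.25, 0.35, 0.42, 0.15, 0.14),
    fwhm   = c(160,  70,   45,   42,   30,   26,   24,   42,   48)
  )
}

# reference absorption-peak registry for the purified proteins; the first two
# centres of each entry are the published marker pair
protein_registry <- function() {
  minor <- data.frame(center = c(2930, 1080, 3280),
                      height = c(0.10, 0.08, 0.12),
                      fwhm   = c(60, 50, 130))
  list(
    abeta42 = rbind(data.frame(center = c(1547, 1628),
                               height = c(0.38, 0.50), fwhm = c(16, 14)), minor),
    ptau    = rbind(data.frame(center = c(1396, 1636),
                               height = c(0.45, 0.50), fwhm = c(14, 15)), minor),
    gfap    = rbind(data.frame(center = c(1358, 1649),
                               height = c(0.42, 0.50), fwhm = c(14, 15)), minor)
  )
}

#' Published reference peak pairs of the purified proteins
#'
#' @return Named list: `abeta42` c(1547, 1628), `ptau` c(1396, 1636),
#'   `gfap` c(1358, 1649) (cm^-1).
#' @export
protein_peak_registry <- function() {
  lapply(protein_registry(), function(df) sort(df$center[1:2]))
}

#' Simulate a purified-protein reference spectrum
#'
#' Sum of Gaussian bands whose centres include exactly the published marker
#' pair for the protein (Abeta42: 1547/1628; p-tau: 1396/1636; GFAP:
#' 1358/1649 cm^-1) plus minor far-away secondary bands, with optional
#' additive Gaussian noise.
#'
#' @param protein One of `"abeta42"`, `"ptau"`, `"gfap"`.
#' @param grid A [wavenumber_grid].
#' @param noise_sd Additive noise sd (AU); 0 gives the noise-free reference.
#' @param seed Optional integer seed (only used when `noise_sd > 0`).
#' @return A [spectrum].
#' @export
simulate_protein_spectrum <- function(protein, grid = canonical_grid(),
                                      noise_sd = 0, seed = NULL) {
  reg <- protein_registry()
  if (!protein %in% names(reg))
    stop("unknown protein '", protein, "'; expected one of ",
         paste(names(reg), collapse = ", "))
  bands <- reg[[protein]]
  bands <- bands[bands$center >= min(grid$values) &
                   bands$center <= max(grid$values), , drop = FALSE]
  y <- rep(0, length(grid$values))
  for (i in seq_len(nrow(bands)))
    y <- y + gaussian_band(grid, bands$center[i], bands$height[i], bands$fwhm[i])
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  }
  new_spectrum(grid, y, sample_id = protein, meta = list(protein = protein))
}

#' Default planted effects per diagnosis
#'
#' Fractional band-depth changes at the marker centres (negative = reduced
#' absorbance in patients): AD at the six published panel wavenumbers, MCI in
#' the 1365-1398 region, DLB/FTD/PSP at distinct amide-II-region centres.
#'
#' @return Named list of data frames `center`, `depth`.
#' @export
default_effect_map <- function() {
  list(
    AD  = data.frame(center = c(1358, 1396, 1547, 1628, 1636, 1649),
                     depth = -0.08),
    MCI = data.frame(center = c(1365, 1382, 1396), depth = -0.04),
    DLB = data.frame(center = c(1524, 1558), depth = -0.08),
    FTD = data.frame(center = c(1508, 1528), depth = -0.08),
    PSP = data.frame(center = c(1536, 1552), depth = -0.08),
    HC  = data.frame(center = numeric(), depth = numeric())
  )
}

# analyte log-normal parameters per group: log-median and IQR-derived log-sd
# (cohort baseline table); DLB/FTD/PSP reuse the HC values (not reported)
analyte_group_params <- function() {
  p <- list(
    ptau217 = list(AD = c(5.23, 4.20, 6.76), HC = c(4.48, 3.60, 6.05),
                   MCI = c(3.50, 3.00, 4.01)),
    abeta42 = list(AD = c(60.41, 48.06, 85.75), HC = c(70.13, 52.11, 92.70),
                   MCI = c(69.05, 47.74, 98.18)),
    gfap    = list(AD = c(41.32, 27.92, 61.16), HC = c(19.15, 14.92, 27.91),
                   MCI = c(24.67, 16.62, 41.50))
  )
  lapply(p, function(groups) {
    out <- lapply(groups, function(q)
      c(mu = log(q[1L]), sigma = (log(q[3L]) - log(q[2L])) / 1.349))
    for (g in c("DLB", "FTD", "PSP")) out[[g]] <- out[["HC"]]
    out
  })
}

# MMSE medians [IQR] per group from the cohort baseline table
mmse_group_params <- function() {
  q <- list(AD = c(15, 8, 20), HC = c(29, 29, 30), MCI = c(25, 22, 27),
            DLB = c(15, 7, 22), FTD = c(16, 8, 22), PSP = c(24, 18, 27))
  lapply(q, function(x) c(m = x[1L], s = max((x[3L] - x[2L]) / 1.349, 0.5)))
}

#' Default analyte couplings
#'
#' Negative coupling of p-tau217 (anchor 1396 cm^-1) and GFAP (1358 cm^-1)
#' log-concentrations to band depth; zero coupling for Abeta42 (1547 cm^-1).
#'
#' @return Named list with `center`, `sign`, `strength` per analyte.
#' @export
default_couplings <- function() {
  list(ptau217 = list(center = 1396, sign = -1, strength = 0.5),
       gfap    = list(center = 1358, sign = -1, strength = 0.5),
       abeta42 = list(center = 1547, sign = -1, strength = 0))
}

#' Synthetic cohort design
#'
#' Parameters of the generative model. Each sample's spectrum is
#' `scatter * (base bands + sum_c f_c * env(c) * bump_c) + baseline + noise`,
#' where `f_c` is the fractional band-depth deviation at marker centre `c`:
#' the group's planted depth plus a shared per-sample deviation plus an
#' independent per-centre deviation. Analyte log-concentrations are linearly
#' coupled (with the stated sign and strength) to the sample's depth deviation
#' at the analyte's anchor centre; MMSE is drawn from group medians/IQRs and,
#' for MCI, positively coupled to fingerprint band depth.
#'
#' @param n_per_group Samples per diagnosis group (>= 2).
#' @param groups Character subset of `r paste(DIAGNOSIS_CODES, collapse = ", ")`.
#' @param grid Wavenumber grid for the simulated spectra.
#' @param base_bands Data frame `center`, `height`, `fwhm` of the shared
#'   plasma background bands.
#' @param effect_map Named list (by group) of data frames `center`, `depth`
#'   (fractional change in (-1, 1); negative = shallower band).
#' @param effect_fwhm Width (cm^-1) of the local depth-perturbation bump.
#' @param depth_sd_center Per-sample, per-centre sd of the fractional depth
#'   deviation (biological variability independent across marker bands).
#' @param depth_tails_df Degrees of freedom of the (variance-standardized)
#'   Student-t distribution of the per-centre deviations; finite values give
#'   the heavy-tailed population heterogeneity seen in clinical cohorts
#'   (comorbidity, disease-stage spread), `Inf` gives Gaussian deviations.
#' @param depth_sd_shared Per-sample sd of the deviation shared by all marker
#'   bands.
#' @param noise_sd Additive spectral noise sd (AU).
#' @param baseline_offset,baseline_slope Uniform ranges for the linear
#'   baseline (AU and AU/cm^-1).
#' @param scatter_sd Sd of the multiplicative scatter factor (mean 1).
#' @param coupling Named list per analyte: `center`, `sign`, `strength` in
#'   \[0, 1\] linking log-concentration to the standardized depth deviation.
#' @param mmse_coupling Correlation of MCI MMSE scores with the 1396 cm^-1
#'   depth deviation.
#' @param seed Integer seed; fixes every output bit-for-bit.
#' @return Object of class `cohort_design`.
#' @export
cohort_design <- function(n_per_group = 150, groups = c("AD", "HC"),
                          grid = canonical_grid(),
                          base_bands = default_base_bands(),
                          effect_map = default_effect_map(),
                          effect_fwhm = 5,
                          depth_sd_center = 0.125,
                          depth_tails_df = 4,
                          depth_sd_shared = 0.01,
                          noise_sd = 0.03,
                          baseline_offset = c(-0.005, 0.005),
                          baseline_slope = c(-5e-6, 5e-6),
                          scatter_sd = 0.02,
                          coupling = default_couplings(),
                          mmse_coupling = 0.4,
                          seed = 1L) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  bad <- setdiff(groups, DIAGNOSIS_CODES)
  if (length(bad)) stop("unknown group(s): ", paste(bad, collapse = ", "))
  for (g in groups) {
    em <- effect_map[[g]]
    if (is.null(em)) next
    if (nrow(em) && any(abs(em$depth) >= 1))
      stop("fractional depth changes must lie in (-1, 1)")
    if (nrow(em) && (any(em$center < min(grid$values)) ||
                     any(em$center > max(grid$values))))
      stop("effect centers must lie on the grid")
  }
  structure(list(n_per_group = n_per_group, groups = groups, grid = grid,
                 base_bands = base_bands, effect_map = effect_map,
                 effect_fwhm = effect_fwhm,
                 depth_sd_center = depth_sd_center,
                 depth_tails_df = depth_tails_df,
                 depth_sd_shared = depth_sd_shared, noise_sd = noise_sd,
                 baseline_offset = baseline_offset,
                 baseline_slope = baseline_slope, scatter_sd = scatter_sd,
                 coupling = coupling, mmse_coupling = mmse_coupling,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Simulate a cohort of plasma spectra
#'
#' Draws spectra, analyte concentrations and MMSE scores according to a
#' [cohort_design()]. Deterministic under the design's seed. The planted truth
#' (effect centres/depths per group, couplings, seed) is attached as
#' `meta$truth` and can be serialized with [write_truth_json()] for recovery
#' scoring.
#'
#' @param design A [cohort_design].
#' @return A [spectra_set] with `n_per_group * length(groups)` rows (grouped in
#'   `groups` order), analytes and MMSE filled in.
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  grid <- design$grid
  nv <- length(grid$values)
  bb <- design$base_bands
  bb <- bb[bb$center >= min(grid$values) & bb$center <= max(grid$values), ,
           drop = FALSE]
  base <- rep(0, nv)
  for (i in seq_len(nrow(bb)))
    base <- base + gaussian_band(grid, bb$center[i], bb$height[i], bb$fwhm[i])
  base_at <- function(wn) {
    v <- 0
    for (i in seq_len(nrow(bb)))
      v <- v + bb$height[i] * exp(-4 * log(2) * (wn - bb$center[i])^2 / bb$fwhm[i]^2)
    v
  }
  # union of marker centres across the designed groups: every sample gets a
  # depth deviation there, so controls vary too
  centers <- sort(unique(unlist(lapply(design$groups, function(g) {
    em <- design$effect_map[[g]]
    if (is.null(em)) numeric() else em$center
  }))))
  for (cp in design$coupling) centers <- sort(unique(c(centers, cp$center)))
  env <- vapply(centers, base_at, numeric(1L))
  bumps <- vapply(centers, function(cc)
    exp(-4 * log(2) * (grid$values - cc)^2 / design$effect_fwhm^2),
    numeric(nv))                                   # nv x n_centers

  n_g <- design$n_per_group
  n <- n_g * length(design$groups)
  labels <- rep(design$groups, each = n_g)
  planted <- matrix(0, n, length(centers),
                    dimnames = list(NULL, format_wn(centers)))
  for (g in design$groups) {
    em <- design$effect_map[[g]]
    if (is.null(em) || !nrow(em)) next
    rows <- which(labels == g)
    for (j in seq_len(nrow(em))) {
      k <- match(em$center[j], centers)
      planted[rows, k] <- planted[rows, k] + em$depth[j]
    }
  }
  dev_shared <- stats::rnorm(n, 0, design$depth_sd_shared)
  df <- design$depth_tails_df
  dev_center <- if (is.finite(df)) {
    # variance-standardized t: heavy-tailed biological heterogeneity
    matrix(stats::rt(n * length(centers), df) * sqrt((df - 2) / df) *
             design$depth_sd_center, n)
  } else {
    matrix(stats::rnorm(n * length(centers), 0, design$depth_sd_center), n)
  }
  fdepth <- planted + dev_shared + dev_center     # fractional depth per centre
  scatter <- pmax(1 + stats::rnorm(n, 0, design$scatter_sd), 0.5)
  b_off <- stats::runif(n, design$baseline_offset[1L], design$baseline_offset[2L])
  b_slp <- stats::runif(n, design$baseline_slope[1L], design$baseline_slope[2L])
  noise <- matrix(stats::rnorm(n * nv, 0, design$noise_sd), n)

  bump_amp <- fdepth * rep(env, each = n)         # n x centers
  mat <- tcrossprod(bump_amp, bumps)              # n x nv perturbations
  mat <- mat + rep(base, each = n)
  mat <- mat * scatter
  mat <- mat + outer(b_off, rep(1, nv)) +
    outer(b_slp, grid$values - mean(grid$values), function(a, b) a * b)
  mat <- mat + noise

  # analytes: log-normal, log-concentration coupled to the standardized depth
  # deviation at the analyte's anchor centre
  sd_dev <- sqrt(design$depth_sd_shared^2 + design$depth_sd_center^2)
  apar <- analyte_group_params()
  analytes <- data.frame(row.names = seq_len(n))
  for (a in names(design$coupling)) {
    cp <- design$coupling[[a]]
    k <- match(cp$center, centers)
    z <- (dev_shared + dev_center[, k]) / sd_dev
    eps <- stats::rnorm(n)
    logc <- numeric(n)
    for (g in design$groups) {
      rows <- which(labels == g)
      pg <- apar[[a]][[g]]
      logc[rows] <- pg["mu"] + pg["sigma"] *
        (cp$sign * cp$strength * z[rows] +
           sqrt(1 - cp$strength^2) * eps[rows])
    }
    analytes[[a]] <- exp(logc)
  }

  mpar <- mmse_group_params()
  k96 <- match(1396, centers)
  z96 <- if (!is.na(k96)) (dev_shared + dev_center[, k96]) / sd_dev
         else stats::rnorm(n)
  eps_m <- stats::rnorm(n)
  mmse <- numeric(n)
  for (g in design$groups) {
    rows <- which(labels == g)
    pg <- mpar[[g]]
    rho <- if (g == "MCI") design$mmse_coupling else 0
    mmse[rows] <- pg["m"] + pg["s"] *
      (rho * z96[rows] + sqrt(1 - rho^2) * eps_m[rows])
  }
  mmse <- pmin(pmax(round(mmse), 0), 30)

  truth <- list(
    effect_map = design$effect_map[design$groups],
    coupling = design$coupling,
    depth_sd_center = design$depth_sd_center,
    depth_sd_shared = design$depth_sd_shared,
    noise_sd = design$noise_sd, seed = design$seed
  )
  spectra_set(grid, mat, labels, analytes = analytes, mmse = mmse,
              meta = list(truth = truth,
                          sample_id = sprintf("%s_%03d", labels,
                                              stats::ave(seq_len(n), labels,
                                                         FUN = seq_along))))
}

#' Write the planted-truth sidecar of a simulated cohort
#'
#' @param set A [spectra_set] produced by [simulate_cohort()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(set, path) {
  if (is.null(set$meta$truth)) stop("set carries no planted truth")
  jsonlite::write_json(set$meta$truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' CSF amyloid/tau status
#'
#' Classifies A+/A- and T+/T- from CSF analyte concentrations:
#' A+ iff Abeta42 < 550 pg/ml, or Abeta42 in 551-650 pg/ml with
#' Abeta42/Abeta40 <= 0.1; T+ iff p-tau >= 61 pg/ml.
#'
#' @param csf_abeta42,csf_abeta40,csf_ptau Concentrations in pg/ml (> 0);
#'   vectors recycled to common length.
#' @return Data frame with columns `a_status` ("A+"/"A-") and `t_status`
#'   ("T+"/"T-").
#' @export
classify_csf_status <- function(csf_abeta42, csf_abeta40, csf_ptau) {
  n <- max(length(csf_abeta42), length(csf_abeta40), length(csf_ptau))
  ab42 <- rep_len(csf_abeta42, n); ab40 <- rep_len(csf_abeta40, n)
  ptau <- rep_len(csf_ptau, n)
  if (any(ab42 <= 0) || any(ab40 <= 0) || any(ptau <= 0))
    stop("CSF concentrations must be positive")
  a_pos <- ab42 < 550 | (ab42 >= 551 & ab42 <= 650 & ab42 / ab40 <= 0.1)
  t_pos <- ptau >= 61
  data.frame(a_status = ifelse(a_pos, "A+", "A-"),
             t_status = ifelse(t_pos, "T+", "T-"))
}
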