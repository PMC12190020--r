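# Deterministic synthetic-data generators.  Every generator emits the
# same tabular dialects the readers consume, with the statistical
# structure the downstream analysis assumes: Gaussian, homoscedastic
# noise within a composition class or concentration level.

#' Generator configuration
#'
#' Bundles every tunable of the synthetic-data generators.  Defaults are
#' the reference study conditions: the fitted mixture coefficients, the
#' class sigma averages of the solvent screen (pure 0.039, binary 0.046,
#' ternary 0.060 AU), the Trolox calibration line y = 0.013x + 0.039 with
#' 0.004 AU replicate noise, and the standard microplate geometry.
#'
#' @param seed Integer RNG seed (mandatory: generators are deterministic
#'   given the config).
#' @param scheffe_coeffs Named vector `c(k1,k2,k3,k12,k13,k23)` of the
#'   true mixture model (transformed-signal units).
#' @param sigma_by_class Named vector `c(pure=, binary=, ternary=)` of
#'   replicate SDs (AU) per composition class.
#' @param cal_slope,cal_intercept True calibration line (AU/uM, AU).
#' @param cal_sigma Replicate noise SD for calibration / sample reads (AU).
#' @param kinetic_drift Linear signal drift (AU/min) for kinetic series.
#' @param teac_targets Named vector of true per-sample TEACs (mol/g).
#' @param geometry An [assay_geometry()].
#' @param epsilon Molar absorptivity (L mol^-1 cm^-1).
#' @param replicates Replicates per design point / level / sample.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed,
                             scheffe_coeffs = c(k1 = 0.046, k2 = 0.038,
                                                k3 = 0.015, k12 = 0.063,
                                                k13 = 0.112, k23 = 0.066),
                             sigma_by_class = c(pure = 0.039, binary = 0.046,
                                                ternary = 0.060),
                             cal_slope = 0.013, cal_intercept = 0.039,
                             cal_sigma = 0.004, kinetic_drift = 0,
                             teac_targets = NULL,
                             geometry = assay_geometry(),
                             epsilon = 2.62e4, replicates = 3) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("a single integer seed is mandatory", call. = FALSE)
  }
  if (any(sigma_by_class < 0) || cal_sigma < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  stopifnot(length(scheffe_coeffs) == 6L, inherits(geometry, "assay_geometry"))
  structure(
    list(seed = as.integer(seed), scheffe_coeffs = scheffe_coeffs,
         sigma_by_class = sigma_by_class, cal_slope = cal_slope,
         cal_intercept = cal_intercept, cal_sigma = cal_sigma,
         kinetic_drift = kinetic_drift, teac_targets = teac_targets,
         geometry = geometry, epsilon = epsilon,
         replicates = as.integer(replicates)),
    class = "generator_config"
  )
}

# Standard 7-point simplex design: vertices, edge midpoints, centroid.
simplex_design_points <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
        c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5),
        c(1, 1, 1) / 3)
}

#' Simulate a solvent-screen design table
#'
#' For each of the 7 standard simplex points (3 vertices, 3 edge
#' midpoints, centroid) the mean raw signal is the back-transformed model
#' prediction `Phi(z) / sigma_class`, and replicates add Gaussian noise
#' with SD `sigma_class * noise_scale`.  Negative draws are truncated at 0
#' (raw absorbances are non-negative).
#'
#' @param cfg A [generator_config()].
#' @param noise_scale Multiplier on the class-SD replicate noise
#'   (default 1; 0 gives noiseless replicates).
#' @return A [mixture_design_table()] (flagged degenerate when
#'   `cfg$replicates == 1`).
#' @export
gen_mixture_table <- function(cfg, noise_scale = 1) {
  stopifnot(inherits(cfg, "generator_config"), noise_scale >= 0)
  set.seed(cfg$seed)
  Z <- simplex_design_points()
  cls <- apply(Z, 1L, classify_composition)
  mu <- predict_phi(cfg$scheffe_coeffs, Z) /
    as.numeric(cfg$sigma_by_class[cls])
  rows <- lapply(seq_len(nrow(Z)), function(i) {
    psi <- mu[i] + stats::rnorm(cfg$replicates,
                                sd = cfg$sigma_by_class[[cls[i]]] *
                                  noise_scale)
    data.frame(frac_methanol = Z[i, 1], frac_ethanol = Z[i, 2],
               frac_water = Z[i, 3], replicate = seq_len(cfg$replicates),
               absorbance = pmax(psi, 0))
  })
  mixture_design_table(do.call(rbind, rows))
}

#' Simulate calibration standards
#'
#' `y = slope * x + intercept + Normal(0, cal_sigma)`, `cfg$replicates`
#' per level.
#'
#' @param cfg A [generator_config()].
#' @param levels Concentration levels in uM (default the six equally
#'   spaced levels 0..50); at least 3 required.
#' @return Data frame in the calibration dialect
#'   (`conc_uM, replicate, absorbance`).
#' @export
gen_calibration <- function(cfg, levels = seq(0, 50, by = 10)) {
  stopifnot(inherits(cfg, "generator_config"))
  if (length(levels) < 3L) {
    stop("need at least 3 concentration levels", call. = FALSE)
  }
  set.seed(cfg$seed)
  rows <- lapply(levels, function(x) {
    data.frame(conc_uM = x, replicate = seq_len(cfg$replicates),
               absorbance = cfg$cal_intercept + cfg$cal_slope * x +
                 stats::rnorm(cfg$replicates, sd = cfg$cal_sigma))
  })
  do.call(rbind, rows)
}

#' Simulate kinetic absorbance series
#'
#' `A(t) = base + drift * t + Normal(0, cal_sigma)` at each of
#' `n_timepoints` minutes (0, 1, ..., n_timepoints - 1), one series per
#' replicate, mirroring a plate read every minute.
#'
#' @param cfg A [generator_config()].
#' @param base Baseline absorbance (AU); may be a named vector, one series
#'   set per level.
#' @param n_timepoints Number of readings per series (>= 2; default 31,
#'   i.e. 0..30 min).
#' @return Data frame in the plate dialect
#'   (`well, time_min, wavelength_nm, absorbance`) plus a `level` column
#'   mapping wells to the names of `base`.
#' @export
gen_kinetic <- function(cfg, base, n_timepoints = 31) {
  stopifnot(inherits(cfg, "generator_config"))
  if (n_timepoints < 2L) stop("need n_timepoints >= 2", call. = FALSE)
  set.seed(cfg$seed)
  if (is.null(names(base))) names(base) <- paste0("L", seq_along(base))
  t <- seq_len(n_timepoints) - 1
  well_pool <- as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
  idx <- 0L
  rows <- lapply(names(base), function(lv) {
    do.call(rbind, lapply(seq_len(cfg$replicates), function(r) {
      idx <<- idx + 1L
      data.frame(well = well_pool[idx], time_min = t, wavelength_nm = 450,
                 absorbance = base[[lv]] + cfg$kinetic_drift * t +
                   stats::rnorm(n_timepoints, sd = cfg$cal_sigma),
                 level = lv)
    }))
  })
  do.call(rbind, rows)
}

#' Simulate a sample plate from target TEAC values
#'
#' Inverts the TEAC formula: each sample's mean blank-corrected
#' absorbance is `delta_A = teac * epsilon * V_s * W_s * h / (V_f * V_i)`;
#' replicate wells add Gaussian noise (`cal_sigma`) and blank wells sit at
#' the calibration intercept.  A warning is recorded when an implied
#' delta_A falls outside [0, 3] (beyond any plausible photometric range).
#'
#' @param cfg A [generator_config()] with positive `teac_targets` (mol/g).
#' @return List with `plate` (a [plate_table()], single 30-min endpoint
#'   reading per well) and `layout` (data frame `well, sample_id`, blanks
#'   labelled `"blank"`).
#' @export
gen_samples <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  tt <- cfg$teac_targets
  if (is.null(tt) || length(tt) == 0L) {
    stop("cfg$teac_targets must be supplied", call. = FALSE)
  }
  if (any(tt <= 0)) stop("teac_targets must be positive", call. = FALSE)
  if (is.null(names(tt))) names(tt) <- paste0("S", seq_along(tt))
  set.seed(cfg$seed)
  g <- cfg$geometry
  da_mean <- tt * cfg$epsilon * g$v_s * g$w_s * g$h / (g$v_f * g$v_i)
  if (any(da_mean < 0 | da_mean > 3)) {
    warning("implied delta_A outside [0, 3] for sample(s): ",
            paste(names(tt)[da_mean < 0 | da_mean > 3], collapse = ", "),
            call. = FALSE)
  }
  well_pool <- as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
  series <- list()
  layout <- list()
  idx <- 0L
  add_well <- function(label, value) {
    idx <<- idx + 1L
    w <- well_pool[idx]
    series[[length(series) + 1L]] <<- kinetic_series(w, 30, value)
    layout[[length(layout) + 1L]] <<- data.frame(well = w, sample_id = label)
  }
  blank_base <- cfg$cal_intercept
  for (r in seq_len(cfg$replicates)) {
    add_well("blank", blank_base + stats::rnorm(1, sd = cfg$cal_sigma))
  }
  for (s in names(tt)) {
    for (r in seq_len(cfg$replicates)) {
      add_well(s, blank_base + da_mean[[s]] +
                 stats::rnorm(1, sd = cfg$cal_sigma))
    }
  }
  list(plate = plate_table(series), layout = do.call(rbind, layout))
}
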