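# Trolox equivalent antioxidant capacity (TEAC) of sample extracts from
# blank-corrected plate absorbances and the assay geometry.

#' Assay geometry
#'
#' The volumes, mass and optical path entering the TEAC computation.
#' Defaults reproduce a standard microplate CUPRAC setup: 250 uL final
#' well volume, 10 mL extract, 100 uL of extract per well, 80 mg of
#' sample, 0.50 cm solution height.
#'
#' @param v_f Final well volume (mL).
#' @param v_i Initial extract volume (mL).
#' @param v_s Sample volume added to the well (mL), at most `v_f`.
#' @param w_s Sample mass (g).
#' @param h Optical path length (cm).
#' @param provenance Optional named list of extraction metadata (vortex
#'   time, centrifugation, ...); carried through to reports, never used in
#'   computation.
#' @return An object of class `assay_geometry`.
#' @export
assay_geometry <- function(v_f = 0.25, v_i = 10, v_s = 0.10, w_s = 0.080,
                           h = 0.50, provenance = list()) {
  vals <- c(v_f = v_f, v_i = v_i, v_s = v_s, w_s = w_s, h = h)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all geometry parameters must be finite and > 0", call. = FALSE)
  }
  if (v_s > v_f) stop("v_s cannot exceed the final well volume v_f",
                      call. = FALSE)
  structure(list(v_f = v_f, v_i = v_i, v_s = v_s, w_s = w_s, h = h,
                 provenance = provenance),
            class = "assay_geometry")
}

#' Blank-corrected absorbance difference
#'
#' `delta_A = A_sample - A_blank`, using endpoint absorbances when kinetic
#' series are supplied.  A negative difference is allowed (it simply means
#' the sample absorbs less than the reagent blank) but raises a warning.
#'
#' @param sample,blank Either numeric endpoint absorbances or
#'   [kinetic_series()] objects (endpoints are taken with `n_last`).
#' @param n_last Trailing readings averaged for the endpoint (default 1).
#' @return delta_A in AU.
#' @export
delta_absorbance <- function(sample, blank, n_last = 1) {
  if (inherits(sample, "kinetic_series") && inherits(blank, "kinetic_series")) {
    if (sample$wavelength != blank$wavelength) {
      stop("wavelength mismatch: sample ", sample$wavelength, " nm vs blank ",
           blank$wavelength, " nm", call. = FALSE)
    }
    sample <- endpoint_absorbance(sample, n_last)
    blank <- endpoint_absorbance(blank, n_last)
  }
  da <- as.numeric(sample) - as.numeric(blank)
  if (any(da < 0)) {
    warning("negative delta_A: sample absorbance below blank", call. = FALSE)
  }
  da
}

#' Trolox equivalent antioxidant capacity
#'
#' `TEAC = delta_A * V_f * V_i / (epsilon * V_s * W_s * h)` in mol Trolox
#' equivalents per gram of sample.  The computation is exact and linear in
#' `delta_A`.
#'
#' @param delta_a Blank-corrected absorbance(s), AU.
#' @param geometry An [assay_geometry()].
#' @param epsilon Molar absorptivity of Trolox in the reagent
#'   (L mol^-1 cm^-1), > 0.
#' @return TEAC in mol/g (vectorized over `delta_a`).
#' @export
teac <- function(delta_a, geometry, epsilon) {
  stopifnot(inherits(geometry, "assay_geometry"))
  if (!is.numeric(epsilon) || epsilon <= 0) {
    stop("epsilon must be > 0", call. = FALSE)
  }
  as.numeric(delta_a) * geometry$v_f * geometry$v_i /
    (epsilon * geometry$v_s * geometry$w_s * geometry$h)
}

#' Convert TEAC between units
#'
#' @param x TEAC value(s) in mol/g.
#' @param to One of `"mol/g"`, `"mmol/g"`, `"umol/g"`.
#' @return Converted value(s).
#' @export
convert_teac <- function(x, to = c("mmol/g", "mol/g", "umol/g")) {
  to <- match.arg(to)
  x * switch(to, "mol/g" = 1, "mmol/g" = 1e3, "umol/g" = 1e6)
}

#' Summarize replicate TEAC values
#'
#' @param values Numeric vector of replicate TEACs.
#' @return List with `n`, `mean` and `sd` (sample SD with n-1 denominator;
#'   `NA` for a single replicate).
#' @export
summarize_sample <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("no replicate values", call. = FALSE)
  list(n = length(values), mean = mean(values),
       sd = if (length(values) >= 2L) stats::sd(values) else NA_real_)
}

#' Quantify TEAC for every sample on a plate
#'
#' Maps wells to samples through a layout table, computes the endpoint
#' blank mean, blank-corrects every sample well, applies the TEAC formula
#' and summarizes replicates per sample.
#'
#' @param plate A [plate_table()].
#' @param layout Data frame with columns `well` and `sample_id`; wells
#'   labelled `blank_label` are reagent blanks.  The paper's plate layout
#'   is user-supplied metadata, never inferred.
#' @param geometry An [assay_geometry()].
#' @param epsilon Molar absorptivity (L mol^-1 cm^-1).
#' @param blank_label Layout label identifying blank wells (default
#'   `"blank"`).
#' @param n_last Trailing readings averaged for endpoints (default 1).
#' @param max_delta_a Optional upper bound of the calibrated absorbance
#'   range; a warning is emitted for any delta_A above it (the TEAC value
#'   is still reported).
#' @param unit Display unit for the per-sample summary (default
#'   `"mmol/g"`); replicate values are always carried in mol/g.
#' @return An object of class `teac_result`: per-sample list with
#'   replicate delta_A and TEAC values, mean and SD in both mol/g and the
#'   display unit.
#' @export
quantify_plate <- function(plate, layout, geometry, epsilon,
                           blank_label = "blank", n_last = 1,
                           max_delta_a = NULL, unit = "mmol/g") {
  stopifnot(inherits(plate, "plate_table"))
  if (!all(c("well", "sample_id") %in% names(layout))) {
    stop("layout must have columns well, sample_id", call. = FALSE)
  }
  layout$well <- toupper(layout$well)
  unknown <- setdiff(layout$well, names(plate$series))
  if (length(unknown)) {
    stop("layout references well(s) absent from the plate: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ends <- vapply(plate$series, endpoint_absorbance, numeric(1),
                 n_last = n_last)
  blanks <- layout$well[layout$sample_id == blank_label]
  if (length(blanks) == 0L) stop("no blank wells in layout", call. = FALSE)
  blank_mean <- mean(ends[blanks])
  samples <- unique(layout$sample_id[layout$sample_id != blank_label])
  out <- lapply(samples, function(sid) {
    wells <- layout$well[layout$sample_id == sid]
    da <- ends[wells] - blank_mean
    if (any(da < 0)) {
      warning("sample ", sid, ": negative delta_A in well(s) ",
              paste(wells[da < 0], collapse = ", "), call. = FALSE)
    }
    if (!is.null(max_delta_a) && any(da > max_delta_a)) {
      warning("sample ", sid, ": delta_A above the calibrated range (",
              format(max_delta_a), " AU)", call. = FALSE)
    }
    vals <- teac(da, geometry, epsilon)
    s <- summarize_sample(vals)
    list(sample_id = sid, wells = wells,
         delta_a = unname(da), teac_mol_g = unname(vals),
         n = s$n, mean_mol_g = s$mean, sd_mol_g = s$sd,
         mean_display = convert_teac(s$mean, unit),
         sd_display = convert_teac(s$sd, unit), unit = unit)
  })
  names(out) <- samples
  structure(list(samples = out, blank_mean = blank_mean, unit = unit,
                 epsilon = epsilon, geometry = unclass(geometry)),
            class = "teac_result")
}

#' @export
print.teac_result <- function(x, ...) {
  cat("TEAC quantification (", x$unit, ")\n", sep = "")
  for (s in x$samples) {
    cat(sprintf("  %s: %.4g +/- %.2g  (n = %d)\n", s$sample_id,
                s$mean_display, s$sd_display, s$n))
  }
  invisible(x)
}
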