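# ICH-style validation of the Trolox calibration: linearity (lack-of-fit
# vs pure-error ANOVA), LOD/LOQ, back-calculated accuracy, kinetic
# precision and molar absorptivity.

#' Fit the calibration line by ordinary least squares
#'
#' Fits `y = phi * x + beta` (absorbance on concentration) and reports the
#' signed Pearson correlation of (x, y).
#'
#' @param points Data frame with columns `conc_uM` and `absorbance`
#'   (optionally `replicate`).
#' @return An object of class `calibration_fit` with elements `phi`
#'   (slope, AU/uM), `beta` (intercept, AU), `r`, `n`, `se_phi`, `se_beta`,
#'   `sigma_resid` and the underlying `lm` fit.
#' @export
fit_line <- function(points) {
  stopifnot(all(c("conc_uM", "absorbance") %in% names(points)))
  x <- as.numeric(points$conc_uM)
  y <- as.numeric(points$absorbance)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("concentrations must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(y))) stop("absorbances must be finite", call. = FALSE)
  if (length(unique(x)) < 2L) {
    stop("calibration needs at least 2 distinct concentration levels",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  # a noiseless fit is legitimate (synthetic data); its zero SEs are exact
  cf <- suppressWarnings(summary(fit)$coefficients)
  structure(
    list(phi = unname(cf["x", "Estimate"]),
         beta = unname(cf["(Intercept)", "Estimate"]),
         r = stats::cor(x, y), n = length(x),
         se_phi = unname(cf["x", "Std. Error"]),
         se_beta = unname(cf["(Intercept)", "Std. Error"]),
         sigma_resid = suppressWarnings(summary(fit)$sigma),
         lm = fit),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Calibration: y = %.3fx + %.3f   (r = %.3f, n = %d)\n",
              x$phi, x$beta, x$r, x$n))
  invisible(x)
}

#' Lack-of-fit versus pure-error ANOVA for the calibration line
#'
#' Decomposes the residual sum of squares about the fitted line into pure
#' error (replicate scatter about level means, df = n - L) and lack of fit
#' (level means about the line, df = L - 2, for L concentration levels),
#' and forms the one-sided F ratio with the lack-of-fit mean square in the
#' numerator.
#'
#' @param points Data frame with `conc_uM` and `absorbance`; every level
#'   must carry at least 2 replicates and there must be at least 3 levels.
#' @param fit A [fit_line()] result on the same data.
#' @param alpha Significance level for the critical value (default 0.05).
#' @return An object of class `lof_anova` with `ss_pure`, `ss_lof`,
#'   `df_pure`, `df_lof`, `ms_pure`, `ms_lof`, `f_exp`, `f_crit`, `p_value`,
#'   `alpha` and a per-level table (`level_table`) carrying the level means,
#'   fitted values and per-observation lack-of-fit square error
#'   `(mean - fitted)^2`.
#' @export
lack_of_fit <- function(points, fit, alpha = 0.05) {
  stopifnot(inherits(fit, "calibration_fit"))
  x <- as.numeric(points$conc_uM)
  y <- as.numeric(points$absorbance)
  levels_x <- sort(unique(x))
  L <- length(levels_x)
  if (L < 3L) stop("lack-of-fit needs at least 3 concentration levels",
                   call. = FALSE)
  n_per <- table(x)
  if (any(n_per < 2L)) {
    stop("level(s) without replication: ",
         paste(names(n_per)[n_per < 2L], collapse = ", "), call. = FALSE)
  }
  ybar <- tapply(y, x, mean)[as.character(levels_x)]
  nlev <- as.numeric(n_per[as.character(levels_x)])
  yhat <- fit$beta + fit$phi * levels_x
  ss_pure <- sum((y - stats::ave(y, x))^2)
  ss_lof <- sum(nlev * (ybar - yhat)^2)
  df_pure <- length(y) - L
  df_lof <- L - 2L
  ms_pure <- ss_pure / df_pure
  ms_lof <- ss_lof / df_lof
  f_exp <- ms_lof / ms_pure
  structure(
    list(ss_pure = ss_pure, ss_lof = ss_lof,
         df_pure = df_pure, df_lof = df_lof,
         ms_pure = ms_pure, ms_lof = ms_lof,
         f_exp = f_exp,
         f_crit = f_critical(alpha, df_lof, df_pure),
         p_value = stats::pf(f_exp, df_lof, df_pure, lower.tail = FALSE),
         alpha = alpha,
         level_table = data.frame(
           conc_uM = levels_x, n = nlev, mean = as.numeric(ybar),
           fitted = yhat, lof_sq = (as.numeric(ybar) - yhat)^2)),
    class = "lof_anova"
  )
}

#' @export
print.lof_anova <- function(x, ...) {
  cat("Lack-of-fit ANOVA\n")
  cat(sprintf("  lack-of-fit: SS %.4g on %d df (MS %.4g)\n",
              x$ss_lof, x$df_lof, x$ms_lof))
  cat(sprintf("  pure error : SS %.4g on %d df (MS %.4g)\n",
              x$ss_pure, x$df_pure, x$ms_pure))
  cat(sprintf("  F = %.4f vs F_crit(%g; %d, %d) = %.4f\n",
              x$f_exp, x$alpha, x$df_lof, x$df_pure, x$f_crit))
  invisible(x)
}

#' Upper-tail F critical value
#'
#' The (1 - alpha) quantile of the F distribution with `df1` and `df2`
#' degrees of freedom (computed through the regularized incomplete beta
#' inverse underlying [stats::qf()]); agrees with published F tables to 4
#' decimals.
#'
#' @param alpha Significance level in (0, 1).
#' @param df1,df2 Numerator / denominator degrees of freedom (>= 1).
#' @return The critical value.
#' @export
f_critical <- function(alpha, df1, df2) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  if (df1 < 1 || df2 < 1) stop("degrees of freedom must be >= 1",
                               call. = FALSE)
  stats::qf(1 - alpha, df1, df2)
}

#' Joint linearity decision
#'
#' The calibration is accepted as linear only when both conditions hold:
#' Pearson `r > r_min` and `F_experimental < F_critical` of the
#' lack-of-fit test.  Both sub-conditions are reported separately.
#'
#' @param fit A [fit_line()] result.
#' @param anova A [lack_of_fit()] result from the same data.
#' @param r_min Correlation threshold (default 0.990; applied to r itself,
#'   not r squared).
#' @return List with `linear`, `r_ok`, `f_ok` and the compared quantities.
#' @export
assess_linearity <- function(fit, anova, r_min = 0.990) {
  stopifnot(inherits(fit, "calibration_fit"), inherits(anova, "lof_anova"))
  r_ok <- fit$r > r_min
  f_ok <- anova$f_exp < anova$f_crit
  list(linear = r_ok && f_ok, r_ok = r_ok, f_ok = f_ok,
       r = fit$r, r_min = r_min, f_exp = anova$f_exp, f_crit = anova$f_crit)
}

#' Blank standard deviation
#'
#' Two estimators are exposed: `"replicates"` (sample SD of the endpoint
#' absorbances of the blank-level standards, the default) and `"residual"`
#' (residual standard deviation of the calibration line).
#'
#' @param points Calibration data frame (`conc_uM`, `absorbance`).
#' @param fit A [fit_line()] result (required for `method = "residual"`).
#' @param method `"replicates"` or `"residual"`.
#' @return sigma_blank in AU.
#' @export
estimate_sigma_blank <- function(points, fit = NULL,
                                 method = c("replicates", "residual")) {
  method <- match.arg(method)
  if (method == "replicates") {
    blanks <- points$absorbance[points$conc_uM == 0]
    if (length(blanks) < 2L) {
      stop("need >= 2 blank (0 uM) replicates for sigma_blank", call. = FALSE)
    }
    return(stats::sd(blanks))
  }
  stopifnot(inherits(fit, "calibration_fit"))
  fit$sigma_resid
}

#' Detection and quantification limits
#'
#' `LOD = 3.3 * sigma_blank / phi` and `LOQ = 10 * sigma_blank / phi`, so
#' that `LOQ / LOD = 10 / 3.3` exactly.
#'
#' @param sigma_blank Blank standard deviation (AU), >= 0.
#' @param phi Calibration slope (AU/uM), > 0.
#' @return List with `lod` and `loq` in uM.
#' @export
lod_loq <- function(sigma_blank, phi) {
  if (!is.numeric(phi) || phi <= 0) stop("slope phi must be > 0",
                                         call. = FALSE)
  if (!is.numeric(sigma_blank) || sigma_blank < 0) {
    stop("sigma_blank must be >= 0", call. = FALSE)
  }
  list(lod = 3.3 * sigma_blank / phi, loq = 10 * sigma_blank / phi)
}

#' Back-calculated accuracy of the calibration standards
#'
#' Inverts the line, `x_hat = (y - beta) / phi`, and reports the percent
#' deviation `100 * (x_hat - x) / x` for each non-blank standard.  At the
#' blank level a percent deviation is undefined; the absolute deviation
#' `x_hat` in uM is reported there instead (`accuracy_pct` is `NA`).
#'
#' @param points Calibration data frame.
#' @param fit A [fit_line()] result.
#' @return Data frame `conc_uM, absorbance, back_calc, accuracy_pct,
#'   abs_dev_uM`.
#' @export
back_calc_accuracy <- function(points, fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  x <- as.numeric(points$conc_uM)
  y <- as.numeric(points$absorbance)
  xhat <- (y - fit$beta) / fit$phi
  data.frame(conc_uM = x, absorbance = y, back_calc = xhat,
             accuracy_pct = ifelse(x > 0, 100 * (xhat - x) / x, NA_real_),
             abs_dev_uM = ifelse(x > 0, NA_real_, abs(xhat)))
}

#' Kinetic precision as per-level coefficient of variation
#'
#' Pools every replicate-by-timepoint reading within a concentration level
#' and reports `CV = 100 * sd / mean` per level.  A level with mean 0 has
#' an undefined CV and is reported as `NA`.
#'
#' @param readings Data frame with columns `level` and `absorbance`, one
#'   row per reading (all timepoints of all replicates).
#' @return Data frame `level, n, mean, sd, cv_pct`, in level order.
#' @export
precision_cv <- function(readings) {
  stopifnot(all(c("level", "absorbance") %in% names(readings)))
  lv <- readings$level
  y <- as.numeric(readings$absorbance)
  n_per <- table(lv)
  if (any(n_per < 2L)) {
    stop("level(s) with fewer than 2 readings: ",
         paste(names(n_per)[n_per < 2L], collapse = ", "), call. = FALSE)
  }
  agg <- do.call(rbind, lapply(split(y, lv), function(v) {
    data.frame(n = length(v), mean = mean(v), sd = stats::sd(v))
  }))
  lvl <- rownames(agg)
  num <- suppressWarnings(as.numeric(lvl))
  ord <- if (all(!is.na(num))) order(num) else order(lvl)
  out <- data.frame(level = lvl, agg,
                    cv_pct = ifelse(agg$mean == 0, NA_real_,
                                    100 * agg$sd / agg$mean),
                    row.names = NULL)
  out[ord, , drop = FALSE]
}

#' Molar absorptivity from the calibration slope
#'
#' By Beer-Lambert, a slope phi in AU per uM over a path length h (cm)
#' gives `epsilon = phi * 1e6 / h` in L mol^-1 cm^-1.  The standard error
#' is propagated linearly from the slope's standard error.
#'
#' @param phi Calibration slope (AU/uM).
#' @param h Optical path length in cm, > 0.
#' @param se_phi Optional standard error of the slope.
#' @return List with `epsilon` and `se` (L mol^-1 cm^-1; `se` is `NA` when
#'   `se_phi` is not supplied).
#' @export
molar_absorptivity <- function(phi, h, se_phi = NULL) {
  if (!is.numeric(h) || h <= 0) stop("path length h must be > 0",
                                     call. = FALSE)
  list(epsilon = phi * 1e6 / h,
       se = if (is.null(se_phi)) NA_real_ else se_phi * 1e6 / h)
}

#' Full calibration validation
#'
#' Runs the complete ICH-style validation: line fit, lack-of-fit ANOVA,
#' joint linearity decision, blank SD, LOD/LOQ, back-calculated accuracy,
#' molar absorptivity and (when kinetic readings are supplied) per-level
#' precision CVs.
#'
#' @param points Calibration data frame (`conc_uM`, `absorbance`).
#' @param path_length Optical path length in cm (default 0.5, the solution
#'   height of a 250 uL fill in a standard 96-well plate).
#' @param alpha Significance level for the lack-of-fit test (default 0.05).
#' @param r_min Linearity correlation threshold (default 0.990).
#' @param sigma_blank_method `"replicates"` or `"residual"` (see
#'   [estimate_sigma_blank()]).
#' @param kinetic Optional data frame of kinetic readings (`level`,
#'   `absorbance`) for [precision_cv()].
#' @param accuracy_limit_pct Acceptance bound on back-calculated accuracy
#'   (default 15).
#' @return An object of class `validation_report` (a named list suitable
#'   for [write_report()]).
#' @export
validate_calibration <- function(points, path_length = 0.5, alpha = 0.05,
                                 r_min = 0.990,
                                 sigma_blank_method = c("replicates",
                                                        "residual"),
                                 kinetic = NULL, accuracy_limit_pct = 15) {
  sigma_blank_method <- match.arg(sigma_blank_method)
  fit <- fit_line(points)
  anova <- lack_of_fit(points, fit, alpha = alpha)
  lin <- assess_linearity(fit, anova, r_min = r_min)
  sb <- estimate_sigma_blank(points, fit, method = sigma_blank_method)
  limits <- lod_loq(sb, fit$phi)
  acc <- back_calc_accuracy(points, fit)
  eps <- molar_absorptivity(fit$phi, path_length, fit$se_phi)
  cv <- if (!is.null(kinetic)) precision_cv(kinetic) else NULL
  acc_ok <- all(abs(acc$accuracy_pct) <= accuracy_limit_pct, na.rm = TRUE)
  structure(
    list(schema = "cuprackit/1",
         fit = list(phi = fit$phi, beta = fit$beta, r = fit$r, n = fit$n,
                    se_phi = fit$se_phi, se_beta = fit$se_beta),
         anova = unclass(anova)[c("ss_pure", "ss_lof", "df_pure", "df_lof",
                                  "ms_pure", "ms_lof", "f_exp", "f_crit",
                                  "p_value", "alpha")],
         linearity = lin,
         sigma_blank = sb, sigma_blank_method = sigma_blank_method,
         lod = limits$lod, loq = limits$loq,
         accuracy = acc, accuracy_limit_pct = accuracy_limit_pct,
         accuracy_ok = acc_ok,
         precision = cv,
         epsilon = eps$epsilon, epsilon_se = eps$se,
         path_length_cm = path_length),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("CUPRAC calibration validation\n")
  cat(sprintf("  model : y = %.3fx + %.3f   r = %.3f (threshold %.3f)\n",
              x$fit$phi, x$fit$beta, x$fit$r, x$linearity$r_min))
  cat(sprintf("  F_exp = %.4f  <  F_crit = %.4f  on (%d, %d) df\n",
              x$anova$f_exp, x$anova$f_crit, x$anova$df_lof, x$anova$df_pure))
  cat(sprintf("  linear: %s\n", if (x$linearity$linear) "yes" else "NO"))
  cat(sprintf("  LOD %.2f uM, LOQ %.2f uM (sigma_blank %.4f AU, %s)\n",
              x$lod, x$loq, x$sigma_blank, x$sigma_blank_method))
  cat(sprintf("  epsilon = %.3g +/- %.2g L mol^-1 cm^-1 (h = %.2f cm)\n",
              x$epsilon, x$epsilon_se, x$path_length_cm))
  amax <- max(abs(x$accuracy$accuracy_pct), na.rm = TRUE)
  cat(sprintf("  max |accuracy| %.1f%% (limit %.0f%%): %s\n", amax,
              x$accuracy_limit_pct, if (x$accuracy_ok) "ok" else "EXCEEDED"))
  if (!is.null(x$precision)) {
    cat(sprintf("  precision CV range: %.1f-%.1f%%\n",
                min(x$precision$cv_pct, na.rm = TRUE),
                max(x$precision$cv_pct, na.rm = TRUE)))
  }
  invisible(x)
}
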