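# Scheffe quadratic mixture modeling of solvent blends on the ternary
# simplex (methanol z1, ethanol z2, water z3; z1 + z2 + z3 = 1).

#' Construct and validate a solvent composition
#'
#' Compositions live on the 3-component simplex.  Inputs whose sum deviates
#' from 1 by at most `sum_tol` are renormalized to sum exactly 1 (this
#' covers designs printed with rounded fractions such as 0.33/0.33/0.33);
#' larger deviations are an error.
#'
#' @param z1,z2,z3 Volume fractions of methanol, ethanol and water.
#' @param sum_tol Tolerance on `z1 + z2 + z3` before normalization
#'   (default 0.02).
#' @return Named numeric vector `c(z1=, z2=, z3=)` summing exactly to 1.
#' @export
solvent_composition <- function(z1, z2, z3, sum_tol = 0.02) {
  z <- c(z1 = as.numeric(z1), z2 = as.numeric(z2), z3 = as.numeric(z3))
  if (any(!is.finite(z)) || any(z < 0) || any(z > 1 + sum_tol)) {
    stop("invalid composition: fractions must be finite and within [0, 1]",
         call. = FALSE)
  }
  s <- sum(z)
  if (abs(s - 1) > sum_tol) {
    stop("invalid composition: fractions sum to ", format(s),
         " (must be within ", sum_tol, " of 1)", call. = FALSE)
  }
  if (s == 0) stop("invalid composition: all fractions zero", call. = FALSE)
  z / s
}

#' Classify a composition as pure, binary or ternary
#'
#' The class is the number of components present above `zero_tol`; it
#' selects which class-average replicate standard deviation applies in the
#' signal transform and back-transform.
#'
#' @param z Composition (length-3 numeric, already normalized).
#' @param zero_tol Threshold below which a fraction counts as absent
#'   (default 1e-6; printed designs use exact zeros).
#' @return `"pure"`, `"binary"` or `"ternary"`.
#' @export
classify_composition <- function(z, zero_tol = 1e-6) {
  z <- as.numeric(z)
  stopifnot(length(z) == 3L)
  n <- sum(z > zero_tol)
  if (n == 0L) {
    stop("invalid composition: no component above zero_tol", call. = FALSE)
  }
  c("pure", "binary", "ternary")[n]
}

# Canonical key for grouping replicate rows of the same blend.
composition_key <- function(zmat) {
  apply(round(zmat, 6), 1L, paste, collapse = "/")
}

#' Build a mixture-design table from replicate signals
#'
#' @param data Data frame with columns `frac_methanol`, `frac_ethanol`,
#'   `frac_water`, `replicate`, `absorbance` (the raw signal psi, AU).
#' @param sigma_by_class Optional named vector
#'   `c(pure=, binary=, ternary=)` of class-average replicate standard
#'   deviations (AU) to use in the signal transform.  When `NULL` the
#'   values are estimated from the replicates via
#'   [compute_sigma_by_class()] (requires >= 2 replicates per blend).
#' @param sigma_digits Optional number of decimals to which estimated
#'   sigma values are rounded before use; reported solvent screens
#'   conventionally quote the class averages at 3 decimals.
#' @param zero_tol Passed to [classify_composition()].
#' @return An object of class `mixture_design` holding the validated
#'   observations, their classes and the per-class sigma map (which may be
#'   `NULL` when the design is degenerate for sigma estimation).
#' @export
mixture_design_table <- function(data, sigma_by_class = NULL,
                                 sigma_digits = NULL, zero_tol = 1e-6) {
  need <- c("frac_methanol", "frac_ethanol", "frac_water", "absorbance")
  if (!all(need %in% names(data))) {
    stop("design data must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"replicate" %in% names(data)) {
    data$replicate <- stats::ave(data$absorbance,
                                 composition_key(as.matrix(
                                   data[, need[1:3]])),
                                 FUN = seq_along)
  }
  psi <- as.numeric(data$absorbance)
  if (any(!is.finite(psi)) || any(psi < 0)) {
    stop("signals psi must be finite and non-negative", call. = FALSE)
  }
  z <- t(apply(as.matrix(data[, need[1:3]]), 1L, function(r) {
    solvent_composition(r[1], r[2], r[3])
  }))
  colnames(z) <- c("z1", "z2", "z3")
  cls <- apply(z, 1L, classify_composition, zero_tol = zero_tol)
  key <- composition_key(z)
  counts <- table(key)
  degenerate <- any(counts < 2L)
  x <- structure(
    list(z = z, psi = psi, replicate = data$replicate, class = cls,
         key = key, sigma_by_class = sigma_by_class,
         degenerate = degenerate, zero_tol = zero_tol),
    class = "mixture_design"
  )
  if (is.null(sigma_by_class)) {
    if (!degenerate) {
      sig <- suppressWarnings(compute_sigma_by_class(x))
      if (!is.null(sigma_digits)) sig <- round(sig, sigma_digits)
      if (any(sig == 0)) {
        # zero replicate scatter: transform would be degenerate
        x$degenerate <- TRUE
      } else {
        x$sigma_by_class <- sig
      }
    }
  } else {
    present <- unique(cls)
    if (!all(present %in% names(sigma_by_class)) ||
        any(sigma_by_class[present] <= 0)) {
      stop("configuration error: sigma_by_class must supply a positive ",
           "sigma for every class present (",
           paste(present, collapse = ", "), ")", call. = FALSE)
    }
  }
  x
}

#' @export
print.mixture_design <- function(x, ...) {
  cat("<mixture_design> ", length(unique(x$key)), " blend(s), ",
      length(x$psi), " observation(s)\n", sep = "")
  if (!is.null(x$sigma_by_class)) {
    cat("  sigma_by_class:",
        paste(names(x$sigma_by_class), round(x$sigma_by_class, 4),
              sep = "=", collapse = ", "), "\n")
  } else if (x$degenerate) {
    cat("  degenerate for sigma estimation (singleton blend present)\n")
  }
  invisible(x)
}

#' Class-average replicate standard deviations
#'
#' For each distinct blend the sample standard deviation (n-1 denominator)
#' of its replicate signals is computed; these are then averaged, unweighted,
#' within each composition class (pure / binary / ternary).
#'
#' @param table A [mixture_design_table()].
#' @return Named numeric vector of class sigma averages (AU).  A class in
#'   which all replicates are identical yields sigma 0 and a warning, since
#'   a zero sigma makes the transform degenerate.
#' @export
compute_sigma_by_class <- function(table) {
  stopifnot(inherits(table, "mixture_design"))
  counts <- table(table$key)
  if (any(counts < 2L)) {
    stop("cannot estimate sigma: blend(s) without replication: ",
         paste(names(counts)[counts < 2L], collapse = "; "), call. = FALSE)
  }
  per_point_sd <- tapply(table$psi, table$key, stats::sd)
  point_class <- tapply(table$class, table$key, function(v) v[1L])
  sig <- tapply(as.numeric(per_point_sd), as.character(point_class), mean)
  sig <- stats::setNames(as.numeric(sig), names(sig))
  if (any(sig == 0)) {
    warning("degenerate sigma: class(es) with zero replicate scatter: ",
            paste(names(sig)[sig == 0], collapse = ", "), call. = FALSE)
  }
  sig
}

#' Transform raw signals by the class sigma average
#'
#' The modeled response is `Phi = psi * sigma_average(class)`, i.e. each
#' raw absorbance is scaled by the average replicate standard deviation of
#' its composition class.  This weighting folds the class-dependent
#' measurement scatter into the response before the Scheffe fit.
#'
#' @param table A [mixture_design_table()].
#' @param sigma_by_class Optional override of the table's sigma map.
#' @return Data frame with columns `z1,z2,z3,class,replicate,psi,phi`.
#' @export
transform_signals <- function(table, sigma_by_class = NULL) {
  stopifnot(inherits(table, "mixture_design"))
  sig <- sigma_by_class
  if (is.null(sig)) sig <- table$sigma_by_class
  if (is.null(sig)) {
    stop("configuration error: no sigma_by_class available ",
         "(design degenerate for sigma estimation?)", call. = FALSE)
  }
  present <- unique(table$class)
  if (!all(present %in% names(sig))) {
    stop("configuration error: sigma_by_class missing class(es): ",
         paste(setdiff(present, names(sig)), collapse = ", "), call. = FALSE)
  }
  data.frame(table$z, class = table$class, replicate = table$replicate,
             psi = table$psi,
             phi = table$psi * as.numeric(sig[table$class]),
             row.names = NULL)
}

scheffe_design_matrix <- function(z) {
  z <- rbind(z)
  cbind(z1 = z[, 1], z2 = z[, 2], z3 = z[, 3],
        z12 = z[, 1] * z[, 2], z13 = z[, 1] * z[, 3],
        z23 = z[, 2] * z[, 3])
}

#' Fit the quadratic Scheffe mixture polynomial
#'
#' Ordinary least squares of the transformed signal Phi on the six canonical
#' terms `z1, z2, z3, z1*z2, z1*z3, z2*z3` with no intercept (the simplex
#' constraint makes an intercept redundant).  Linear coefficients are the
#' predicted vertex responses; interaction coefficients capture blending
#' synergy along the edges.
#'
#' @param transformed Data frame from [transform_signals()] (columns
#'   `z1,z2,z3,phi`), or any data frame with those columns.
#' @return An object of class `scheffe_fit` with elements `coefficients`
#'   (k1,k2,k3,k12,k13,k23), `se`, `residuals`, `fitted`, `df_residual`
#'   and the underlying `lm` fit.
#' @export
fit_scheffe <- function(transformed) {
  need <- c("z1", "z2", "z3", "phi")
  stopifnot(all(need %in% names(transformed)))
  X <- scheffe_design_matrix(as.matrix(transformed[, c("z1", "z2", "z3")]))
  qrX <- qr(X)
  if (qrX$rank < 6L) {
    have <- colSums(abs(X) > 1e-12) > 0
    lack <- colnames(X)[!have]
    msg <- if (length(lack)) paste0(" (no support for term(s): ",
                                    paste(lack, collapse = ", "), ")") else ""
    stop("singular design: rank ", qrX$rank, " < 6", msg,
         "; the design needs at least the 3 vertices and 3 binary blends",
         call. = FALSE)
  }
  dat <- data.frame(phi = transformed$phi, X)
  fit <- stats::lm(phi ~ 0 + z1 + z2 + z3 + z12 + z13 + z23, data = dat)
  k <- stats::coef(fit)
  names(k) <- c("k1", "k2", "k3", "k12", "k13", "k23")
  se <- rep(NA_real_, 6L)
  if (fit$df.residual > 0L) {
    se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  }
  names(se) <- names(k)
  structure(
    list(coefficients = k, se = se, residuals = unname(stats::residuals(fit)),
         fitted = unname(stats::fitted(fit)), df_residual = fit$df.residual,
         lm = fit),
    class = "scheffe_fit"
  )
}

#' @export
coef.scheffe_fit <- function(object, ...) object$coefficients

#' @export
print.scheffe_fit <- function(x, digits = 3, ...) {
  k <- round(x$coefficients, digits)
  cat("Scheffe quadratic mixture model (transformed signal Phi)\n")
  cat(sprintf("  Phi = %s z1 + %s z2 + %s z3 + %s z1z2 + %s z1z3 + %s z2z3\n",
              k[1], k[2], k[3], k[4], k[5], k[6]))
  cat("  residual df:", x$df_residual, "\n")
  invisible(x)
}

#' Predict the transformed signal Phi at compositions
#'
#' @param coeffs A [fit_scheffe()] result or a named numeric vector
#'   `c(k1,k2,k3,k12,k13,k23)`.
#' @param z A composition (length-3 vector) or a matrix with one
#'   composition per row.
#' @return Numeric vector of predicted Phi values.
#' @export
predict_phi <- function(coeffs, z) {
  k <- if (inherits(coeffs, "scheffe_fit")) coeffs$coefficients else coeffs
  stopifnot(length(k) == 6L)
  as.numeric(scheffe_design_matrix(z) %*% as.numeric(k))
}

#' Back-transform a predicted Phi to an absorbance signal
#'
#' Inverts the class-sigma transform: `psi = Phi / sigma_average(class(z))`.
#' The sigma of the composition's *own* class is used, so predicted psi is
#' discontinuous across class boundaries (edges vs interior); the optimizer
#' therefore examines edges and interior separately.
#'
#' @param phi Predicted transformed signal(s).
#' @param z Composition (length-3) or matrix of compositions matching `phi`.
#' @param sigma_by_class Named sigma map `c(pure=, binary=, ternary=)`.
#' @param zero_tol Passed to [classify_composition()].
#' @return Predicted absorbance psi (AU).
#' @export
back_transform <- function(phi, z, sigma_by_class, zero_tol = 1e-6) {
  z <- rbind(z)
  cls <- apply(z, 1L, classify_composition, zero_tol = zero_tol)
  if (!all(cls %in% names(sigma_by_class))) {
    stop("configuration error: sigma_by_class missing class(es): ",
         paste(setdiff(cls, names(sigma_by_class)), collapse = ", "),
         call. = FALSE)
  }
  sig <- as.numeric(sigma_by_class[cls])
  if (any(sig <= 0)) {
    stop("division error: sigma_average is zero for class ",
         paste(unique(cls[sig <= 0]), collapse = ", "), call. = FALSE)
  }
  as.numeric(phi) / sig
}

# Closed-form stationary points of the quadratic on each edge and in the
# interior of the simplex (candidates the lattice could straddle).
stationary_candidates <- function(k) {
  out <- list()
  edges <- list(c(1L, 2L, 4L), c(1L, 3L, 5L), c(2L, 3L, 6L))  # (i, j, kij idx)
  for (e in edges) {
    kij <- k[e[3]]
    if (abs(kij) > 1e-15) {
      ti <- (k[e[1]] - k[e[2]] + kij) / (2 * kij)
      if (ti > 0 && ti < 1) {
        z <- c(0, 0, 0)
        z[e[1]] <- ti
        z[e[2]] <- 1 - ti
        out[[length(out) + 1L]] <- z
      }
    }
  }
  # interior: grad(Phi) = lambda * 1 on z1+z2+z3 = 1
  M <- rbind(c(0, k[4], k[5], -1),
             c(k[4], 0, k[6], -1),
             c(k[5], k[6], 0, -1),
             c(1, 1, 1, 0))
  sol <- tryCatch(solve(M, c(-k[1], -k[2], -k[3], 1)), error = function(e) NULL)
  if (!is.null(sol)) {
    z <- sol[1:3]
    if (all(is.finite(z)) && all(z > 0) && all(z < 1)) {
      out[[length(out) + 1L]] <- z
    }
  }
  out
}

#' Locate the composition maximizing the predicted absorbance
#'
#' Exhaustively evaluates the back-transformed signal psi over the simplex
#' lattice of pitch `grid_step`, augmented with the closed-form stationary
#' point of Phi on each edge and in the interior, and returns the global
#' argmax.  Ties (within 1e-12 AU) are broken toward larger methanol
#' fraction, then larger water fraction.
#'
#' @param coeffs A [fit_scheffe()] result or coefficient vector.
#' @param sigma_by_class Named sigma map covering pure, binary and ternary.
#' @param grid_step Lattice pitch; must divide 1 evenly (default 0.005).
#' @param zero_tol Passed to [classify_composition()].
#' @return An object of class `optimum_result` with the winning
#'   `composition`, its `class`, `phi_pred`, `psi_pred` and `grid_step`.
#' @export
optimize_composition <- function(coeffs, sigma_by_class, grid_step = 0.005,
                                 zero_tol = 1e-6) {
  k <- if (inherits(coeffs, "scheffe_fit")) coeffs$coefficients else coeffs
  k <- as.numeric(k)
  stopifnot(length(k) == 6L)
  m <- 1 / grid_step
  if (abs(m - round(m)) > 1e-8) {
    stop("grid_step must divide 1 evenly", call. = FALSE)
  }
  need <- c("pure", "binary", "ternary")
  if (!all(need %in% names(sigma_by_class)) ||
      any(sigma_by_class[need] <= 0)) {
    stop("configuration error: sigma_by_class must supply positive sigma ",
         "for pure, binary and ternary", call. = FALSE)
  }
  m <- round(m)
  g <- expand.grid(i = 0:m, j = 0:m)
  g <- g[g$i + g$j <= m, ]
  Z <- cbind(g$i / m, g$j / m, (m - g$i - g$j) / m)
  extra <- stationary_candidates(k)
  if (length(extra)) Z <- rbind(Z, do.call(rbind, extra))
  phi <- predict_phi(k, Z)
  psi <- back_transform(phi, Z, sigma_by_class, zero_tol = zero_tol)
  best <- max(psi)
  cand <- which(psi >= best - 1e-12)
  # tie-break: larger z1, then larger z3
  cand <- cand[order(-Z[cand, 1], -Z[cand, 3])]
  i <- cand[1L]
  z <- stats::setNames(Z[i, ], c("z1", "z2", "z3"))
  structure(
    list(composition = z,
         class = classify_composition(z, zero_tol),
         phi_pred = phi[i], psi_pred = psi[i], grid_step = grid_step),
    class = "optimum_result"
  )
}

#' @export
print.optimum_result <- function(x, ...) {
  cat(sprintf(
    "Optimal solvent blend (%s): methanol %.2f / ethanol %.2f / water %.2f\n",
    x$class, x$composition[1], x$composition[2], x$composition[3]))
  cat(sprintf("  predicted signal: %.3f AU (Phi = %.4f), grid step %g\n",
              x$psi_pred, x$phi_pred, x$grid_step))
  invisible(x)
}

#' Mean signal ratios relative to a reference blend
#'
#' The mean raw signal of each distinct blend divided by the mean signal of
#' the reference blend (typically pure water, the poorest Trolox solvent).
#'
#' @param table A [mixture_design_table()].
#' @param reference Reference composition (length-3; default pure water).
#' @param digits Decimals for the reported ratio (default 2).
#' @return Data frame `z1,z2,z3,mean_psi,ratio` covering every distinct
#'   blend; the reference itself appears with ratio 1.
#' @export
signal_ratios <- function(table, reference = c(0, 0, 1), digits = 2) {
  stopifnot(inherits(table, "mixture_design"))
  ref <- solvent_composition(reference[1], reference[2], reference[3])
  refkey <- composition_key(rbind(ref))
  means <- tapply(table$psi, table$key, mean)
  if (!refkey %in% names(means)) {
    stop("reference composition not present in the design", call. = FALSE)
  }
  keys <- names(means)
  zs <- do.call(rbind, lapply(strsplit(keys, "/", fixed = TRUE), as.numeric))
  ord <- order(-zs[, 1], -zs[, 2])
  data.frame(z1 = zs[ord, 1], z2 = zs[ord, 2], z3 = zs[ord, 3],
             mean_psi = as.numeric(means[keys][ord]),
             ratio = round(as.numeric(means[keys][ord]) /
                             as.numeric(means[refkey]), digits),
             row.names = NULL)
}

#' Export a ternary prediction grid
#'
#' Produces the `(z1, z2, z3, phi_pred, psi_pred)` lattice used for
#' external ternary / contour plotting of the fitted response surface.
#'
#' @inheritParams optimize_composition
#' @return Data frame with one row per lattice composition.
#' @export
prediction_grid <- function(coeffs, sigma_by_class, grid_step = 0.01,
                            zero_tol = 1e-6) {
  k <- if (inherits(coeffs, "scheffe_fit")) coeffs$coefficients else coeffs
  m <- round(1 / grid_step)
  g <- expand.grid(i = 0:m, j = 0:m)
  g <- g[g$i + g$j <= m, ]
  Z <- cbind(g$i / m, g$j / m, (m - g$i - g$j) / m)
  phi <- predict_phi(k, Z)
  psi <- back_transform(phi, Z, sigma_by_class, zero_tol = zero_tol)
  data.frame(z1 = Z[, 1], z2 = Z[, 2], z3 = Z[, 3],
             phi_pred = phi, psi_pred = psi)
}
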