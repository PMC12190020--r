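# Between-sample comparison of TEAC values: Cochran's C variance
# homogeneity screen, one-way ANOVA, and multiple-range homogeneous
# subsets (Fisher LSD by default, Tukey HSD as an option).

# Normalize groups input to a summary data frame (label, n, mean, sd).
# Raw input: data.frame(label, value-like column). Summary input:
# data.frame(label, mean, sd [, n]); a missing n defaults to `n_default`
# and the assumption is recorded in the "n_assumed" attribute.
as_group_summary <- function(groups, n_default = 3) {
  stopifnot(is.data.frame(groups), "label" %in% names(groups))
  valcol <- intersect(c("teac", "value"), names(groups))
  if (length(valcol)) {
    v <- as.numeric(groups[[valcol[1L]]])
    spl <- split(v, groups$label)
    if (any(lengths(spl) < 2L)) {
      stop("every group needs >= 2 replicates", call. = FALSE)
    }
    out <- data.frame(label = names(spl),
                      n = lengths(spl),
                      mean = vapply(spl, mean, numeric(1)),
                      sd = vapply(spl, stats::sd, numeric(1)),
                      row.names = NULL)
    attr(out, "n_assumed") <- FALSE
    attr(out, "raw") <- spl
    return(out)
  }
  if (!all(c("mean", "sd") %in% names(groups))) {
    stop("groups must be raw (label + teac/value) or summaries ",
         "(label, mean, sd [, n])", call. = FALSE)
  }
  out <- data.frame(label = groups$label,
                    n = if ("n" %in% names(groups)) as.numeric(groups$n)
                        else rep(n_default, nrow(groups)),
                    mean = as.numeric(groups$mean),
                    sd = as.numeric(groups$sd), row.names = NULL)
  if (any(out$n < 2)) stop("every group needs n >= 2", call. = FALSE)
  attr(out, "n_assumed") <- !("n" %in% names(groups))
  out
}

#' Cochran's C test for homogeneity of variances
#'
#' `C = max(s_i^2) / sum(s_i^2)` over k groups with a common replicate
#' count n.  The critical value follows from the F quantile,
#' `C_crit = 1 / (1 + (k - 1) / F(1 - alpha/k; n - 1, (k - 1)(n - 1)))`.
#' Variances are judged homogeneous when `C <= C_crit`.
#'
#' @param variances Numeric vector of per-group variances (k >= 2).
#' @param n Common replicate count per group (the test is undefined for
#'   unequal group sizes).
#' @param alpha Significance level (default 0.05).
#' @return List with `statistic`, `critical`, `homogeneous`, `k`, `n`,
#'   `alpha`.
#' @export
cochran_c <- function(variances, n, alpha = 0.05) {
  variances <- as.numeric(variances)
  k <- length(variances)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(!is.finite(variances)) || any(variances < 0)) {
    stop("variances must be finite and >= 0", call. = FALSE)
  }
  if (length(n) != 1L || n < 2) {
    stop("Cochran's C requires a single common replicate count n >= 2 ",
         "(test undefined for unequal group sizes)", call. = FALSE)
  }
  if (sum(variances) == 0) {
    stop("all variances are zero; C undefined", call. = FALSE)
  }
  C <- max(variances) / sum(variances)
  fq <- stats::qf(1 - alpha / k, n - 1, (k - 1) * (n - 1))
  c_crit <- 1 / (1 + (k - 1) / fq)
  list(statistic = C, critical = c_crit, homogeneous = C <= c_crit,
       k = k, n = n, alpha = alpha)
}

#' One-way ANOVA from raw replicates or group summaries
#'
#' Standard between/within decomposition.  Because the decomposition
#' depends on the data only through per-group n, mean and SD, raw and
#' summary inputs give identical results:
#' `SSB = sum n_i (mean_i - grand)^2`, `SSW = sum (n_i - 1) sd_i^2`.
#'
#' @param groups Either raw data (`label` plus `teac`/`value` column) or
#'   summaries (`label`, `mean`, `sd` and optionally `n`).
#' @param n_default Replicate count assumed when summaries omit `n`
#'   (default 3); the assumption is recorded in the result.
#' @return An object of class `oneway_fit` with `f`, `p_value`, `ss_between`,
#'   `ss_within`, `df_between`, `df_within`, `ms_within` and the group
#'   `summary` table.
#' @export
oneway_f <- function(groups, n_default = 3) {
  s <- as_group_summary(groups, n_default)
  k <- nrow(s)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  N <- sum(s$n)
  grand <- sum(s$n * s$mean) / N
  ssb <- sum(s$n * (s$mean - grand)^2)
  ssw <- sum((s$n - 1) * s$sd^2)
  dfb <- k - 1L
  dfw <- N - k
  msb <- ssb / dfb
  msw <- ssw / dfw
  f <- msb / msw
  structure(
    list(f = f, p_value = stats::pf(f, dfb, dfw, lower.tail = FALSE),
         ss_between = ssb, ss_within = ssw,
         df_between = dfb, df_within = as.integer(dfw),
         ms_between = msb, ms_within = msw,
         summary = s, n_assumed = isTRUE(attr(s, "n_assumed"))),
    class = "oneway_fit"
  )
}

#' @export
print.oneway_fit <- function(x, ...) {
  p_disp <- max(x$p_value, 1e-12)  # display floor
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p %s\n",
              x$df_between, x$df_within, x$f,
              if (x$p_value < 1e-12) "< 1e-12" else sprintf("= %.4g", p_disp)))
  if (x$n_assumed) cat("  (replicate count assumed, not supplied)\n")
  invisible(x)
}

#' Multiple-range test: homogeneous subsets
#'
#' Pairwise comparisons with the pooled within-group mean square: Fisher's
#' least significant difference (default) or Tukey's HSD.  Groups are
#' merged into homogeneous subsets by transitive non-significance
#' (connected components of the non-significant-pair graph), reported in
#' increasing order of mean.
#'
#' @param groups Raw or summary groups (see [oneway_f()]).
#' @param alpha Significance level (default 0.05).
#' @param method `"lsd"` or `"tukey"`.
#' @param n_default Replicate count assumed for summary input without `n`.
#' @return List with `subsets` (list of label vectors), `pairwise` (data
#'   frame of differences, thresholds and significance), `method`, `alpha`.
#' @export
lsd_subsets <- function(groups, alpha = 0.05, method = c("lsd", "tukey"),
                        n_default = 3) {
  method <- match.arg(method)
  aov1 <- oneway_f(groups, n_default)
  s <- aov1$summary
  k <- nrow(s)
  msw <- aov1$ms_within
  dfw <- aov1$df_within
  pairs <- utils::combn(seq_len(k), 2L)
  diffs <- abs(s$mean[pairs[1L, ]] - s$mean[pairs[2L, ]])
  se <- sqrt(msw * (1 / s$n[pairs[1L, ]] + 1 / s$n[pairs[2L, ]]))
  threshold <- switch(method,
    lsd = stats::qt(1 - alpha / 2, dfw) * se,
    tukey = stats::qtukey(1 - alpha, k, dfw) * se / sqrt(2))
  sig <- diffs > threshold
  # connected components of the non-significance graph
  comp <- seq_len(k)
  for (j in seq_len(ncol(pairs))) {
    if (!sig[j]) {
      a <- comp[pairs[1L, j]]
      b <- comp[pairs[2L, j]]
      comp[comp == max(a, b)] <- min(a, b)
    }
  }
  ord <- order(s$mean)
  subset_ids <- unique(comp[ord])
  subsets <- lapply(subset_ids, function(id) s$label[comp == id])
  list(subsets = subsets,
       pairwise = data.frame(
         group1 = s$label[pairs[1L, ]], group2 = s$label[pairs[2L, ]],
         diff = diffs, threshold = threshold, significant = sig),
       method = method, alpha = alpha, anova = aov1)
}

#' Full between-sample comparison
#'
#' Runs the comparison sequence: Cochran's C homogeneity screen (when all
#' groups share a replicate count), one-way ANOVA, and the multiple-range
#' test into homogeneous subsets.
#'
#' @inheritParams lsd_subsets
#' @return An object of class `comparison_report`.
#' @export
compare_groups <- function(groups, alpha = 0.05, method = c("lsd", "tukey"),
                           n_default = 3) {
  method <- match.arg(method)
  aov1 <- oneway_f(groups, n_default)
  s <- aov1$summary
  cochran <- NULL
  if (length(unique(s$n)) == 1L) {
    cochran <- cochran_c(s$sd^2, unique(s$n), alpha)
  }
  mr <- lsd_subsets(groups, alpha, method, n_default)
  structure(
    list(schema = "cuprackit/1",
         groups = s, n_assumed = aov1$n_assumed,
         cochran = cochran, anova = unclass(aov1)[c(
           "f", "p_value", "ss_between", "ss_within", "df_between",
           "df_within", "ms_between", "ms_within")],
         subsets = mr$subsets, pairwise = mr$pairwise,
         method = method, alpha = alpha),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Between-sample comparison\n")
  if (!is.null(x$cochran)) {
    cat(sprintf("  Cochran C = %.3f (crit %.3f): variances %s\n",
                x$cochran$statistic, x$cochran$critical,
                if (x$cochran$homogeneous) "homogeneous" else "HETEROGENEOUS"))
  }
  p <- x$anova$p_value
  cat(sprintf("  ANOVA F(%d, %d) = %.3f, p %s\n", x$anova$df_between,
              x$anova$df_within, x$anova$f,
              if (p < 1e-12) "< 1e-12" else sprintf("= %.4g", p)))
  lab <- vapply(x$subsets, paste, character(1), collapse = ", ")
  cat("  homogeneous subsets (", x$method, "): ",
      paste0("{", lab, "}", collapse = " "), "\n", sep = "")
  invisible(x)
}
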