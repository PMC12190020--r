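cal <- trolox_calibration()

test_that("calibration line matches the reference fit and trivial cases", {
  fit <- fit_line(cal)
  expect_equal(round(fit$phi, 3), 0.013)
  expect_equal(round(fit$beta, 3), 0.039)
  expect_equal(round(fit$r, 3), 0.998)
  expect_equal(fit$n, 18L)

  two <- data.frame(conc_uM = c(0, 10), absorbance = c(0.1, 0.3))
  f2 <- fit_line(two)
  expect_equal(f2$r, 1)
  expect_equal(f2$phi, 0.02)

  exact <- data.frame(conc_uM = 0:5, absorbance = 0.02 * (0:5) + 0.1)
  fe <- fit_line(exact)
  expect_equal(fe$phi, 0.02, tolerance = 1e-12)
  expect_equal(fe$beta, 0.1, tolerance = 1e-12)

  expect_error(fit_line(data.frame(conc_uM = c(1, 1),
                                   absorbance = c(0.1, 0.2))), "distinct")
})

test_that("lack-of-fit ANOVA reproduces the reference decomposition", {
  fit <- fit_line(cal)
  an <- lack_of_fit(cal, fit)
  expect_identical(an$df_lof, 4L)
  expect_identical(an$df_pure, 12L)
  expect_lt(abs(an$f_exp - 3.165) / 3.165, 0.02)
  expect_true(an$f_exp < an$f_crit)

  # per-observation lack-of-fit square error at the 10 uM level
  lof10 <- an$level_table$lof_sq[an$level_table$conc_uM == 10]
  expect_equal(lof10, 4.90e-5, tolerance = 0.01)

  # bookkeeping: pure + lack-of-fit = residual SS about the line
  resid_ss <- sum(residuals(fit$lm)^2)
  expect_equal(an$ss_pure + an$ss_lof, resid_ss, tolerance = 1e-10)

  # independent route: stats::anova on nested lm models
  x <- cal$conc_uM
  oracle <- anova(lm(cal$absorbance ~ x), lm(cal$absorbance ~ factor(x)))
  expect_equal(an$ss_lof, oracle$`Sum of Sq`[2], tolerance = 1e-10)
  expect_equal(an$f_exp, (oracle$`Sum of Sq`[2] / oracle$Df[2]) /
                 (oracle$RSS[2] / oracle$Res.Df[2]), tolerance = 1e-10)
})

test_that("lack-of-fit edge cases: perfect line, unreplicated level", {
  x <- rep(c(0, 10, 20), each = 2)
  y <- 0.01 * x + 0.05 + rep(c(-0.002, 0.002), 3)  # means exactly on a line
  d <- data.frame(conc_uM = x, absorbance = y)
  an <- lack_of_fit(d, fit_line(d))
  expect_equal(an$ss_lof, 0, tolerance = 1e-20)
  expect_equal(an$f_exp, 0, tolerance = 1e-12)

  bad <- data.frame(conc_uM = c(0, 0, 10, 20, 20),
                    absorbance = c(0.1, 0.11, 0.2, 0.3, 0.31))
  expect_error(lack_of_fit(bad, fit_line(bad)), "10")
  expect_error(lack_of_fit(d[1:4, ], fit_line(d[1:4, ])), "3 concentration")
})

test_that("F critical values agree with published tables to 4 decimals", {
  table_values <- rbind(
    c(0.05, 1, 1, 161.4476), c(0.05, 1, 10, 4.9646),
    c(0.05, 2, 2, 19.0000), c(0.05, 2, 10, 4.1028),
    c(0.05, 3, 15, 3.2874), c(0.05, 4, 12, 3.2592),
    c(0.05, 5, 20, 2.7109), c(0.05, 10, 20, 2.3479),
    c(0.01, 1, 10, 10.0443), c(0.01, 4, 12, 5.4120),
    c(0.01, 5, 20, 4.1027), c(0.10, 2, 10, 2.9245))
  for (i in seq_len(nrow(table_values))) {
    v <- table_values[i, ]
    expect_equal(round(f_critical(v[1], v[2], v[3]), 4), v[4],
                 tolerance = 1e-8)
  }
  # chi-square limiting case and inverse consistency
  expect_equal(f_critical(0.05, 1, 1e6), 3.8415, tolerance = 1e-4)
  expect_equal(pf(f_critical(0.05, 4, 12), 4, 12), 0.95, tolerance = 1e-12)
  expect_error(f_critical(1.5, 4, 12), "alpha")
  expect_error(f_critical(0.05, 0, 12), "freedom")
})

test_that("linearity requires both the correlation and the F condition", {
  fit <- fit_line(cal)
  an <- lack_of_fit(cal, fit)
  lin <- assess_linearity(fit, an)
  expect_true(lin$linear && lin$r_ok && lin$f_ok)

  fake_fit <- fit
  fake_fit$r <- 0.95
  expect_false(assess_linearity(fake_fit, an)$linear)

  fake_an <- an
  fake_an$f_exp <- an$f_crit + 1
  good_r <- fit
  good_r$r <- 0.999
  expect_false(assess_linearity(good_r, fake_an)$linear)
})

test_that("LOD/LOQ follow the 3.3/10 sigma-over-slope formulas", {
  blanks <- cal$absorbance[cal$conc_uM == 0]
  sb <- estimate_sigma_blank(cal, method = "replicates")
  expect_equal(sb, sd(blanks), tolerance = 1e-12)
  fit <- fit_line(cal)
  lim <- lod_loq(sb, fit$phi)
  expect_equal(lim$lod, 3.3 * sb / fit$phi, tolerance = 1e-12)
  expect_equal(lim$lod, 0.815, tolerance = 1e-2)
  expect_equal(lim$loq / lim$lod, 10 / 3.3, tolerance = 1e-12)

  expect_equal(lod_loq(0, 0.013), list(lod = 0, loq = 0))
  l1 <- lod_loq(0.003, 0.013)
  l2 <- lod_loq(0.006, 0.013)
  expect_equal(l2$lod, 2 * l1$lod, tolerance = 1e-12)
  expect_equal(l2$loq, 2 * l1$loq, tolerance = 1e-12)
  expect_error(lod_loq(0.003, 0), "phi")

  # residual-based alternative estimator
  sbr <- estimate_sigma_blank(cal, fit, method = "residual")
  expect_equal(sbr, summary(fit$lm)$sigma, tolerance = 1e-12)
})

test_that("back-calculated accuracy matches the reference table", {
  fit <- fit_line(cal)
  acc <- back_calc_accuracy(cal, fit)
  a10 <- acc$accuracy_pct[acc$conc_uM == 10 & acc$absorbance == 0.179]
  expect_equal(a10, 7.3, tolerance = 0.01)
  a50 <- acc$accuracy_pct[acc$conc_uM == 50 & acc$absorbance == 0.723]
  expect_equal(a50, 5.0, tolerance = 0.02)
  expect_true(all(abs(acc$accuracy_pct) <= 15, na.rm = TRUE))
  # largest deviation sits at the 10 uM level
  worst <- acc$conc_uM[which.max(abs(acc$accuracy_pct))]
  expect_equal(worst, 10)
  # blank rows report absolute deviation, not a percentage
  expect_true(all(is.na(acc$accuracy_pct[acc$conc_uM == 0])))
  expect_true(all(is.finite(acc$abs_dev_uM[acc$conc_uM == 0])))

  on_line <- data.frame(conc_uM = 10, absorbance = fit$beta + 10 * fit$phi)
  expect_equal(back_calc_accuracy(on_line, fit)$accuracy_pct, 0,
               tolerance = 1e-10)
})

test_that("precision CV pools replicate-by-timepoint readings per level", {
  const <- data.frame(level = rep("a", 5), absorbance = rep(0.3, 5))
  expect_equal(precision_cv(const)$cv_pct, 0)

  two <- data.frame(level = "a", absorbance = c(0.10, 0.30))
  expect_equal(precision_cv(two)$cv_pct, 100 * sd(c(0.1, 0.3)) / 0.2,
               tolerance = 1e-12)
  expect_equal(precision_cv(two)$cv_pct, 70.7, tolerance = 1e-3)

  zero_mean <- data.frame(level = "a", absorbance = c(-1, 1))
  expect_true(is.na(precision_cv(zero_mean)$cv_pct))
  expect_error(precision_cv(data.frame(level = "a", absorbance = 1)),
               "fewer than 2")
})

test_that("molar absorptivity follows Beer-Lambert scaling", {
  e <- molar_absorptivity(0.01301, 0.5)
  expect_equal(e$epsilon, 0.01301 * 1e6 / 0.5, tolerance = 1e-12)
  expect_lt(abs(e$epsilon - 2.62e4) / 2.62e4, 0.01)
  expect_equal(molar_absorptivity(0, 0.5)$epsilon, 0)
  expect_equal(molar_absorptivity(0.013, 1)$epsilon,
               molar_absorptivity(0.013, 0.5)$epsilon / 2, tolerance = 1e-12)
  expect_error(molar_absorptivity(0.013, 0), "path length")
  ese <- molar_absorptivity(0.013, 0.5, se_phi = 0.0002)
  expect_equal(ese$se, 0.0002 * 1e6 / 0.5, tolerance = 1e-12)
})

test_that("the full validation report hangs together", {
  v <- validate_calibration(cal)
  expect_true(v$linearity$linear)
  expect_true(v$accuracy_ok)
  expect_equal(v$loq / v$lod, 10 / 3.3, tolerance = 1e-12)
  expect_equal(v$epsilon, v$fit$phi * 1e6 / 0.5, tolerance = 1e-12)
  expect_output(print(v), "linear: yes")
})
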