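test_that("compositions validate, normalize and classify", {
  expect_equal(sum(solvent_composition(0.33, 0.33, 0.33)), 1)
  expect_equal(solvent_composition(0.33, 0.33, 0.33),
               c(z1 = 1, z2 = 1, z3 = 1) / 3, tolerance = 1e-12)
  expect_error(solvent_composition(0.5, 0.5, 0.5), "sum")
  expect_error(solvent_composition(-0.1, 0.6, 0.5), "within \\[0, 1\\]")

  expect_identical(classify_composition(c(1, 0, 0)), "pure")
  expect_identical(classify_composition(c(0.64, 0, 0.36)), "binary")
  expect_identical(classify_composition(solvent_composition(0.33, 0.33, 0.33)),
                   "ternary")
  expect_error(classify_composition(c(0, 0, 0)), "invalid composition")
})

test_that("signal transform multiplies by the class sigma average", {
  screen <- trolox_solvent_screen()
  tr <- transform_signals(screen)
  # hand products of bundled values
  i_pure <- which(tr$z1 == 1 & tr$psi == 1.147)
  expect_equal(tr$phi[i_pure], 1.147 * 0.039, tolerance = 1e-12)
  i_cent <- which(tr$class == "ternary" & tr$psi == 0.933)
  expect_equal(tr$phi[i_cent], 0.933 * 0.060, tolerance = 1e-12)

  zero <- mixture_design_table(
    data.frame(frac_methanol = 1, frac_ethanol = 0, frac_water = 0,
               replicate = 1, absorbance = 0),
    sigma_by_class = screen_sigma)
  expect_equal(transform_signals(zero)$phi, 0)

  nosig <- mixture_design_table(
    data.frame(frac_methanol = 1, frac_ethanol = 0, frac_water = 0,
               replicate = 1, absorbance = 0.5))
  expect_error(transform_signals(nosig), "sigma")
})

test_that("class sigma averages match the reported values and flag degeneracy", {
  raw <- read_design_table(cuprac_example("solvent_screen.csv"))
  sig <- compute_sigma_by_class(mixture_design_table(raw))
  expect_equal(unname(sig["pure"]), 0.039, tolerance = 0.03)
  expect_lt(abs(sig[["pure"]] - 0.039), 0.001)
  expect_lt(abs(sig[["binary"]] - 0.046), 0.001)
  expect_lt(abs(sig[["ternary"]] - 0.060), 0.001)

  singleton <- mixture_design_table(
    data.frame(frac_methanol = c(1, 0), frac_ethanol = c(0, 1),
               frac_water = c(0, 0), replicate = c(1, 1),
               absorbance = c(1, 1)), sigma_by_class = screen_sigma)
  expect_error(compute_sigma_by_class(singleton), "without replication")

  const <- noiseless_design(reported_coeffs, screen_sigma)
  expect_warning(compute_sigma_by_class(mixture_design_table(
    const, sigma_by_class = screen_sigma)), "degenerate")
})

test_that("Scheffe fit is exact on saturated designs and recovers noiseless truth", {
  # 6 support points, no centroid: saturated, zero residuals
  design <- noiseless_design(reported_coeffs, screen_sigma, replicates = 1)
  design <- design[1:6, ]  # 3 vertices + 3 edge midpoints, no centroid
  tab <- mixture_design_table(design, sigma_by_class = screen_sigma)
  fit <- fit_scheffe(transform_signals(tab))
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients), unname(reported_coeffs),
               tolerance = 1e-10)

  # full 7-point noiseless design: machine-precision recovery
  tab7 <- mixture_design_table(noiseless_design(reported_coeffs, screen_sigma),
                               sigma_by_class = screen_sigma)
  fit7 <- fit_scheffe(transform_signals(tab7))
  expect_equal(unname(fit7$coefficients), unname(reported_coeffs),
               tolerance = 1e-10)
})

test_that("least squares equals the closed-form vertex/edge estimates on
           vertex + midpoint designs", {
  set.seed(7)
  for (i in 1:20) {
    k <- c(runif(3, 0, 0.1), runif(3, -0.1, 0.2))
    design <- noiseless_design(k, screen_sigma)[1:18, ]  # drop centroid
    design$absorbance <- pmax(design$absorbance +
                                rnorm(18, sd = 0.02), 0)
    tab <- mixture_design_table(design, sigma_by_class = screen_sigma)
    tr <- transform_signals(tab)
    fit <- fit_scheffe(tr)
    expect_equal(unname(fit$coefficients), unname(closed_form_scheffe(tr)),
                 tolerance = 1e-10)
  }
})

test_that("rank-deficient designs fail with an informative error", {
  design <- data.frame(frac_methanol = rep(c(1, 0), each = 2),
                       frac_ethanol = rep(c(0, 1), each = 2),
                       frac_water = 0, replicate = rep(1:2, 2),
                       absorbance = c(1.1, 1.2, 0.9, 1.0))
  tab <- mixture_design_table(design, sigma_by_class = screen_sigma)
  expect_error(fit_scheffe(transform_signals(tab)), "singular design")
  expect_error(fit_scheffe(transform_signals(tab)), "z3")
})

test_that("polynomial prediction matches hand evaluation", {
  expect_equal(predict_phi(reported_coeffs, c(1, 0, 0)), 0.046)
  centroid <- sum(reported_coeffs[1:3]) / 3 + sum(reported_coeffs[4:6]) / 9
  expect_equal(predict_phi(reported_coeffs, c(1, 1, 1) / 3), centroid,
               tolerance = 1e-12)
  expect_equal(centroid, 0.0598, tolerance = 1e-3)
  edge <- (0.046 + 0.015) / 2 + 0.112 / 4
  expect_equal(predict_phi(reported_coeffs, c(0.5, 0, 0.5)), edge,
               tolerance = 1e-12)
  expect_equal(edge, 0.0585, tolerance = 1e-4)
})

test_that("back-transform inverts the signal transform", {
  expect_equal(back_transform(0.046, c(1, 0, 0), screen_sigma),
               0.046 / 0.039)
  expect_equal(back_transform(0, c(0.5, 0, 0.5), screen_sigma), 0)
  expect_error(back_transform(0.1, c(1, 0, 0), c(pure = 0, binary = 1,
                                                 ternary = 1)), "division")
  screen <- trolox_solvent_screen()
  tr <- transform_signals(screen)
  back <- back_transform(tr$phi, as.matrix(tr[, c("z1", "z2", "z3")]),
                         screen$sigma_by_class)
  expect_equal(back, tr$psi, tolerance = 1e-12)
})

test_that("optimizer finds the methanol/water optimum and honours tie-breaks", {
  # the exact edge stationary point (0.6384 with the printed coefficients)
  # is included among candidates and rounds to the reported 0.64
  opt <- optimize_composition(reported_coeffs, screen_sigma,
                              grid_step = 0.005)
  expect_equal(round(unname(opt$composition), 2), c(0.64, 0, 0.36))
  expect_identical(opt$class, "binary")
  expect_equal(unname(opt$composition[1]),
               (0.046 - 0.015 + 0.112) / (2 * 0.112), tolerance = 1e-9)

  # no interactions: best vertex wins
  lin <- c(k1 = 3, k2 = 2, k3 = 1, k12 = 0, k13 = 0, k23 = 0)
  eqsig <- c(pure = 1, binary = 1, ternary = 1)
  opt <- optimize_composition(lin, eqsig, grid_step = 0.05)
  expect_equal(unname(opt$composition), c(1, 0, 0))

  # symmetric positive blending: interior stationary point beats the edges
  sym <- c(k1 = 1, k2 = 1, k3 = 1, k12 = 0.4, k13 = 0.4, k23 = 0.4)
  opt <- optimize_composition(sym, eqsig, grid_step = 0.05)
  expect_equal(unname(opt$composition), rep(1 / 3, 3), tolerance = 1e-9)

  # ties resolved toward larger z1, then larger z3
  flat <- c(k1 = 1, k2 = 1, k3 = 1, k12 = 0, k13 = 0, k23 = 0)
  opt <- optimize_composition(flat, eqsig, grid_step = 0.05)
  expect_equal(unname(opt$composition), c(1, 0, 0))
  two_best <- c(k1 = 0, k2 = 1, k3 = 1, k12 = 0, k13 = 0, k23 = 0)
  opt <- optimize_composition(two_best, eqsig, grid_step = 0.05)
  expect_equal(unname(opt$composition), c(0, 0, 1))

  expect_error(optimize_composition(sym, eqsig, grid_step = 0.03),
               "divide 1 evenly")
})

test_that("optimizer dominates every lattice and stationary candidate", {
  set.seed(11)
  sigs <- screen_sigma
  for (i in 1:5) {
    k <- c(runif(3, 0, 0.1), runif(3, -0.05, 0.15))
    opt <- optimize_composition(k, sigs, grid_step = 0.01)
    grid <- prediction_grid(k, sigs, grid_step = 0.01)
    expect_gte(opt$psi_pred, max(grid$psi_pred) - 1e-12)
  }
})

test_that("signal ratios against pure water reproduce the screen's pattern", {
  screen <- trolox_solvent_screen()
  r <- signal_ratios(screen)
  get <- function(z1, z2, z3) {
    r$ratio[abs(r$z1 - z1) < 1e-9 & abs(r$z2 - z2) < 1e-9 &
              abs(r$z3 - z3) < 1e-9]
  }
  expect_equal(get(1, 0, 0), 3.07)
  expect_equal(get(0.5, 0, 0.5), 3.29)
  expect_equal(get(0, 0, 1), 1.00)  # reference against itself
  expect_error(signal_ratios(screen, reference = c(0.2, 0.2, 0.6)),
               "not present")
})
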