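# Shared fixtures, built in code.

# Reference class-sigma map of the bundled solvent screen.
screen_sigma <- c(pure = 0.039, binary = 0.046, ternary = 0.060)

# Coefficients of the reported quadratic mixture model.
reported_coeffs <- c(k1 = 0.046, k2 = 0.038, k3 = 0.015,
                     k12 = 0.063, k13 = 0.112, k23 = 0.066)

# Closed-form Scheffe estimates on a vertices + edge-midpoints design:
# k_i = mean Phi at vertex i, k_ij = 4 * mean Phi at midpoint ij - 2 (k_i + k_j).
closed_form_scheffe <- function(transformed) {
  key <- apply(round(as.matrix(transformed[, c("z1", "z2", "z3")]), 6), 1,
               paste, collapse = "/")
  m <- tapply(transformed$phi, key, mean)
  v <- function(z1, z2, z3) m[[paste(round(c(z1, z2, z3), 6), collapse = "/")]]
  k1 <- v(1, 0, 0); k2 <- v(0, 1, 0); k3 <- v(0, 0, 1)
  c(k1 = k1, k2 = k2, k3 = k3,
    k12 = 4 * v(0.5, 0.5, 0) - 2 * (k1 + k2),
    k13 = 4 * v(0.5, 0, 0.5) - 2 * (k1 + k3),
    k23 = 4 * v(0, 0.5, 0.5) - 2 * (k2 + k3))
}

# Design data frame for the 7 standard simplex points with given psi means
# and no noise (n replicates each).
noiseless_design <- function(coeffs, sigma, replicates = 3) {
  Z <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5), c(1, 1, 1) / 3)
  cls <- apply(Z, 1, classify_composition)
  mu <- predict_phi(coeffs, Z) / as.numeric(sigma[cls])
  do.call(rbind, lapply(seq_len(nrow(Z)), function(i) {
    data.frame(frac_methanol = Z[i, 1], frac_ethanol = Z[i, 2],
               frac_water = Z[i, 3], replicate = seq_len(replicates),
               absorbance = mu[i])
  }))
}

# Plate CSV text for n wells x m timepoints, written to a temp file.
write_plate_fixture <- function(n_wells = 3, n_time = 31, path = tempfile(fileext = ".csv")) {
  wells <- paste0("A", seq_len(n_wells))
  df <- expand.grid(time_min = 0:(n_time - 1), well = wells)
  df$wavelength_nm <- 450
  df$absorbance <- round(0.1 + 0.01 * df$time_min, 4)
  write.csv(df[, c("well", "time_min", "wavelength_nm", "absorbance")],
            path, row.names = FALSE, quote = FALSE)
  path
}
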