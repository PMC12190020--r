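# Bundled reference datasets: the triplicate Trolox solvent screen over
# the 7-point methanol/ethanol/water simplex and the six-level Trolox
# calibration in methanol/water (0.64:0.36), shipped as plain CSVs under
# inst/extdata and loaded through the package's own readers.

#' Path to a bundled example data file
#'
#' @param file File name under `inst/extdata`; with no argument, lists the
#'   available files.
#' @return A file path (or a character vector of file names).
#' @export
cuprac_example <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "cuprackit")))
  }
  path <- system.file("extdata", file, package = "cuprackit")
  if (path == "") stop("no bundled file '", file, "'", call. = FALSE)
  path
}

#' Reference solvent-screen design table
#'
#' Triplicate Trolox absorbance signals (450 nm) for seven
#' methanol/ethanol/water blends: the three pure solvents, the three
#' binary midpoints and the centroid.  The table ships with the class
#' sigma averages reported alongside the screen (pure 0.039, binary
#' 0.046, ternary 0.060 AU, quoted at 3 decimals); these define the
#' signal transform for this dataset.  Re-estimating them from the
#' replicates via [compute_sigma_by_class()] reproduces the same values
#' up to that rounding.
#'
#' @return A [mixture_design_table()].
#' @export
trolox_solvent_screen <- function() {
  mixture_design_table(read_design_table(cuprac_example("solvent_screen.csv")),
                       sigma_by_class = c(pure = 0.039, binary = 0.046,
                                          ternary = 0.060))
}

#' Reference Trolox calibration table
#'
#' Triplicate absorbances (450 nm, methanol/water 0.64:0.36, 0.5 cm path)
#' at six equally spaced Trolox levels, 0-50 uM.
#'
#' @return Data frame in the calibration dialect.
#' @export
trolox_calibration <- function() {
  read_calibration_table(cuprac_example("trolox_calibration.csv"))
}
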