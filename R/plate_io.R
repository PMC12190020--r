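#' @keywords internal
"_PACKAGE"

# ---- internal validation helpers ------------------------------------------

#' @importFrom utils read.csv write.csv
NULL

# Read a delimited text file with explicit numeric validation.  All columns
# come in as character so that locale problems (comma decimal separators)
# are caught and reported instead of silently producing NAs.
read_checked_csv <- function(path, required, numeric_cols) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("format error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in intersect(numeric_cols, names(df))) {
    v <- df[[col]]
    if (any(grepl(",", v, fixed = TRUE))) {
      stop("format error: column '", col, "' contains a comma; ",
           "numbers must use '.' as the decimal separator", call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !(is.na(v) | v == ""))
    if (length(bad) > 0L) {
      stop("format error: column '", col, "' has non-numeric value '",
           v[bad[1L]], "' (row ", bad[1L], ")", call. = FALSE)
    }
    df[[col]] <- num
  }
  df
}

is_finite_number <- function(x) is.numeric(x) && all(is.finite(x))

# ---- kinetic series and plates --------------------------------------------

#' Kinetic absorbance series for a single well
#'
#' A time-ordered series of absorbance readings for one well of a 96-well
#' plate, as produced by a plate reader monitoring a CUPRAC reaction
#' (typically one reading per minute over 30 min at 450 nm).
#'
#' @param well_id Plate coordinate, row letter plus column number
#'   (`"A1"`..`"H12"`, case-insensitive; stored uppercase).
#' @param timepoints Numeric vector of times in minutes, non-negative and
#'   strictly increasing.
#' @param absorbances Numeric vector of absorbances (AU), same length as
#'   `timepoints`, all finite.
#' @param wavelength Detection wavelength in nm (default 450).
#' @return An object of class `kinetic_series`.
#' @export
kinetic_series <- function(well_id, timepoints, absorbances, wavelength = 450) {
  well_id <- toupper(as.character(well_id))
  if (!grepl("^[A-H](1[0-2]|[1-9])$", well_id)) {
    stop("invalid well id '", well_id, "': expected A1..H12 (8x12 plate)",
         call. = FALSE)
  }
  timepoints <- as.numeric(timepoints)
  absorbances <- as.numeric(absorbances)
  if (length(timepoints) != length(absorbances)) {
    stop("well ", well_id, ": timepoints and absorbances differ in length",
         call. = FALSE)
  }
  if (length(timepoints) == 0L) {
    stop("well ", well_id, ": empty series", call. = FALSE)
  }
  if (any(!is.finite(timepoints)) || any(timepoints < 0)) {
    stop("well ", well_id, ": timepoints must be finite and non-negative",
         call. = FALSE)
  }
  if (any(diff(timepoints) <= 0)) {
    stop("validation error: non-monotone timepoints in well ", well_id,
         call. = FALSE)
  }
  if (any(!is.finite(absorbances))) {
    stop("well ", well_id, ": absorbances must be finite", call. = FALSE)
  }
  structure(
    list(well_id = well_id, timepoints = timepoints,
         absorbances = absorbances, wavelength = wavelength),
    class = "kinetic_series"
  )
}

#' Endpoint absorbance of a kinetic series
#'
#' The single absorbance that enters calibration or quantification.  By
#' default this is the reading at the final timepoint; setting `n_last`
#' averages the last `n_last` readings instead.
#'
#' @param x A [kinetic_series()].
#' @param n_last Number of trailing readings to average (default 1).
#' @return Endpoint absorbance in AU.
#' @export
endpoint_absorbance <- function(x, n_last = 1) {
  stopifnot(inherits(x, "kinetic_series"))
  n <- length(x$absorbances)
  n_last <- as.integer(n_last)
  if (n_last < 1L || n_last > n) {
    stop("n_last must be between 1 and the series length (", n, ")",
         call. = FALSE)
  }
  mean(x$absorbances[(n - n_last + 1L):n])
}

#' Plate of kinetic series
#'
#' @param series List of [kinetic_series()] objects with unique well ids.
#' @param metadata Named list of free-form metadata (instrument, date,
#'   temperature, ...).
#' @return An object of class `plate_table`.
#' @export
plate_table <- function(series = list(), metadata = list()) {
  stopifnot(is.list(series))
  for (s in series) {
    if (!inherits(s, "kinetic_series")) {
      stop("all elements of 'series' must be kinetic_series objects",
           call. = FALSE)
    }
  }
  ids <- vapply(series, function(s) s$well_id, character(1))
  if (anyDuplicated(ids)) {
    stop("validation error: duplicated well id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(series) <- ids
  structure(list(series = series, metadata = metadata), class = "plate_table")
}

#' @export
print.plate_table <- function(x, ...) {
  cat("<plate_table> ", length(x$series), " well(s)\n", sep = "")
  invisible(x)
}

#' Read a plate file in the canonical long format
#'
#' The canonical plate dialect is a UTF-8 comma-separated file with header
#' `well,time_min,wavelength_nm,absorbance` and one row per reading
#' (the `wavelength_nm` column may be omitted, defaulting to 450 nm).
#' Row order in the file is irrelevant: readings are sorted by time within
#' each well.
#'
#' @param path Path to the CSV file.
#' @return A [plate_table()].
#' @export
read_plate <- function(path) {
  df <- read_checked_csv(path,
                         required = c("well", "time_min", "absorbance"),
                         numeric_cols = c("time_min", "wavelength_nm",
                                          "absorbance"))
  if (nrow(df) == 0L) {
    return(plate_table(list()))
  }
  if (!"wavelength_nm" %in% names(df)) df$wavelength_nm <- 450
  df$well <- toupper(df$well)
  key <- paste(df$well, df$time_min)
  if (anyDuplicated(key)) {
    dup <- df$well[duplicated(key)][1L]
    stop("validation error: duplicated (well, time) reading in well ", dup,
         call. = FALSE)
  }
  series <- lapply(split(df, df$well), function(d) {
    d <- d[order(d$time_min), , drop = FALSE]
    wl <- unique(d$wavelength_nm)
    if (length(wl) != 1L) {
      stop("validation error: multiple wavelengths in well ", d$well[1L],
           call. = FALSE)
    }
    kinetic_series(d$well[1L], d$time_min, d$absorbance, wl)
  })
  plate_table(unname(series))
}

#' Write a plate to the canonical long format
#'
#' @param plate A [plate_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate <- function(plate, path) {
  stopifnot(inherits(plate, "plate_table"))
  rows <- lapply(plate$series, function(s) {
    data.frame(well = s$well_id, time_min = s$timepoints,
               wavelength_nm = s$wavelength, absorbance = s$absorbances)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df)) {
    df <- data.frame(well = character(), time_min = numeric(),
                     wavelength_nm = numeric(), absorbance = numeric())
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- design / calibration / group tables ----------------------------------

#' Read a mixture-design table
#'
#' Dialect: `frac_methanol,frac_ethanol,frac_water,replicate,absorbance`,
#' one row per replicate measurement of a solvent blend.
#'
#' @param path Path to the CSV file.
#' @return A validated data frame.
#' @export
read_design_table <- function(path) {
  cols <- c("frac_methanol", "frac_ethanol", "frac_water", "replicate",
            "absorbance")
  read_checked_csv(path, required = cols, numeric_cols = cols)
}

#' Write a mixture-design table
#' @param design Data frame in the design dialect.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_table <- function(design, path) {
  cols <- c("frac_methanol", "frac_ethanol", "frac_water", "replicate",
            "absorbance")
  stopifnot(all(cols %in% names(design)))
  utils::write.csv(design[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a calibration table
#'
#' Dialect: `conc_uM,replicate,absorbance`, one row per replicate standard.
#'
#' @param path Path to the CSV file.
#' @return A validated data frame.
#' @export
read_calibration_table <- function(path) {
  cols <- c("conc_uM", "replicate", "absorbance")
  read_checked_csv(path, required = cols, numeric_cols = cols)
}

#' Write a calibration table
#' @param cal Data frame in the calibration dialect.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_table <- function(cal, path) {
  cols <- c("conc_uM", "replicate", "absorbance")
  stopifnot(all(cols %in% names(cal)))
  utils::write.csv(cal[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a groups table for between-sample comparison
#'
#' Two dialects are accepted: raw replicates (`label,replicate,teac`) or
#' per-group summaries (`label,n,mean,sd`).
#'
#' @param path Path to the CSV file.
#' @return A validated data frame; attribute `"dialect"` records which form
#'   was read (`"raw"` or `"summary"`).
#' @export
read_groups_table <- function(path) {
  probe <- utils::read.csv(path, colClasses = "character", nrows = 1L)
  if (all(c("label", "replicate", "teac") %in% names(probe))) {
    out <- read_checked_csv(path, required = c("label", "replicate", "teac"),
                            numeric_cols = c("replicate", "teac"))
    attr(out, "dialect") <- "raw"
  } else if (all(c("label", "n", "mean", "sd") %in% names(probe))) {
    out <- read_checked_csv(path, required = c("label", "n", "mean", "sd"),
                            numeric_cols = c("n", "mean", "sd"))
    attr(out, "dialect") <- "summary"
  } else {
    stop("format error: groups file must have columns label,replicate,teac ",
         "or label,n,mean,sd", call. = FALSE)
  }
  out
}

# ---- JSON reports ----------------------------------------------------------

# Strip classes and reject non-finite numbers (NaN/Inf; NA is allowed and
# serialized as null) before serialization.
prepare_report_node <- function(x, where = "report") {
  if (is.data.frame(x)) {
    for (col in names(x)) prepare_report_node(x[[col]],
                                              paste0(where, "$", col))
    return(x)
  }
  if (is.list(x)) {
    nm <- names(x)
    out <- lapply(seq_along(x), function(i) {
      lab <- if (!is.null(nm) && nzchar(nm[i])) paste0(where, "$", nm[i])
             else where
      prepare_report_node(x[[i]], lab)
    })
    names(out) <- nm
    return(out)
  }
  if (is.numeric(x) && any(is.nan(x) | is.infinite(x))) {
    stop("refusing to write non-finite value in ", where, call. = FALSE)
  }
  x
}

#' Write a result object as a JSON report
#'
#' Reports carry a `schema` field (`"cuprackit/1"`) and round-trip through
#' [read_report()] at full double precision.  Non-finite values are refused.
#'
#' @param report A named list (or classed result object) to serialize.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (!is.list(report)) stop("report must be a list", call. = FALSE)
  body <- prepare_report_node(report)
  if (is.null(body$schema)) body <- c(list(schema = "cuprackit/1"), body)
  ok <- tryCatch({
    jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null", pretty = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error writing report: ", conditionMessage(ok),
                        call. = FALSE)
  invisible(path)
}

#' Read a JSON report written by [write_report()]
#' @param path Path to the JSON file.
#' @return The deserialized list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
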