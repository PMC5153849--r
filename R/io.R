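# Readers and writers for the package's plain-text formats: tidy plate CSV,
# dilution CSV, counts CSV, calibration JSON and instrument/scatterer config
# JSON. All writers are deterministic (fixed column and row order, UTF-8,
# LF line endings, >= 9 significant digits) so seeded pipelines are
# byte-stable.

writeLinesLF <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
}

checkColumns <- function(d, need, path) {
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
}

#' Read a tidy plate-reader CSV
#'
#' Expected columns: `well`, `time_s`, `od` (header required; extra columns
#' are preserved). Duplicate `(well, time_s)` pairs and negative times are
#' rejected with the offending line numbers.
#'
#' @param path file path.
#' @return data.frame sorted by well then time, with any extra columns kept.
#' @export
readPlateCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- read.csv(path, stringsAsFactors = FALSE)
  checkColumns(d, c("well", "time_s", "od"), path)
  d$time_s <- as.numeric(d$time_s)
  d$od <- as.numeric(d$od)
  bad <- which(!is.finite(d$time_s) | d$time_s < 0 | !is.finite(d$od))
  if (length(bad))
    stop("malformed rows (non-numeric or negative time/od) at data line(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  key <- paste(d$well, d$time_s)
  if (anyDuplicated(key))
    stop("duplicate (well, time_s) pairs at data line(s): ",
         paste(utils::head(which(duplicated(key)), 10), collapse = ", "),
         call. = FALSE)
  d[order(d$well, d$time_s), , drop = FALSE]
}

#' Write a tidy plate-reader CSV
#'
#' Deterministic output: rows ordered by well then time, numeric columns at
#' nine significant digits, LF endings.
#'
#' @param table data.frame with columns `well`, `time_s`, `od`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePlateCsv <- function(table, path) {
  checkColumns(table, c("well", "time_s", "od"), "(in-memory table)")
  d <- table[order(table$well, table$time_s), c("well", "time_s", "od"),
             drop = FALSE]
  lines <- c("well,time_s,od",
             if (nrow(d)) paste(d$well, fmtNum(d$time_s), fmtNum(d$od),
                                sep = ","))
  writeLinesLF(lines, path)
  invisible(path)
}

#' Convert a GrowthCurve to/from the tidy plate table
#'
#' @param curve a [GrowthCurve-class].
#' @return `plateTable`: tidy data.frame (`well`, `time_s`, `od`);
#'   `plateToGrowthCurve`: a [GrowthCurve-class] built from such a table.
#' @export
plateTable <- function(curve) {
  stopifnot(is(curve, "GrowthCurve"))
  od <- odMatrix(curve)
  data.frame(well = rep(colnames(od), each = nrow(od)),
             time_s = rep(timePoints(curve), ncol(od)),
             od = as.vector(od))
}

#' @rdname plateTable
#' @param table tidy data.frame with columns `well`, `time_s`, `od`; every
#'   well must share the same time grid.
#' @export
plateToGrowthCurve <- function(table) {
  wells <- sort(unique(table$well))
  times <- sort(unique(table$time_s))
  od <- matrix(NA_real_, length(times), length(wells),
               dimnames = list(NULL, wells))
  for (w in wells) {
    sub <- table[table$well == w, ]
    if (!identical(sort(sub$time_s), times))
      stop("well '", w, "' does not share the common time grid",
           call. = FALSE)
    od[, w] <- sub$od[order(sub$time_s)]
  }
  GrowthCurve(times, od, well = wells)
}

#' Read / write a dilution-series CSV
#'
#' Columns: `concentration_per_ml`, `od`, `replicate_id`.
#'
#' @param path file path.
#' @param instrument_id instrument label for the returned series.
#' @return `readDilutionCsv`: a [DilutionSeries-class].
#' @export
readDilutionCsv <- function(path, instrument_id = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- read.csv(path, stringsAsFactors = FALSE)
  checkColumns(d, c("concentration_per_ml", "od", "replicate_id"), path)
  DilutionSeries(d$concentration_per_ml, d$od, d$replicate_id,
                 instrument_id = instrument_id)
}

#' @rdname readDilutionCsv
#' @param series a [DilutionSeries-class].
#' @export
writeDilutionCsv <- function(series, path) {
  stopifnot(is(series, "DilutionSeries"))
  d <- series@data
  lines <- c("concentration_per_ml,od,replicate_id",
             if (nrow(d)) paste(fmtNum(d$concentration_per_ml), fmtNum(d$od),
                                d$replicate_id, sep = ","))
  writeLinesLF(lines, path)
  invisible(path)
}

#' Read / write a field-of-view counts CSV
#'
#' Columns: `field_id`, `count`.
#'
#' @param path file path.
#' @return `readCountsCsv`: data.frame with `field_id`, `count`.
#' @export
readCountsCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- read.csv(path, stringsAsFactors = FALSE)
  checkColumns(d, c("field_id", "count"), path)
  if (any(d$count < 0) || any(d$count != round(d$count)))
    stop("counts must be non-negative integers", call. = FALSE)
  d
}

#' @rdname readCountsCsv
#' @param counts integer vector of per-field counts.
#' @export
writeCountsCsv <- function(counts, path) {
  lines <- c("field_id,count",
             if (length(counts)) paste(paste0("f", seq_along(counts)),
                                       as.integer(counts), sep = ","))
  writeLinesLF(lines, path)
  invisible(path)
}

CALIBRATION_SCHEMA_VERSION <- 1L

#' Write / read a calibration-curve JSON artifact
#'
#' The artifact is schema-versioned; readers reject files with an unknown
#' major schema version.
#'
#' @param curve a [CalibrationCurve-class].
#' @param path file path.
#' @return `writeCalibrationJson`: `path` invisibly; `readCalibrationJson`:
#'   a [CalibrationCurve-class].
#' @export
writeCalibrationJson <- function(curve, path) {
  stopifnot(is(curve, "CalibrationCurve"))
  sc <- curve@scatterer
  obj <- list(
    schema_version = CALIBRATION_SCHEMA_VERSION,
    coefficients = unname(curve@coefficients),
    od_valid_range = curve@od_valid_range,
    c_valid_range = curve@c_valid_range,
    scatterer = if (is.null(sc)) NULL else
      list(diameter_um = sc@diameter, n_particle = sc@n_particle,
           size_cv = sc@size_cv),
    instrument_id = curve@instrument_id,
    date = curve@date,
    fit = list(method = curve@fit$method, tuning = curve@fit$tuning,
               rmse = curve@rmse, n_points = curve@fit$n_points,
               n_trimmed = curve@fit$n_trimmed,
               iterations = curve@fit$iterations))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  writeLinesLF(json, path)
  invisible(path)
}

#' @rdname writeCalibrationJson
#' @export
readCalibrationJson <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::fromJSON(path)
  ver <- obj$schema_version %||% 0L
  if (floor(ver) != CALIBRATION_SCHEMA_VERSION)
    stop("unsupported calibration schema version ", ver, " (supported: ",
         CALIBRATION_SCHEMA_VERSION, ")", call. = FALSE)
  sc <- NULL
  if (!is.null(obj$scatterer))
    sc <- Scatterer(obj$scatterer$diameter_um, obj$scatterer$n_particle,
                    obj$scatterer$size_cv %||% 0)
  p <- as.numeric(obj$coefficients)
  new("CalibrationCurve",
      coefficients = setNames(p, paste0("p", seq_along(p) - 1)),
      od_valid_range = as.numeric(obj$od_valid_range),
      c_valid_range = as.numeric(obj$c_valid_range),
      weights = numeric(), rmse = as.numeric(obj$fit$rmse %||% NA_real_),
      fit = list(method = obj$fit$method %||% "unknown",
                 tuning = obj$fit$tuning %||% NA_real_,
                 iterations = obj$fit$iterations %||% NA_integer_,
                 converged = TRUE,
                 n_points = obj$fit$n_points %||% NA_integer_,
                 n_trimmed = obj$fit$n_trimmed %||% 0L),
      scatterer = sc, instrument_id = obj$instrument_id %||% "unknown",
      date = obj$date %||% "")
}

#' Read an instrument configuration JSON
#'
#' Expected fields: `instrument_id`, `path_length_cm`, `volume_correction`
#' (map of fill volume in ul to factor), `od_saturation`,
#' `single_scatter_threshold`.
#'
#' @param path file path.
#' @return list with `instrument_id`, a [PathConfig-class] in `$path`,
#'   `od_saturation` and `single_scatter_threshold`.
#' @export
readInstrumentConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::fromJSON(path)
  vc <- unlist(obj$volume_correction %||% list())
  pc <- PathConfig(path_length_cm = obj$path_length_cm %||% 1,
                   volume_correction = if (length(vc)) vc else
                     c("300" = 1.0560, "200" = 1.5848, "100" = 6.3694))
  list(instrument_id = obj$instrument_id %||% "unknown", path = pc,
       od_saturation = obj$od_saturation %||% 3.5,
       single_scatter_threshold = obj$single_scatter_threshold %||% 0.2)
}

#' Read a scatterer/context/geometry configuration JSON
#'
#' Expected blocks: `scatterer` (`diameter_um`, `n_particle`, `size_cv`),
#' `context` (`wavelength_nm`, `n_medium`), optional `geometry`
#' (`aperture_radius_mm`, `detector_distance_mm`).
#'
#' @param path file path.
#' @return list with `scatterer`, `context` and `geometry` (possibly `NULL`).
#' @export
readScatteringConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$scatterer) || is.null(obj$context))
    stop("config must contain 'scatterer' and 'context' blocks",
         call. = FALSE)
  geometry <- NULL
  if (!is.null(obj$geometry))
    geometry <- DetectorGeometry(obj$geometry$aperture_radius_mm,
                                 obj$geometry$detector_distance_mm)
  list(scatterer = Scatterer(obj$scatterer$diameter_um,
                             obj$scatterer$n_particle,
                             obj$scatterer$size_cv %||% 0),
       context = OpticalContext(obj$context$wavelength_nm %||% 600,
                                obj$context$n_medium %||% 1.333),
       geometry = geometry)
}
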