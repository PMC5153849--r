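#' @import methods
#' @importFrom stats coef lm mad median anova approx predict rnorm rpois sd setNames quantile
#' @importFrom utils read.csv modifyList
NULL

# ---- single-particle optics -------------------------------------------------

#' Scatterer: a (spherical-equivalent) particle population
#'
#' Describes the particles responsible for turbidity: polystyrene calibration
#' beads or microbial cells mapped to equivalent-volume spheres. `size_cv` is
#' the coefficient of variation of the diameter; when it is positive,
#' cross-sections are averaged over a lognormal diameter distribution.
#'
#' @slot diameter numeric(1), sphere diameter in micrometres (> 0).
#' @slot n_particle numeric(1), real refractive index of the particle (>= 1).
#' @slot size_cv numeric(1), coefficient of variation of diameter (>= 0).
#' @export
setClass("Scatterer",
  representation(diameter = "numeric", n_particle = "numeric",
                 size_cv = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@diameter) != 1 || !is.finite(object@diameter) ||
        object@diameter <= 0)
      msg <- c(msg, "'diameter' must be a single positive number (um)")
    if (length(object@n_particle) != 1 || !is.finite(object@n_particle) ||
        object@n_particle < 1)
      msg <- c(msg, "'n_particle' must be a single number >= 1")
    if (length(object@size_cv) != 1 || !is.finite(object@size_cv) ||
        object@size_cv < 0)
      msg <- c(msg, "'size_cv' must be a single number >= 0")
    if (length(msg)) msg else TRUE
  })

#' @param diameter sphere diameter in micrometres.
#' @param n_particle real refractive index of the particle.
#' @param size_cv coefficient of variation of the diameter (default 0,
#'   monodisperse).
#' @return A `Scatterer` object.
#' @examples
#' Scatterer(0.96, 1.59)            # a polystyrene calibration bead
#' Scatterer(1.0, 1.40, size_cv = 0.1)  # an E. coli-like equivalent sphere
#' @rdname Scatterer-class
#' @export
Scatterer <- function(diameter, n_particle, size_cv = 0) {
  new("Scatterer", diameter = as.numeric(diameter),
      n_particle = as.numeric(n_particle), size_cv = as.numeric(size_cv))
}

#' OpticalContext: wavelength and suspending medium
#'
#' @slot wavelength_nm numeric(1), vacuum wavelength in nanometres (> 0).
#' @slot n_medium numeric(1), refractive index of the medium (>= 1).
#' @export
setClass("OpticalContext",
  representation(wavelength_nm = "numeric", n_medium = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@wavelength_nm) != 1 || !is.finite(object@wavelength_nm) ||
        object@wavelength_nm <= 0)
      msg <- c(msg, "'wavelength_nm' must be a single positive number")
    if (length(object@n_medium) != 1 || !is.finite(object@n_medium) ||
        object@n_medium < 1)
      msg <- c(msg, "'n_medium' must be a single number >= 1")
    if (length(msg)) msg else TRUE
  })

#' @param wavelength_nm vacuum wavelength in nanometres (default 600, the
#'   standard OD600 setting).
#' @param n_medium medium refractive index (default 1.333, water).
#' @return An `OpticalContext` object.
#' @rdname OpticalContext-class
#' @export
OpticalContext <- function(wavelength_nm = 600, n_medium = 1.333) {
  new("OpticalContext", wavelength_nm = as.numeric(wavelength_nm),
      n_medium = as.numeric(n_medium))
}

#' DetectorGeometry: aperture radius and detector distance
#'
#' Forward-scattered light within the acceptance half-angle
#' `atan(aperture_radius / detector_distance)` reaches the detector and is
#' wrongly counted as transmitted; this geometry drives the instrument-specific
#' part of the turbidity signal.
#'
#' @slot aperture_radius numeric(1), aperture radius in millimetres (> 0).
#' @slot detector_distance numeric(1), sample-to-detector distance in
#'   millimetres (> 0).
#' @export
setClass("DetectorGeometry",
  representation(aperture_radius = "numeric", detector_distance = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@aperture_radius) != 1 ||
        !is.finite(object@aperture_radius) || object@aperture_radius <= 0)
      msg <- c(msg, "'aperture_radius' must be a single positive number (mm)")
    if (length(object@detector_distance) != 1 ||
        !is.finite(object@detector_distance) || object@detector_distance <= 0)
      msg <- c(msg, "'detector_distance' must be a single positive number (mm)")
    if (!length(msg)) {
      th <- atan(object@aperture_radius / object@detector_distance)
      if (!(th > 0 && th < pi / 2))
        msg <- c(msg, "acceptance half-angle must lie in (0, pi/2)")
    }
    if (length(msg)) msg else TRUE
  })

#' @param aperture_radius aperture radius (mm).
#' @param detector_distance sample-to-detector distance (mm).
#' @return A `DetectorGeometry` object.
#' @rdname DetectorGeometry-class
#' @export
DetectorGeometry <- function(aperture_radius, detector_distance) {
  new("DetectorGeometry", aperture_radius = as.numeric(aperture_radius),
      detector_distance = as.numeric(detector_distance))
}

#' ScatteringResult: extinction/scattering efficiencies and cross-section
#'
#' @slot q_ext numeric(1), extinction efficiency (>= 0).
#' @slot q_sca numeric(1), scattering efficiency (>= 0).
#' @slot sigma_ext numeric(1), extinction cross-section in cm^2, or `NA` when
#'   the result was computed from a bare size parameter with no physical
#'   diameter attached.
#' @export
setClass("ScatteringResult",
  representation(q_ext = "numeric", q_sca = "numeric", sigma_ext = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.finite(object@q_ext) || object@q_ext < 0)
      msg <- c(msg, "'q_ext' must be finite and >= 0")
    if (!is.finite(object@q_sca) || object@q_sca < 0)
      msg <- c(msg, "'q_sca' must be finite and >= 0")
    if (!is.na(object@sigma_ext) && object@sigma_ext < 0)
      msg <- c(msg, "'sigma_ext' must be >= 0")
    if (length(msg)) msg else TRUE
  })

ScatteringResult <- function(q_ext, q_sca, sigma_ext = NA_real_) {
  new("ScatteringResult", q_ext = as.numeric(q_ext), q_sca = as.numeric(q_sca),
      sigma_ext = as.numeric(sigma_ext))
}

setClassUnion("ScattererOrNULL", c("Scatterer", "NULL"))
setClassUnion("DetectorGeometryOrNULL", c("DetectorGeometry", "NULL"))

# ---- forward model ----------------------------------------------------------

#' SuspensionState: particle concentration in an optical context
#'
#' @slot concentration numeric(1), particles per millilitre (>= 0).
#' @slot scatterer a [Scatterer-class].
#' @slot context an [OpticalContext-class].
#' @export
setClass("SuspensionState",
  representation(concentration = "numeric", scatterer = "Scatterer",
                 context = "OpticalContext"),
  validity = function(object) {
    if (length(object@concentration) != 1 || !is.finite(object@concentration) ||
        object@concentration < 0)
      "'concentration' must be a single number >= 0 (per ml)" else TRUE
  })

#' @param concentration particle concentration (ml^-1).
#' @param scatterer a [Scatterer-class].
#' @param context an [OpticalContext-class].
#' @return A `SuspensionState` object.
#' @rdname SuspensionState-class
#' @export
SuspensionState <- function(concentration, scatterer,
                            context = OpticalContext()) {
  new("SuspensionState", concentration = as.numeric(concentration),
      scatterer = scatterer, context = context)
}

#' PathConfig: optical path length and fill-volume correction table
#'
#' In microplates the optical path runs vertically through the liquid column,
#' so the effective path length depends on the fill volume. Readings taken at a
#' given fill volume are rescaled to the 1 cm-equivalent scale by the
#' instrument-specific multiplicative factors stored here (names are fill
#' volumes in microlitres).
#'
#' @slot path_length_cm numeric(1), optical path length in cm (> 0).
#' @slot volume_correction named numeric, fill volume (ul, as names) to
#'   multiplicative OD factor (> 0).
#' @export
setClass("PathConfig",
  representation(path_length_cm = "numeric", volume_correction = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@path_length_cm) != 1 ||
        !is.finite(object@path_length_cm) || object@path_length_cm <= 0)
      msg <- c(msg, "'path_length_cm' must be a single positive number")
    vc <- object@volume_correction
    if (length(vc)) {
      if (is.null(names(vc)) || any(!nzchar(names(vc))))
        msg <- c(msg, "'volume_correction' must be named by fill volume (ul)")
      if (any(!is.finite(vc)) || any(vc <= 0))
        msg <- c(msg, "all volume-correction factors must be positive")
    }
    if (length(msg)) msg else TRUE
  })

#' @param path_length_cm optical path length in cm (default 1).
#' @param volume_correction named numeric vector of OD factors keyed by fill
#'   volume in microlitres. Defaults to the BMG plate-reader table:
#'   1.0560 (300 ul), 1.5848 (200 ul), 6.3694 (100 ul).
#' @return A `PathConfig` object.
#' @rdname PathConfig-class
#' @export
PathConfig <- function(path_length_cm = 1,
                       volume_correction = c("300" = 1.0560, "200" = 1.5848,
                                             "100" = 6.3694)) {
  new("PathConfig", path_length_cm = as.numeric(path_length_cm),
      volume_correction = volume_correction)
}

#' MultipleScattering: quadratic turbidity-correction parameters
#'
#' At densities beyond the single-scattering regime the OD bends away from the
#' Beer-Lambert line; the bend is modelled as a parabola in the decadic
#' turbidity, `OD = tau - q * tau^2`, valid on the monotone branch
#' `tau < 1/(2q)`. `q = 0` recovers Beer-Lambert exactly.
#'
#' @slot quad_coeff numeric(1), the dimensionless quadratic coefficient
#'   q (>= 0), fit per instrument/scatterer.
#' @export
setClass("MultipleScattering",
  representation(quad_coeff = "numeric"),
  validity = function(object) {
    if (length(object@quad_coeff) != 1 || !is.finite(object@quad_coeff) ||
        object@quad_coeff < 0)
      "'quad_coeff' must be a single number >= 0" else TRUE
  })

#' @param quad_coeff quadratic turbidity coefficient q (default 0.1).
#' @return A `MultipleScattering` object.
#' @rdname MultipleScattering-class
#' @export
MultipleScattering <- function(quad_coeff = 0.1) {
  new("MultipleScattering", quad_coeff = as.numeric(quad_coeff))
}

# ---- calibration ------------------------------------------------------------

#' DilutionSeries: paired known concentrations and OD readings
#'
#' One row per individual OD reading; replicate readings at the same known
#' concentration share a `concentration_per_ml` value and carry distinct
#' `replicate_id`s. Synthetic series keep their generating ground truth in the
#' `truth` slot.
#'
#' @slot data data.frame with columns `concentration_per_ml`, `od`,
#'   `replicate_id`.
#' @slot scatterer the [Scatterer-class] measured, or `NULL` if unknown.
#' @slot instrument_id character(1) instrument label.
#' @slot truth list of ground-truth generator parameters (empty for real data).
#' @export
setClass("DilutionSeries",
  representation(data = "data.frame", scatterer = "ScattererOrNULL",
                 instrument_id = "character", truth = "list"),
  validity = function(object) {
    d <- object@data
    need <- c("concentration_per_ml", "od", "replicate_id")
    if (!all(need %in% names(d)))
      return(paste("data must have columns", paste(need, collapse = ", ")))
    msg <- character()
    if (any(!is.finite(d$concentration_per_ml)) ||
        any(d$concentration_per_ml < 0))
      msg <- c(msg, "concentrations must be finite and >= 0")
    if (any(!is.finite(d$od)))
      msg <- c(msg, "OD readings must be finite")
    if (length(msg)) msg else TRUE
  })

#' @param concentration known concentrations (ml^-1), one per reading.
#' @param od OD readings, same length.
#' @param replicate_id replicate labels, recycled if length 1.
#' @param scatterer optional [Scatterer-class] metadata.
#' @param instrument_id instrument label (default `"unknown"`).
#' @param truth optional list of ground-truth parameters for synthetic series.
#' @return A `DilutionSeries` object, rows sorted by concentration.
#' @rdname DilutionSeries-class
#' @export
DilutionSeries <- function(concentration, od, replicate_id = "r1",
                           scatterer = NULL, instrument_id = "unknown",
                           truth = list()) {
  d <- data.frame(concentration_per_ml = as.numeric(concentration),
                  od = as.numeric(od),
                  replicate_id = as.character(replicate_id))
  d <- d[order(d$concentration_per_ml, d$replicate_id), , drop = FALSE]
  rownames(d) <- NULL
  new("DilutionSeries", data = d, scatterer = scatterer,
      instrument_id = instrument_id, truth = truth)
}

#' CalibrationCurve: fitted OD-vs-concentration polynomial
#'
#' Stores `OD(C) = p0 + p1*C + p2*C^2 (+ ...)` together with the OD and
#' concentration ranges over which the fit is supported, robust-fit
#' diagnostics, and provenance. Inversion refuses to leave `od_valid_range`
#' unless extrapolation is explicitly requested.
#'
#' @slot coefficients numeric, polynomial coefficients p0..pd (C in ml^-1).
#' @slot od_valid_range numeric(2), OD span of the fitted data.
#' @slot c_valid_range numeric(2), concentration span of the fitted data.
#' @slot weights numeric, final robust weights (one per fitted reading).
#' @slot rmse numeric(1), root-mean-square residual of the fit.
#' @slot fit list: method, tuning constant, iterations, converged flag,
#'   n_points, n_trimmed.
#' @slot scatterer the [Scatterer-class] the curve was measured on, or `NULL`.
#' @slot instrument_id character(1).
#' @slot date character(1), ISO date of fitting.
#' @export
setClass("CalibrationCurve",
  representation(coefficients = "numeric", od_valid_range = "numeric",
                 c_valid_range = "numeric", weights = "numeric",
                 rmse = "numeric", fit = "list",
                 scatterer = "ScattererOrNULL", instrument_id = "character",
                 date = "character"),
  validity = function(object) {
    p <- object@coefficients
    msg <- character()
    if (length(p) < 2) msg <- c(msg, "need at least linear coefficients")
    else if (!is.finite(p[2]) || p[2] <= 0)
      msg <- c(msg, "'p1' must be > 0 (OD must increase with C at low C)")
    if (length(object@od_valid_range) != 2 ||
        diff(object@od_valid_range) < 0)
      msg <- c(msg, "'od_valid_range' must be an increasing length-2 range")
    if (length(object@c_valid_range) != 2 ||
        diff(object@c_valid_range) < 0)
      msg <- c(msg, "'c_valid_range' must be an increasing length-2 range")
    if (!length(msg) && length(p) >= 2) {
      # monotone increasing across the supported concentration range
      dv <- polyDeriv(p, object@c_valid_range)
      if (any(dv <= 0))
        msg <- c(msg, "curve must be strictly increasing on c_valid_range")
    }
    if (length(msg)) msg else TRUE
  })

# ---- cross-instrument calibration ------------------------------------------

#' CrossCalibration: proportional mapping between two instruments
#'
#' @slot scale numeric(1), multiplicative factor taking instrument-A OD to
#'   instrument-B OD (> 0).
#' @slot offset numeric(1), additive offset (0 unless explicitly freed).
#' @slot rmse numeric(1), residual RMSE of the mapping.
#' @slot n integer(1), number of paired readings.
#' @slot instruments character(2), instrument labels (from, to).
#' @export
setClass("CrossCalibration",
  representation(scale = "numeric", offset = "numeric", rmse = "numeric",
                 n = "integer", instruments = "character"),
  validity = function(object) {
    if (!is.finite(object@scale) || object@scale <= 0)
      "'scale' must be finite and > 0" else TRUE
  })

# ---- growth curves ----------------------------------------------------------

#' GrowthCurve: OD time series with replicate structure
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] with one
#' assay `"od"` (timepoints in rows, replicate wells in columns) and the time
#' grid in `rowData(x)$time_s`.
#'
#' @export
#' @import SummarizedExperiment
setClass("GrowthCurve", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character()
    if (!"od" %in% SummarizedExperiment::assayNames(object))
      return("must carry an 'od' assay")
    t <- SummarizedExperiment::rowData(object)$time_s
    if (is.null(t)) return("rowData must contain 'time_s'")
    if (any(!is.finite(t)) || any(diff(t) <= 0))
      msg <- c(msg, "'time_s' must be finite and strictly increasing")
    od <- SummarizedExperiment::assay(object, "od")
    if (any(od < 0, na.rm = TRUE))
      msg <- c(msg, "'od' must be >= 0 (blank-subtract and clip first)")
    if (length(msg)) msg else TRUE
  })

#' @param time_s timepoints in seconds, strictly increasing.
#' @param od numeric vector (one well) or matrix (timepoints x wells) of
#'   blank-subtracted OD readings. Small negatives are clipped to 0 with a
#'   warning.
#' @param well well/replicate labels (default `"w1"`, `"w2"`, ...).
#' @param metadata optional list (instrument id, fill volume, ...).
#' @return A `GrowthCurve` object.
#' @rdname GrowthCurve-class
#' @export
GrowthCurve <- function(time_s, od, well = NULL, metadata = list()) {
  od <- as.matrix(od)
  if (nrow(od) != length(time_s))
    stop("'od' must have one row per timepoint")
  if (any(od < 0, na.rm = TRUE)) {
    neg <- od[od < 0 & !is.na(od)]
    if (any(neg < -0.01))
      stop("OD readings substantially below zero; check blank subtraction")
    warning("clipping ", sum(od < 0, na.rm = TRUE),
            " small negative OD value(s) to 0")
    od[od < 0] <- 0
  }
  if (is.null(well)) well <- paste0("w", seq_len(ncol(od)))
  colnames(od) <- well
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(od = od),
    rowData = S4Vectors::DataFrame(time_s = as.numeric(time_s)),
    metadata = metadata)
  new("GrowthCurve", se)
}

#' ConcentrationCurve: cell-concentration time series with validity flags
#'
#' Assays: `"concentration"` (ml^-1) and `"flag"` (character: `"ok"`,
#' `"below_range"`, `"above_range"`); time grid in `rowData(x)$time_s`.
#'
#' @export
setClass("ConcentrationCurve", contains = "SummarizedExperiment",
  validity = function(object) {
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("concentration", "flag") %in% an))
      return("must carry 'concentration' and 'flag' assays")
    if (is.null(SummarizedExperiment::rowData(object)$time_s))
      return("rowData must contain 'time_s'")
    cc <- SummarizedExperiment::assay(object, "concentration")
    fl <- SummarizedExperiment::assay(object, "flag")
    if (any(cc[fl == "ok"] < 0, na.rm = TRUE))
      return("valid concentrations must be >= 0")
    TRUE
  })

#' @param time_s timepoints in seconds.
#' @param concentration numeric vector or matrix (ml^-1), `NA` where invalid.
#' @param flag character vector/matrix of per-point validity flags; defaults
#'   to `"ok"` everywhere.
#' @param well well labels.
#' @param metadata optional list.
#' @return A `ConcentrationCurve` object.
#' @rdname ConcentrationCurve-class
#' @export
ConcentrationCurve <- function(time_s, concentration, flag = NULL,
                               well = NULL, metadata = list()) {
  cc <- as.matrix(concentration)
  if (is.null(flag)) flag <- matrix("ok", nrow(cc), ncol(cc))
  fl <- matrix(as.character(flag), nrow(cc), ncol(cc))
  if (is.null(well)) well <- paste0("w", seq_len(ncol(cc)))
  colnames(cc) <- colnames(fl) <- well
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(concentration = cc, flag = fl),
    rowData = S4Vectors::DataFrame(time_s = as.numeric(time_s)),
    metadata = metadata)
  new("ConcentrationCurve", se)
}

#' GrowthMetrics: per-replicate and summarized growth-curve statistics
#'
#' @slot per_replicate data.frame with one row per replicate: `replicate`,
#'   `mu_max_hr`, `t_mu_max_hr`, `lag_hr`, `yield`.
#' @slot summary list with means and SEMs across replicates.
#' @export
setClass("GrowthMetrics",
  representation(per_replicate = "data.frame", summary = "list"))

# ---- synthetic data ---------------------------------------------------------

#' SizeTrajectory: prescribed cell-size behaviour during simulated growth
#'
#' Modes:
#' \describe{
#'   \item{constant}{diameter fixed at `baseline_diameter` (minimal-medium
#'     growth, where cell size stays constant until starvation).}
#'   \item{stationary_shrink}{per-cell volume falls by `shrink_fraction` as the
#'     population approaches carrying capacity (stationary-phase volume
#'     reduction).}
#'   \item{filamentation}{during `[pulse_start_hr, pulse_end_hr]` division
#'     halts: cell number is held flat while per-cell volume keeps growing
#'     (beta-lactam filamentation); afterwards filaments divide and the
#'     per-cell volume relaxes back over `relax_hr`.}
#' }
#'
#' @slot mode character(1), one of `"constant"`, `"stationary_shrink"`,
#'   `"filamentation"`.
#' @slot baseline_diameter numeric(1), equivalent-sphere diameter (um, > 0).
#' @slot params list of mode parameters (`shrink_fraction`; `pulse_start_hr`,
#'   `pulse_end_hr`, `relax_hr`).
#' @export
setClass("SizeTrajectory",
  representation(mode = "character", baseline_diameter = "numeric",
                 params = "list"),
  validity = function(object) {
    msg <- character()
    if (!object@mode %in% c("constant", "stationary_shrink", "filamentation"))
      msg <- c(msg, "unknown size-trajectory mode")
    if (!is.finite(object@baseline_diameter) || object@baseline_diameter <= 0)
      msg <- c(msg, "'baseline_diameter' must be > 0")
    p <- object@params
    if (object@mode == "stationary_shrink") {
      sf <- p$shrink_fraction
      if (is.null(sf) || !is.finite(sf) || sf < 0 || sf >= 1)
        msg <- c(msg, "'shrink_fraction' must lie in [0, 1)")
    }
    if (object@mode == "filamentation") {
      if (is.null(p$pulse_start_hr) || is.null(p$pulse_end_hr) ||
          p$pulse_end_hr <= p$pulse_start_hr)
        msg <- c(msg, "filamentation needs pulse_start_hr < pulse_end_hr")
      if (!is.null(p$relax_hr) && p$relax_hr <= 0)
        msg <- c(msg, "'relax_hr' must be > 0")
    }
    if (length(msg)) msg else TRUE
  })

#' @param mode size-trajectory mode.
#' @param baseline_diameter baseline equivalent-sphere diameter (um).
#' @param shrink_fraction fractional per-cell volume loss at carrying capacity
#'   (stationary_shrink mode).
#' @param pulse_start_hr,pulse_end_hr filamentation pulse window (hours).
#' @param relax_hr relaxation timescale for post-pulse filament division
#'   (hours, default 0.3: division of an existing filament needs no growth).
#' @return A `SizeTrajectory` object.
#' @rdname SizeTrajectory-class
#' @export
SizeTrajectory <- function(mode = c("constant", "stationary_shrink",
                                    "filamentation"),
                           baseline_diameter = 1.0, shrink_fraction = 0.3,
                           pulse_start_hr = 3, pulse_end_hr = 6,
                           relax_hr = 0.3) {
  mode <- match.arg(mode)
  params <- switch(mode,
    constant = list(),
    stationary_shrink = list(shrink_fraction = shrink_fraction),
    filamentation = list(pulse_start_hr = pulse_start_hr,
                         pulse_end_hr = pulse_end_hr, relax_hr = relax_hr))
  new("SizeTrajectory", mode = mode,
      baseline_diameter = as.numeric(baseline_diameter), params = params)
}

#' CountingSetup: microscope field-of-view counting geometry
#'
#' @slot fov_x,fov_y,fov_z numeric(1), field-of-view dimensions in
#'   micrometres (> 0).
#' @slot n_fields integer(1), number of independent fields counted (>= 1).
#' @export
setClass("CountingSetup",
  representation(fov_x = "numeric", fov_y = "numeric", fov_z = "numeric",
                 n_fields = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(!is.finite(c(object@fov_x, object@fov_y, object@fov_z))) ||
        any(c(object@fov_x, object@fov_y, object@fov_z) <= 0))
      msg <- c(msg, "field-of-view dimensions must be positive (um)")
    if (object@n_fields < 1L)
      msg <- c(msg, "'n_fields' must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' @param fov_x,fov_y,fov_z field-of-view dimensions in micrometres; defaults
#'   are the 55.6 x 55.6 x 100 um imaging stack.
#' @param n_fields number of independent fields counted (default 30, within
#'   the usual 20-50).
#' @return A `CountingSetup` object.
#' @rdname CountingSetup-class
#' @export
CountingSetup <- function(fov_x = 55.6, fov_y = 55.6, fov_z = 100,
                          n_fields = 30L) {
  new("CountingSetup", fov_x = as.numeric(fov_x), fov_y = as.numeric(fov_y),
      fov_z = as.numeric(fov_z), n_fields = as.integer(n_fields))
}
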