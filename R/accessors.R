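# Accessors and show methods.

#' @describeIn ScatteringResult-class extinction efficiency.
#' @param x a `ScatteringResult`.
#' @export
qExt <- function(x) { stopifnot(is(x, "ScatteringResult")); x@q_ext }

#' @describeIn ScatteringResult-class scattering efficiency.
#' @export
qSca <- function(x) { stopifnot(is(x, "ScatteringResult")); x@q_sca }

#' @describeIn ScatteringResult-class extinction cross-section (cm^2).
#' @export
sigmaExt <- function(x) { stopifnot(is(x, "ScatteringResult")); x@sigma_ext }

#' Acceptance half-angle of a detector geometry (radians)
#'
#' @param geometry a [DetectorGeometry-class].
#' @return `atan(aperture_radius / detector_distance)` in radians.
#' @export
acceptanceAngle <- function(geometry) {
  stopifnot(is(geometry, "DetectorGeometry"))
  atan(geometry@aperture_radius / geometry@detector_distance)
}

#' @describeIn CalibrationCurve-class polynomial coefficients (p0, p1, ...).
#' @param object a `CalibrationCurve`.
#' @param ... unused.
#' @export
setMethod("coef", "CalibrationCurve", function(object, ...)
  object@coefficients)

#' @describeIn CalibrationCurve-class OD range supported by the fit.
#' @param x a `CalibrationCurve`.
#' @export
odValidRange <- function(x) { stopifnot(is(x, "CalibrationCurve")); x@od_valid_range }

#' @describeIn CalibrationCurve-class concentration range supported by the fit.
#' @export
cValidRange <- function(x) { stopifnot(is(x, "CalibrationCurve")); x@c_valid_range }

#' Timepoints of a growth or concentration curve (seconds)
#'
#' @param x a [GrowthCurve-class] or [ConcentrationCurve-class].
#' @return Numeric vector of timepoints in seconds.
#' @export
timePoints <- function(x) {
  stopifnot(is(x, "SummarizedExperiment"))
  SummarizedExperiment::rowData(x)$time_s
}

#' OD assay matrix of a growth curve (timepoints x wells)
#'
#' @param x a [GrowthCurve-class].
#' @return Numeric matrix of OD readings.
#' @export
odMatrix <- function(x) {
  stopifnot(is(x, "GrowthCurve"))
  SummarizedExperiment::assay(x, "od")
}

#' Concentration and flag matrices of a concentration curve
#'
#' @param x a [ConcentrationCurve-class].
#' @return `concentrationMatrix`: numeric matrix (ml^-1, `NA` where out of
#'   range); `flagMatrix`: character matrix of validity flags.
#' @export
concentrationMatrix <- function(x) {
  stopifnot(is(x, "ConcentrationCurve"))
  SummarizedExperiment::assay(x, "concentration")
}

#' @rdname concentrationMatrix
#' @export
flagMatrix <- function(x) {
  stopifnot(is(x, "ConcentrationCurve"))
  SummarizedExperiment::assay(x, "flag")
}

#' @describeIn GrowthMetrics-class per-replicate metrics table.
#' @param x a `GrowthMetrics`.
#' @export
perReplicate <- function(x) { stopifnot(is(x, "GrowthMetrics")); x@per_replicate }

#' @describeIn GrowthMetrics-class across-replicate summary list.
#' @export
metricsSummary <- function(x) { stopifnot(is(x, "GrowthMetrics")); x@summary }

#' Data table of a dilution series
#'
#' @param x a [DilutionSeries-class].
#' @return data.frame with columns `concentration_per_ml`, `od`,
#'   `replicate_id`.
#' @export
seriesData <- function(x) { stopifnot(is(x, "DilutionSeries")); x@data }

setMethod("show", "Scatterer", function(object) {
  cat("Scatterer: D =", object@diameter, "um, n_p =", object@n_particle,
      if (object@size_cv > 0) paste0("(size CV ", object@size_cv, ")") else
        "(monodisperse)", "\n")
})

setMethod("show", "OpticalContext", function(object) {
  cat("OpticalContext: lambda =", object@wavelength_nm, "nm, n_m =",
      object@n_medium, "\n")
})

setMethod("show", "ScatteringResult", function(object) {
  cat("ScatteringResult: Q_ext =", signif(object@q_ext, 6),
      ", Q_sca =", signif(object@q_sca, 6))
  if (!is.na(object@sigma_ext))
    cat(", sigma_ext =", signif(object@sigma_ext, 6), "cm^2")
  cat("\n")
})

setMethod("show", "DilutionSeries", function(object) {
  d <- object@data
  cat("DilutionSeries:", length(unique(d$concentration_per_ml)),
      "concentrations,", nrow(d), "readings, instrument",
      object@instrument_id, "\n")
  cat("  C range:", format(range(d$concentration_per_ml), digits = 3),
      "ml^-1; OD range:", format(range(d$od), digits = 3), "\n")
  if (length(object@truth)) cat("  synthetic (ground truth attached)\n")
})

setMethod("show", "CalibrationCurve", function(object) {
  p <- object@coefficients
  cat("CalibrationCurve (degree", length(p) - 1, "fit,",
      object@fit$method, ")\n")
  cat("  OD(C) coefficients:", paste(names(p), signif(p, 6), sep = " = ",
                                     collapse = ", "), "\n")
  cat("  valid OD range: [", signif(object@od_valid_range[1], 4), ",",
      signif(object@od_valid_range[2], 4), "], RMSE",
      signif(object@rmse, 4), "\n")
  cat("  instrument:", object@instrument_id, "; fitted", object@date, "\n")
})

setMethod("show", "CrossCalibration", function(object) {
  cat("CrossCalibration", object@instruments[1], "->",
      object@instruments[2], ": scale =", signif(object@scale, 6),
      ", offset =", signif(object@offset, 6), ", RMSE =",
      signif(object@rmse, 4), "(n =", object@n, ")\n")
})

setMethod("show", "GrowthMetrics", function(object) {
  s <- object@summary
  cat("GrowthMetrics over", s$n_replicates, "replicate(s):\n")
  cat("  mu_max =", signif(s$mu_max_hr, 4), "hr^-1",
      if (is.finite(s$mu_max_sem %||% NA)) paste("+/-", signif(s$mu_max_sem, 3)),
      "\n")
  cat("  t(mu_max) =", signif(s$t_mu_max_hr, 4), "hr; lag =",
      signif(s$lag_hr, 4), "hr; yield =", signif(s$yield, 4), "\n")
})
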