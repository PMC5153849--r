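# Growth-curve conversion and growth-metric extraction.

#' Convert an OD growth curve to a cell-concentration curve
#'
#' Applies [invertCalibration()] pointwise. Points whose OD lies outside the
#' calibration's supported range are flagged (`"below_range"` /
#' `"above_range"`) and set to `NA` rather than silently extrapolated;
#' replicate structure is preserved.
#'
#' @param curve a [GrowthCurve-class].
#' @param calibration a [CalibrationCurve-class].
#' @param fill_volume_ul optional fill volume: when given, readings are first
#'   rescaled with [applyVolumeCorrection()].
#' @param path a [PathConfig-class] (used only for the volume correction).
#' @return A [ConcentrationCurve-class].
#' @export
odToConcentration <- function(curve, calibration, fill_volume_ul = NULL,
                              path = PathConfig()) {
  stopifnot(is(curve, "GrowthCurve"), is(calibration, "CalibrationCurve"))
  od <- SummarizedExperiment::assay(curve, "od")
  if (!is.null(fill_volume_ul))
    od <- applyVolumeCorrection(od, fill_volume_ul, path)
  rng <- calibration@od_valid_range
  tol <- 1e-9 * max(abs(rng), 1)
  flag <- matrix("ok", nrow(od), ncol(od))
  flag[od < rng[1] - tol] <- "below_range"
  flag[od > rng[2] + tol] <- "above_range"
  conc <- matrix(NA_real_, nrow(od), ncol(od))
  ok <- flag == "ok" & !is.na(od)
  if (any(ok))
    conc[ok] <- invertCalibration(calibration, od[ok])
  ConcentrationCurve(
    time_s = SummarizedExperiment::rowData(curve)$time_s,
    concentration = conc, flag = flag, well = colnames(od),
    metadata = c(S4Vectors::metadata(curve),
                 list(calibration_instrument = calibration@instrument_id)))
}

#' Sliding-window specific growth rate
#'
#' Ordinary least-squares slope of `ln(value)` against time over a centered
#' sliding window, in units of 1/hr. Windows containing non-positive values
#' are skipped (`NA`) with a warning.
#'
#' @param time_s timepoints in seconds, strictly increasing.
#' @param value positive series (OD or concentration).
#' @param window_points window width in points (odd, >= 3; default 5).
#' @return data.frame with `time_hr` and `rate_hr` (NA at the edges and in
#'   skipped windows).
#' @examples
#' t <- seq(0, 4 * 3600, by = 450)
#' growthRateSeries(t, 0.05 * exp(0.69 * t / 3600))
#' @export
growthRateSeries <- function(time_s, value, window_points = 5L) {
  window_points <- as.integer(window_points)
  if (window_points < 3L) stopDomain("'window_points' must be >= 3")
  n <- length(value)
  if (n < window_points)
    stop("series of length ", n, " is shorter than the window (",
         window_points, ")", call. = FALSE)
  if (any(diff(time_s) <= 0)) stopDomain("'time_s' must be strictly increasing")
  half <- window_points %/% 2L
  t_hr <- time_s / 3600
  rate <- rep(NA_real_, n)
  skipped <- FALSE
  for (i in (half + 1L):(n - half)) {
    idx <- (i - half):(i + half)
    v <- value[idx]
    if (any(!is.finite(v)) || any(v <= 0)) { skipped <- TRUE; next }
    tt <- t_hr[idx]
    lv <- log(v)
    rate[i] <- sum((tt - mean(tt)) * (lv - mean(lv))) /
      sum((tt - mean(tt))^2)
  }
  if (skipped)
    warning("windows containing non-positive or missing values were skipped")
  data.frame(time_hr = t_hr, rate_hr = rate)
}

# metrics for a single replicate (numeric vectors)
growthMetricsOne <- function(time_s, value, window_points = 5L) {
  rs <- suppressWarnings(growthRateSeries(time_s, value, window_points))
  yield <- max(value, na.rm = TRUE)
  if (all(is.na(rs$rate_hr)))
    return(list(mu_max = NA_real_, t_mu_max = NA_real_, lag = NA_real_,
                yield = yield))
  i_max <- which.max(rs$rate_hr)
  mu_max <- rs$rate_hr[i_max]
  t_max <- rs$time_hr[i_max]
  lag <- NA_real_
  if (is.finite(mu_max) && mu_max > 0) {
    pos <- which(is.finite(value) & value > 0)
    base_idx <- pos[seq_len(min(3L, length(pos)))]
    baseline <- mean(log(value[base_idx]))
    v_star <- value[i_max]
    if (is.finite(v_star) && v_star > 0) {
      lag <- t_max + (baseline - log(v_star)) / mu_max
      lag <- min(max(lag, 0), t_max)
    }
  }
  list(mu_max = mu_max, t_mu_max = t_max, lag = lag, yield = yield)
}

#' Growth metrics of a curve
#'
#' Extracts, per replicate: the maximum specific growth rate `mu_max` (the
#' peak of [growthRateSeries()]), its timing, the lag time (intersection of
#' the log-space tangent at the point of fastest growth with the initial
#' baseline, the mean of the first three log values), and the maximum value
#' reached (yield). Replicates are then summarized as mean +/- SEM. For
#' non-growing curves (`mu_max <= 0`) the lag is returned as `NA`.
#'
#' @param x a [GrowthCurve-class], [ConcentrationCurve-class], or numeric
#'   vector of values (with `time_s` supplied).
#' @param time_s timepoints in seconds (only for numeric `x`).
#' @param window_points rate-estimation window (default 5).
#' @return A [GrowthMetrics-class].
#' @export
setGeneric("growthMetrics",
           function(x, time_s = NULL, window_points = 5L)
             standardGeneric("growthMetrics"))

metricsFromMatrix <- function(time_s, mat, window_points) {
  reps <- colnames(mat) %||% paste0("w", seq_len(ncol(mat)))
  rows <- lapply(seq_len(ncol(mat)), function(j) {
    m <- growthMetricsOne(time_s, mat[, j], window_points)
    data.frame(replicate = reps[j], mu_max_hr = m$mu_max,
               t_mu_max_hr = m$t_mu_max, lag_hr = m$lag, yield = m$yield)
  })
  per <- do.call(rbind, rows)
  sem <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  }
  summ <- list(
    mu_max_hr = mean(per$mu_max_hr, na.rm = TRUE),
    mu_max_sem = sem(per$mu_max_hr),
    t_mu_max_hr = mean(per$t_mu_max_hr, na.rm = TRUE),
    lag_hr = mean(per$lag_hr, na.rm = TRUE),
    lag_sem = sem(per$lag_hr),
    yield = mean(per$yield, na.rm = TRUE),
    n_replicates = ncol(mat))
  new("GrowthMetrics", per_replicate = per, summary = summ)
}

#' @rdname growthMetrics
#' @export
setMethod("growthMetrics", "GrowthCurve",
  function(x, time_s = NULL, window_points = 5L) {
    metricsFromMatrix(SummarizedExperiment::rowData(x)$time_s,
                      SummarizedExperiment::assay(x, "od"), window_points)
  })

#' @rdname growthMetrics
#' @export
setMethod("growthMetrics", "ConcentrationCurve",
  function(x, time_s = NULL, window_points = 5L) {
    cc <- SummarizedExperiment::assay(x, "concentration")
    cc[SummarizedExperiment::assay(x, "flag") != "ok"] <- NA_real_
    metricsFromMatrix(SummarizedExperiment::rowData(x)$time_s, cc,
                      window_points)
  })

#' @rdname growthMetrics
#' @export
setMethod("growthMetrics", "numeric",
  function(x, time_s = NULL, window_points = 5L) {
    if (is.null(time_s)) stopDomain("'time_s' is required for numeric input")
    metricsFromMatrix(time_s, matrix(x, ncol = 1), window_points)
  })

#' Compare OD-based and count-based growth-rate estimates
#'
#' Computes the ratio of the maximum specific growth rates estimated from an
#' (uncalibrated) OD curve and from a concentration curve of the same
#' culture, and the timing offset of the two rate peaks. When cell size is
#' constant the two estimates agree; when biomass per cell changes (e.g.
#' filamentation) the OD-based rate overestimates the count-based rate and
#' peaks at a different time.
#'
#' @param od_curve a [GrowthCurve-class].
#' @param conc_curve a [ConcentrationCurve-class] (or second
#'   [GrowthCurve-class]).
#' @param window_points rate window for the OD curve (default 5).
#' @param count_window_points rate window for the concentration curve;
#'   defaults to `window_points`. When the two series are sampled at
#'   different intervals, choose the windows to span comparable time.
#' @return list with `mu_ratio` (OD-based / count-based mu_max),
#'   `delta_t_hr` (OD-based peak time minus count-based peak time) and the
#'   two [GrowthMetrics-class] objects.
#' @export
compareRateEstimates <- function(od_curve, conc_curve, window_points = 5L,
                                 count_window_points = window_points) {
  m_od <- growthMetrics(od_curve, window_points = window_points)
  m_cc <- growthMetrics(conc_curve, window_points = count_window_points)
  list(mu_ratio = m_od@summary$mu_max_hr / m_cc@summary$mu_max_hr,
       delta_t_hr = m_od@summary$t_mu_max_hr - m_cc@summary$t_mu_max_hr,
       od_metrics = m_od, count_metrics = m_cc)
}
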