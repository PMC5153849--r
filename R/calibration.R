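# Calibration-curve fitting, inversion and transfer between instruments.

#' Remove saturated points from a dilution series
#'
#' Drops every concentration whose mean OD across replicates reaches the
#' instrument's saturation level, preserving order. The number of removed
#' concentration points is recorded in the `"n_trimmed"` attribute.
#'
#' @param series a [DilutionSeries-class].
#' @param od_sat saturation OD (default 3.5).
#' @return The trimmed [DilutionSeries-class] (with attribute `n_trimmed`).
#' @export
trimSaturated <- function(series, od_sat = 3.5) {
  stopifnot(is(series, "DilutionSeries"))
  if (!is.finite(od_sat) || od_sat <= 0) stopDomain("'od_sat' must be > 0")
  d <- series@data
  uc <- sort(unique(d$concentration_per_ml))
  mean_od <- vapply(uc, function(c0) mean(d$od[d$concentration_per_ml == c0]),
                    numeric(1))
  keep_conc <- uc[mean_od < od_sat]
  n_trimmed <- length(uc) - length(keep_conc)
  if (length(keep_conc) < 4)
    stop("fewer than 4 unsaturated concentration points remain (",
         length(keep_conc), "); cannot support a quadratic calibration",
         call. = FALSE)
  out <- series
  out@data <- d[d$concentration_per_ml %in% keep_conc, , drop = FALSE]
  rownames(out@data) <- NULL
  attr(out, "n_trimmed") <- n_trimmed
  out
}

# Tukey bisquare weights: w = (1 - u^2)^2 for |u| < 1, else 0
bisquareWeights <- function(resid, scale, tuning) {
  u <- resid / (tuning * scale)
  w <- (1 - u^2)^2
  w[abs(u) >= 1] <- 0
  w
}

#' Fit a robust polynomial calibration curve
#'
#' Fits `OD = p0 + p1*C + ... + pd*C^d` (default degree 2) by iteratively
#' reweighted least squares with the Tukey bisquare loss (tuning constant
#' 4.685, scale the normalized median absolute deviation of the residuals),
#' so that occasional gross outliers -- pipetting errors, bubbles, condensation
#' -- are down-weighted rather than dragging the curve. Replicate readings
#' enter as individual observations. Internally the concentration axis is
#' rescaled to order one before fitting (the raw axis spans many decades),
#' and coefficients are mapped back to the per-ml scale.
#'
#' @param series a [DilutionSeries-class] (trim saturated points first; see
#'   [trimSaturated()]).
#' @param degree polynomial degree (default 2).
#' @param tuning bisquare tuning constant (default 4.685).
#' @param max_iter maximum IRLS iterations (default 50).
#' @param tol convergence tolerance on the maximum coefficient change, on the
#'   rescaled axis (default 1e-8).
#' @return A [CalibrationCurve-class].
#' @examples
#' s <- makeBeadSeries(0.96, concentrations = 10^seq(7, 9.5, length.out = 12),
#'                     noise_cv = 0.02, seed = 1)
#' fitCalibration(trimSaturated(s))
#' @export
fitCalibration <- function(series, degree = 2, tuning = 4.685,
                           max_iter = 50L, tol = 1e-8) {
  stopifnot(is(series, "DilutionSeries"))
  d <- series@data
  conc <- d$concentration_per_ml
  od <- d$od
  n_distinct <- length(unique(conc))
  if (n_distinct < degree + 2)
    stop("need at least degree + 2 = ", degree + 2,
         " distinct concentrations; have ", n_distinct, call. = FALSE)
  c_scale <- max(conc)
  u <- conc / c_scale
  X <- outer(u, 0:degree, `^`)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank-deficient (collinear concentrations)",
         call. = FALSE)
  beta <- qr.solve(X, od)
  w <- rep(1, length(od))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    r <- od - drop(X %*% beta)
    s <- median(abs(r - median(r))) / 0.6745
    if (s < 1e-12 * max(abs(od), 1)) { converged <- TRUE; break }  # exact fit
    w <- bisquareWeights(r, s, tuning)
    if (sum(w > 0) < ncol(X))
      stop("bisquare fit collapsed: too few points with non-zero weight",
           call. = FALSE)
    fit <- stats::lm.wfit(X, od, w)
    beta_new <- fit$coefficients
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  # a residual sitting exactly at the bisquare cutoff can make the weights
  # cycle; the iteration cap is then the stopping rule (recorded in the fit
  # diagnostics), provided the remaining movement is not substantial
  if (!converged) {
    if (delta > 1e-4 * max(abs(beta), 1))
      stop("bisquare IRLS did not converge in ", max_iter,
           " iterations (last max coefficient change ", signif(delta, 3),
           ")", call. = FALSE)
    warning("bisquare IRLS stopped at the ", max_iter,
            "-iteration cap (last max coefficient change ",
            signif(delta, 3), ")")
  }
  p <- beta / c_scale^(0:degree)
  resid <- od - polyEval(p, conc)
  # restrict the supported ranges to the monotone increasing branch: for a
  # downward-curving quadratic the vertex may sit inside the data span
  c_lo <- min(conc)
  c_hi <- max(conc)
  if (degree == 2 && p[3] < 0) {
    c_vertex <- -p[2] / (2 * p[3])
    if (c_vertex < c_hi) c_hi <- c_vertex * (1 - 1e-9)
  }
  od_hi <- min(max(od), polyEval(p, c_hi))
  curve <- new("CalibrationCurve",
    coefficients = setNames(p, paste0("p", 0:degree)),
    od_valid_range = c(min(od), od_hi),
    c_valid_range = c(c_lo, c_hi),
    weights = w,
    rmse = sqrt(mean(resid^2)),
    fit = list(method = "bisquare", tuning = tuning, iterations = iter,
               converged = converged, n_points = length(od),
               n_trimmed = attr(series, "n_trimmed") %||% 0L),
    scatterer = series@scatterer,
    instrument_id = series@instrument_id,
    date = format(Sys.Date()))
  validObject(curve)
  curve
}

#' Predicted OD of a calibration curve at given concentrations
#'
#' @param curve a [CalibrationCurve-class].
#' @param concentration concentrations (ml^-1).
#' @return Predicted OD values.
#' @export
predictCalibration <- function(curve, concentration) {
  stopifnot(is(curve, "CalibrationCurve"))
  polyEval(curve@coefficients, concentration)
}

#' Invert a calibration curve: OD to concentration
#'
#' Solves `p2*C^2 + p1*C + (p0 - od) = 0` for the root on the monotone
#' increasing branch within the curve's supported concentration range. By
#' default the OD must lie inside `od_valid_range`; extrapolation beyond the
#' fitted data requires `extrapolate = TRUE`.
#'
#' @param curve a [CalibrationCurve-class].
#' @param od OD value(s) to invert.
#' @param extrapolate allow OD values outside the fitted range (default
#'   `FALSE`).
#' @return Concentration(s) in ml^-1.
#' @export
invertCalibration <- function(curve, od, extrapolate = FALSE) {
  stopifnot(is(curve, "CalibrationCurve"))
  vapply(od, function(o) invertOne(curve, o, extrapolate), numeric(1))
}

invertOne <- function(curve, od, extrapolate) {
  p <- curve@coefficients
  rng <- curve@od_valid_range
  tol <- 1e-9 * max(abs(rng), 1)
  if (!extrapolate && (od < rng[1] - tol || od > rng[2] + tol)) {
    side <- if (od > rng[2]) "saturated: OD above" else "below blank: OD under"
    stop("cannot invert OD = ", od, " (", side, " the calibrated range [",
         signif(rng[1], 4), ", ", signif(rng[2], 4),
         "]); pass extrapolate = TRUE to override", call. = FALSE)
  }
  if (od < p[1] - tol)
    stop("cannot invert OD = ", od, " below blank level p0 = ",
         signif(p[1], 4), call. = FALSE)
  if (length(p) > 3)
    return(invertNumeric(curve, od))
  p0 <- unname(p[1]); p1 <- unname(p[2])
  p2 <- if (length(p) >= 3) unname(p[3]) else 0
  if (p2 == 0) return(max((od - p0) / p1, 0))
  disc <- p1^2 - 4 * p2 * (p0 - od)
  if (disc < 0)
    stop("cannot invert OD = ", od,
         ": saturated (OD above the vertex of the calibration parabola, ",
         signif(p0 - p1^2 / (4 * p2), 4), ")", call. = FALSE)
  # stable form of the root on the increasing branch
  max(2 * (od - p0) / (p1 + sqrt(disc)), 0)
}

# monotone-branch numeric inversion for degrees above 2
invertNumeric <- function(curve, od) {
  p <- curve@coefficients
  f <- function(cc) polyEval(p, cc) - od
  lo <- 0
  hi <- curve@c_valid_range[2] * 2
  if (f(lo) > 0) return(0)
  while (f(hi) < 0 && hi < curve@c_valid_range[2] * 1e3) hi <- hi * 2
  if (f(hi) < 0)
    stop("cannot invert OD = ", od, ": beyond the curve's reachable range",
         call. = FALSE)
  stats::uniroot(f, c(lo, hi), tol = 1e-12 * max(hi, 1))$root
}

#' Table of concentrations at standard OD values across calibration curves
#'
#' Inverts each curve at each requested OD (the conventional set is 0.05,
#' 0.1, 0.5, 1 and 10). Cells where the OD lies outside a curve's calibrated
#' range are `NA` -- never silently extrapolated -- with a parallel `"flags"`
#' attribute distinguishing `"ok"` from `"out_of_range"`.
#'
#' @param curves list of [CalibrationCurve-class] objects.
#' @param od_values OD values to solve for (default `c(0.05, 0.1, 0.5, 1, 10)`).
#' @param labels row labels; defaults to scatterer diameters where available.
#' @return data.frame of concentrations (rows = curves, columns = OD values),
#'   with attribute `flags`.
#' @export
concentrationTable <- function(curves, od_values = c(0.05, 0.1, 0.5, 1, 10),
                               labels = NULL) {
  stopifnot(length(curves) >= 1,
            all(vapply(curves, is, logical(1), "CalibrationCurve")))
  if (is.null(labels))
    labels <- vapply(seq_along(curves), function(i) {
      sc <- curves[[i]]@scatterer
      if (!is.null(sc)) paste0(sc@diameter, "um") else paste0("curve", i)
    }, character(1))
  m <- matrix(NA_real_, length(curves), length(od_values),
              dimnames = list(labels, paste0("od_", od_values)))
  flags <- matrix("ok", length(curves), length(od_values),
                  dimnames = dimnames(m))
  for (i in seq_along(curves)) for (j in seq_along(od_values)) {
    val <- tryCatch(invertCalibration(curves[[i]], od_values[j]),
                    error = function(e) NA_real_)
    m[i, j] <- val
    if (is.na(val)) flags[i, j] <- "out_of_range"
  }
  out <- as.data.frame(m)
  attr(out, "flags") <- flags
  out
}

#' Cross-calibrate two spectrophotometers from paired readings
#'
#' Estimates the proportional factor taking instrument-A readings to
#' instrument-B readings by least squares:
#' `scale = sum(od_a * od_b) / sum(od_a^2)` (closed form). An additive offset
#' is fixed at zero by default (the mapping is a relative difference) and can
#' be freed with `fit_offset = TRUE`.
#'
#' @param od_a,od_b paired OD readings of the same samples on the two
#'   instruments (length >= 3).
#' @param fit_offset also estimate an additive offset (default `FALSE`).
#' @param instruments character(2) labels for the instrument pair.
#' @return A [CrossCalibration-class].
#' @examples
#' crossCalibrate(c(0.1, 0.2, 0.4), c(0.15, 0.30, 0.60))  # scale = 1.5
#' @export
crossCalibrate <- function(od_a, od_b, fit_offset = FALSE,
                           instruments = c("A", "B")) {
  if (length(od_a) != length(od_b) || length(od_a) < 3)
    stopDomain("need at least 3 paired readings of equal length")
  if (any(!is.finite(od_a)) || any(!is.finite(od_b)) ||
      any(od_a < 0) || any(od_b < 0))
    stopDomain("paired readings must be finite and non-negative")
  if (all(od_a == 0))
    stopDomain("all instrument-A readings are zero; scale is undefined")
  if (fit_offset) {
    fit <- lm(od_b ~ od_a)
    offset <- unname(coef(fit)[1])
    scale <- unname(coef(fit)[2])
    resid <- stats::residuals(fit)
  } else {
    offset <- 0
    scale <- sum(od_a * od_b) / sum(od_a^2)
    resid <- od_b - scale * od_a
  }
  new("CrossCalibration", scale = scale, offset = offset,
      rmse = sqrt(mean(resid^2)), n = length(od_a),
      instruments = instruments)
}

#' Align an OD series with a count-derived concentration series
#'
#' Determines the least-squares proportionality `c` between OD and counted
#' concentration, `c = argmin sum (od(t_i) - c * C(t_i))^2`, after linearly
#' interpolating the counts onto the OD timepoints within the overlapping
#' time support.
#'
#' @param od_time_s,od OD series (times in seconds).
#' @param count_time_s,counts count-derived concentration series (ml^-1).
#' @return list with `scale` (the factor `c`), `n` overlapping points,
#'   `rmse`, and per-point `residuals` on the overlap.
#' @export
alignODCounts <- function(od_time_s, od, count_time_s, counts) {
  keep <- od_time_s >= min(count_time_s) & od_time_s <= max(count_time_s)
  if (sum(keep) < 2)
    stop("no overlapping time support between OD and count series",
         call. = FALSE)
  ci <- approx(count_time_s, counts, xout = od_time_s[keep])$y
  odk <- od[keep]
  scale <- sum(odk * ci) / sum(ci^2)
  resid <- odk - scale * ci
  list(scale = scale, n = sum(keep), rmse = sqrt(mean(resid^2)),
       time_s = od_time_s[keep], residuals = resid)
}

#' Minimal adequate polynomial degree by sequential F-tests
#'
#' Fits ordinary polynomials of increasing degree to a dilution series and
#' accepts the lowest degree for which adding the next-order term is not
#' significant in a nested-model F-test at level `alpha`.
#'
#' @param series a [DilutionSeries-class].
#' @param alpha significance level (default 0.01).
#' @param max_degree largest degree considered (default 4).
#' @return The selected degree (integer).
#' @export
selectCalibrationDegree <- function(series, alpha = 0.01, max_degree = 4) {
  stopifnot(is(series, "DilutionSeries"))
  d <- series@data
  u <- d$concentration_per_ml / max(d$concentration_per_ml)
  od <- d$od
  fits <- lapply(1:max_degree, function(k) lm(od ~ poly(u, k, raw = TRUE)))
  for (k in seq_len(max_degree - 1)) {
    pval <- anova(fits[[k]], fits[[k + 1]])$`Pr(>F)`[2]
    if (is.na(pval) || pval >= alpha) return(k)
  }
  max_degree
}
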