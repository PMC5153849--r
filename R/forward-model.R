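# Turbidity forward model: suspension state -> predicted OD across the
# single- and multiple-scattering regimes.

# decadic turbidity tau = sigma * C * L / ln(10)
decadicTurbidity <- function(concentration, sigma_cm2, path_length_cm) {
  sigma_cm2 * concentration * path_length_cm / LN10
}

#' Single-scattering (Beer-Lambert) optical density
#'
#' In the dilute limit every photon scatters at most once and the decadic OD
#' is linear in concentration: `OD = sigma * C * L / ln(10)`.
#'
#' @param state a [SuspensionState-class].
#' @param path a [PathConfig-class].
#' @param sigma_eff effective extinction cross-section in cm^2 (e.g. from
#'   [effectiveSigma()]); if missing it is computed from the state's
#'   scatterer and context with ideal detector geometry.
#' @return The predicted dimensionless OD.
#' @examples
#' s <- SuspensionState(1e9, Scatterer(1, 1.59))
#' odSingleScattering(s, PathConfig(), sigma_eff = 2.302585e-9)  # = 1
#' @export
odSingleScattering <- function(state, path = PathConfig(), sigma_eff = NULL) {
  stopifnot(is(state, "SuspensionState"), is(path, "PathConfig"))
  if (is.null(sigma_eff))
    sigma_eff <- effectiveSigma(state@scatterer, state@context)@sigma_ext
  if (!is.finite(sigma_eff) || sigma_eff < 0)
    stopDomain("'sigma_eff' must be a finite non-negative area (cm^2)")
  decadicTurbidity(state@concentration, sigma_eff, path@path_length_cm)
}

#' Optical density with the quadratic multiple-scattering correction
#'
#' Beyond the single-scattering regime the OD bends below the Beer-Lambert
#' line; this is modelled as `OD = tau - q * tau^2` with
#' `tau = sigma * C * L / ln(10)`, valid on the monotone branch
#' `tau <= 1/(2q)`. Beyond that branch the suspension enters the
#' photon-diffusion limit, which is outside this model's validity.
#'
#' @inheritParams odSingleScattering
#' @param params a [MultipleScattering-class]; `quad_coeff = 0` reduces the
#'   model to [odSingleScattering()].
#' @return The predicted dimensionless OD.
#' @export
odMultipleScattering <- function(state, path = PathConfig(),
                                 sigma_eff = NULL,
                                 params = MultipleScattering()) {
  stopifnot(is(params, "MultipleScattering"))
  tau <- odSingleScattering(state, path, sigma_eff)
  applyTurbidityCorrection(tau, params@quad_coeff)
}

applyTurbidityCorrection <- function(tau, q) {
  if (q > 0 && any(tau > 1 / (2 * q) + 1e-12))
    stop("turbidity tau = ", signif(max(tau), 4),
         " exceeds the monotone branch tau <= 1/(2q) = ",
         signif(1 / (2 * q), 4),
         "; densities this high lie in the photon-diffusion limit, outside ",
         "the validity of the quadratic model", call. = FALSE)
  tau - q * tau^2
}

#' Optical density of a mixed suspension
#'
#' Component turbidities add in the single-scattering sense; the quadratic
#' multiple-scattering correction is then applied to the total. All components
#' must share the optical context (medium and wavelength).
#'
#' @param states list of [SuspensionState-class] objects with identical
#'   contexts.
#' @param path a [PathConfig-class].
#' @param params a [MultipleScattering-class].
#' @param geometry optional [DetectorGeometry-class] used for each
#'   component's cross-section.
#' @return The predicted dimensionless OD of the mixture.
#' @export
mixtureOD <- function(states, path = PathConfig(),
                      params = MultipleScattering(), geometry = NULL) {
  stopifnot(length(states) >= 1,
            all(vapply(states, is, logical(1), "SuspensionState")))
  ctx0 <- states[[1]]@context
  same <- vapply(states, function(s)
    isTRUE(all.equal(s@context@wavelength_nm, ctx0@wavelength_nm)) &&
    isTRUE(all.equal(s@context@n_medium, ctx0@n_medium)), logical(1))
  if (!all(same))
    stopDomain("all mixture components must share medium and wavelength")
  tau <- sum(vapply(states, function(s) {
    sig <- effectiveSigma(s@scatterer, s@context, geometry)@sigma_ext
    decadicTurbidity(s@concentration, sig, path@path_length_cm)
  }, numeric(1)))
  applyTurbidityCorrection(tau, params@quad_coeff)
}

#' Rescale a measured OD to the 1 cm-equivalent scale for its fill volume
#'
#' @param od_measured measured OD value(s).
#' @param fill_volume_ul fill volume in microlitres; must be present in the
#'   path configuration's correction table.
#' @param path a [PathConfig-class] carrying the instrument's correction
#'   factors.
#' @return Corrected OD value(s): `od_measured * factor`.
#' @examples
#' applyVolumeCorrection(0.5, 200, PathConfig())  # 0.7924
#' @export
applyVolumeCorrection <- function(od_measured, fill_volume_ul,
                                  path = PathConfig()) {
  stopifnot(is(path, "PathConfig"))
  key <- as.character(fill_volume_ul)
  vc <- path@volume_correction
  if (!key %in% names(vc))
    stop("no volume-correction factor for ", key, " ul; available volumes: ",
         paste(names(vc), collapse = ", "), call. = FALSE)
  od_measured * vc[[key]]
}

#' Classify an OD reading into the single- or multiple-scattering regime
#'
#' The crossover sits near OD600 0.2; readings at or below the threshold are
#' labelled `"single"` (boundary inclusive on the single side), above it
#' `"multiple"`.
#'
#' @param od OD value(s), >= 0.
#' @param threshold regime threshold (default 0.2).
#' @return Character vector of `"single"` / `"multiple"` labels.
#' @examples
#' regimeClassify(c(0.1, 0.2, 1.5))
#' @export
regimeClassify <- function(od, threshold = 0.2) {
  if (any(!is.finite(od)) || any(od < 0))
    stopDomain("'od' must be finite and >= 0")
  ifelse(od <= threshold, "single", "multiple")
}

#' Predict the OD of a suspension (full forward model)
#'
#' Convenience wrapper chaining [effectiveSigma()] and
#' [odMultipleScattering()].
#'
#' @param state a [SuspensionState-class].
#' @param path a [PathConfig-class].
#' @param params a [MultipleScattering-class].
#' @param geometry optional [DetectorGeometry-class].
#' @param sigma_eff optional precomputed cross-section (cm^2), bypassing the
#'   Mie evaluation.
#' @return The predicted dimensionless OD.
#' @export
predictOD <- function(state, path = PathConfig(),
                      params = MultipleScattering(), geometry = NULL,
                      sigma_eff = NULL) {
  if (is.null(sigma_eff))
    sigma_eff <- effectiveSigma(state@scatterer, state@context,
                                geometry)@sigma_ext
  odMultipleScattering(state, path, sigma_eff, params)
}
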