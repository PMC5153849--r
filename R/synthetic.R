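# Synthetic-data generation with known ground truth: bead dilution series,
# growth with prescribed cell-size trajectories, plate-reader readout noise,
# and microscope field-of-view counting.

#' Simulate a bead dilution series
#'
#' Generates OD readings for a dilution series of beads of known diameter and
#' refractive index through the full forward model (Mie cross-section,
#' quadratic multiple-scattering correction), with multiplicative Gaussian
#' readout noise. The generating parameters are stored in the series' `truth`
#' slot.
#'
#' @param diameter bead diameter (um). The conventional calibration set is
#'   0.51, 0.96, 3.00, 10.0 and 15.7 um polystyrene (`n_p = 1.59`).
#' @param n_particle particle refractive index (default 1.59, polystyrene).
#' @param concentrations known concentrations (ml^-1), increasing.
#' @param context an [OpticalContext-class] (default OD600 in water).
#' @param path a [PathConfig-class].
#' @param params a [MultipleScattering-class].
#' @param geometry optional [DetectorGeometry-class].
#' @param size_cv diameter coefficient of variation (default 0).
#' @param noise_cv multiplicative readout noise CV (default 0.02).
#' @param n_replicates replicate readings per concentration (default 5).
#' @param seed RNG seed (required for reproducibility).
#' @param instrument_id instrument label stored with the series.
#' @return A [DilutionSeries-class] with ground truth in `@truth`.
#' @export
makeBeadSeries <- function(diameter, n_particle = 1.59, concentrations,
                           context = OpticalContext(), path = PathConfig(),
                           params = MultipleScattering(), geometry = NULL,
                           size_cv = 0, noise_cv = 0.02, n_replicates = 5L,
                           seed = 1L, instrument_id = "synthetic") {
  if (noise_cv < 0) stopDomain("'noise_cv' must be >= 0")
  if (any(diff(concentrations) <= 0) || any(concentrations < 0))
    stopDomain("'concentrations' must be non-negative and increasing")
  sc <- Scatterer(diameter, n_particle, size_cv)
  sigma <- effectiveSigma(sc, context, geometry)@sigma_ext
  od_true <- vapply(concentrations, function(cc)
    predictOD(SuspensionState(cc, sc, context), path, params,
              sigma_eff = sigma), numeric(1))
  od <- withSeed(seed, {
    eps <- rnorm(length(od_true) * n_replicates, 0, noise_cv)
    rep(od_true, each = n_replicates) * (1 + eps)
  })
  DilutionSeries(
    concentration = rep(concentrations, each = n_replicates),
    od = od,
    replicate_id = rep(paste0("r", seq_len(n_replicates)),
                       times = length(concentrations)),
    scatterer = sc, instrument_id = instrument_id,
    truth = list(sigma_eff_cm2 = sigma, quad_coeff = params@quad_coeff,
                 path_length_cm = path@path_length_cm, od_true = od_true,
                 noise_cv = noise_cv, seed = seed))
}

#' Simulate population growth with a prescribed cell-size trajectory
#'
#' The total biovolume follows the chosen growth model (exponential or
#' logistic); the size trajectory then decides how that biovolume is divided
#' into cells:
#' \itemize{
#'   \item `constant`: cell number tracks the model, diameter fixed.
#'   \item `stationary_shrink`: cell number tracks the model while per-cell
#'     volume shrinks as the population approaches carrying capacity.
#'   \item `filamentation`: during the pulse window division halts, so cell
#'     number stays flat while per-cell volume (filament length) grows; after
#'     the pulse filaments divide and per-cell volume relaxes back to
#'     baseline, making the count catch up.
#' }
#'
#' @param model `"exponential"` or `"logistic"`.
#' @param n0 starting concentration (ml^-1).
#' @param mu_hr specific growth rate (1/hr).
#' @param capacity carrying capacity (ml^-1; logistic only).
#' @param size_trajectory a [SizeTrajectory-class].
#' @param t_grid_s timepoints in seconds (default: every 7.5 min for 16 hr).
#' @return data.frame with `time_s`, `n_per_ml` (cell count concentration),
#'   `diameter_um` (equivalent-sphere diameter) and `biovolume` (um^3 per
#'   ml); all ground truth, noise-free.
#' @export
simulateGrowth <- function(model = c("exponential", "logistic"), n0 = 1e7,
                           mu_hr = 0.7, capacity = 1e9,
                           size_trajectory = SizeTrajectory("constant"),
                           t_grid_s = seq(0, 16 * 3600, by = 450)) {
  model <- match.arg(model)
  stopifnot(is(size_trajectory, "SizeTrajectory"))
  if (mu_hr < 0) stopDomain("'mu_hr' must be >= 0")
  if (any(diff(t_grid_s) <= 0)) stopDomain("'t_grid_s' must be increasing")
  t_hr <- t_grid_s / 3600
  n_model <- switch(model,
    exponential = n0 * exp(mu_hr * t_hr),
    logistic = capacity / (1 + (capacity / n0 - 1) * exp(-mu_hr * t_hr)))
  d0 <- size_trajectory@baseline_diameter
  v0 <- pi / 6 * d0^3                      # um^3 per cell at baseline
  biovol <- n_model * v0                   # model biovolume, um^3 per ml
  p <- size_trajectory@params
  if (size_trajectory@mode == "constant") {
    n <- n_model
    v_cell <- rep(v0, length(t_hr))
  } else if (size_trajectory@mode == "stationary_shrink") {
    if (model != "logistic")
      stopDomain("'stationary_shrink' requires the logistic model")
    n <- n_model
    v_cell <- v0 * (1 - p$shrink_fraction * n_model / capacity)
    biovol <- n * v_cell
  } else {  # filamentation
    t_on <- p$pulse_start_hr; t_off <- p$pulse_end_hr
    relax <- p$relax_hr %||% 1
    n <- n_model
    v_cell <- rep(v0, length(t_hr))
    in_pulse <- t_hr >= t_on & t_hr < t_off
    after <- t_hr >= t_off
    if (any(in_pulse)) {
      n_hold <- approx(t_hr, n_model, xout = t_on)$y
      n[in_pulse] <- n_hold
      v_cell[in_pulse] <- biovol[in_pulse] / n_hold
      if (any(after)) {
        v_end <- approx(t_hr, biovol, xout = t_off)$y / n_hold
        v_cell[after] <- v0 + (v_end - v0) * exp(-(t_hr[after] - t_off) / relax)
        n[after] <- biovol[after] / v_cell[after]
      }
    }
  }
  d_t <- (6 * v_cell / pi)^(1 / 3)
  data.frame(time_s = t_grid_s, n_per_ml = n, diameter_um = d_t,
             biovolume = biovol)
}

#' Simulate a plate-reader OD readout of a growth trajectory
#'
#' For each timepoint the true OD is computed from the forward model using
#' the instantaneous equivalent-volume-sphere diameter, and the reported
#' reading is the mean of `n_reads` noisy evaluations (multiplicative
#' Gaussian noise), mirroring the reader's 5-read averaging.
#'
#' @param growth data.frame from [simulateGrowth()] (`time_s`, `n_per_ml`,
#'   `diameter_um`).
#' @param n_particle cell refractive index (default 1.40, an E. coli-like
#'   cytoplasm).
#' @param context an [OpticalContext-class].
#' @param path a [PathConfig-class].
#' @param params a [MultipleScattering-class].
#' @param geometry optional [DetectorGeometry-class].
#' @param n_reads readings averaged per timepoint (default 5).
#' @param noise_cv per-read multiplicative noise CV (default 0.02).
#' @param n_wells number of replicate wells (default 1; wells share the true
#'   trajectory, noise is independent).
#' @param seed RNG seed.
#' @return A [GrowthCurve-class]; the true OD trace is kept in
#'   `metadata(x)$od_true`.
#' @export
simulateODReadout <- function(growth, n_particle = 1.40,
                              context = OpticalContext(),
                              path = PathConfig(),
                              params = MultipleScattering(), geometry = NULL,
                              n_reads = 5L, noise_cv = 0.02, n_wells = 1L,
                              seed = 1L) {
  stopifnot(all(c("time_s", "n_per_ml", "diameter_um") %in% names(growth)))
  if (noise_cv < 0) stopDomain("'noise_cv' must be >= 0")
  # cache the cross-section per unique diameter
  d_round <- signif(growth$diameter_um, 10)
  uniq <- unique(d_round)
  sig_map <- vapply(uniq, function(d)
    effectiveSigma(Scatterer(d, n_particle), context, geometry)@sigma_ext,
    numeric(1))
  sigma_t <- sig_map[match(d_round, uniq)]
  tau <- decadicTurbidity(growth$n_per_ml, sigma_t, path@path_length_cm)
  od_true <- applyTurbidityCorrection(tau, params@quad_coeff)
  nt <- length(od_true)
  od <- withSeed(seed, {
    reads <- array(rnorm(nt * n_reads * n_wells, 0, noise_cv),
                   dim = c(nt, n_reads, n_wells))
    apply(od_true * (1 + reads), c(1, 3), mean)
  })
  od[od < 0] <- 0
  GrowthCurve(growth$time_s, od,
              well = paste0("w", seq_len(n_wells)),
              metadata = list(od_true = od_true, n_reads = n_reads,
                              noise_cv = noise_cv, seed = seed,
                              quad_coeff = params@quad_coeff,
                              n_particle = n_particle))
}

#' Simulate microscope field-of-view counting
#'
#' Counts per field are Poisson with mean `C * V_field`, independent across
#' fields; the estimator is the mean count divided by the field volume. For a
#' vector of true concentrations (a time series of sampling points), each
#' timepoint is counted independently.
#'
#' @param concentration true concentration(s), ml^-1.
#' @param setup a [CountingSetup-class]; the default field of view is
#'   55.6 x 55.6 x 100 um.
#' @param seed RNG seed.
#' @return For scalar input: list with `counts` (per field), `c_hat`, `sem`
#'   and `field_volume_ml`. For vector input: data.frame with one row per
#'   timepoint (`c_hat`, `sem`) plus the counts matrix as attribute
#'   `"counts"`.
#' @examples
#' simulateCounting(1e8, CountingSetup(), seed = 1)$c_hat
#' @export
simulateCounting <- function(concentration, setup = CountingSetup(),
                             seed = 1L) {
  stopifnot(is(setup, "CountingSetup"))
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stopDomain("'concentration' must be finite and >= 0")
  v_ml <- fieldVolumeMl(setup)
  nf <- setup@n_fields
  counts <- withSeed(seed, {
    matrix(rpois(length(concentration) * nf,
                 lambda = rep(concentration * v_ml, each = nf)),
           nrow = nf)
  })
  c_hat <- colMeans(counts) / v_ml
  sem <- apply(counts, 2, sd) / sqrt(nf) / v_ml
  if (length(concentration) == 1L)
    return(list(counts = counts[, 1], c_hat = c_hat, sem = sem,
                field_volume_ml = v_ml))
  out <- data.frame(c_hat = c_hat, sem = sem)
  attr(out, "counts") <- counts
  attr(out, "field_volume_ml") <- v_ml
  out
}

#' Field volume of a counting setup, in millilitres
#'
#' @param setup a [CountingSetup-class].
#' @return Volume in ml (1 um^3 = 1e-12 ml).
#' @export
fieldVolumeMl <- function(setup) {
  stopifnot(is(setup, "CountingSetup"))
  setup@fov_x * setup@fov_y * setup@fov_z * 1e-12
}
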