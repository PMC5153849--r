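# Single-particle optics: exact Mie series, limiting approximations, and the
# detector-acceptance correction that makes a real plate reader differ from an
# ideal turbidimeter.

#' Size parameter of a particle in a medium
#'
#' `x = pi * D * n_medium / lambda_vac`: the particle circumference measured in
#' in-medium wavelengths. It is the natural variable of all scattering
#' formulae used here.
#'
#' @param scatterer a [Scatterer-class].
#' @param context an [OpticalContext-class].
#' @return The dimensionless size parameter (> 0).
#' @examples
#' sizeParameter(Scatterer(0.96, 1.59), OpticalContext(600, 1.333)) # ~ 6.70
#' @export
sizeParameter <- function(scatterer, context = OpticalContext()) {
  stopifnot(is(scatterer, "Scatterer"), is(context, "OpticalContext"))
  d_um <- scatterer@diameter
  lam_um <- context@wavelength_nm / 1000
  if (d_um <= 0 || lam_um <= 0)
    stopDomain("diameter and wavelength must be positive")
  pi * d_um * context@n_medium / lam_um
}

# Mie expansion coefficients a_n, b_n (Bohren & Huffman scheme):
# logarithmic derivative D_n(mx) by downward recurrence, Riccati-Bessel
# psi/chi by upward recurrence. Real relative index only.
mieCoefficients <- function(x, m, nmax = NULL) {
  if (is.null(nmax)) nmax <- ceiling(x + 4 * x^(1 / 3) + 2)  # Wiscombe cutoff
  nstart <- nmax + 15L
  mx <- m * x
  D <- numeric(nstart)
  for (n in nstart:2) D[n - 1] <- n / mx - 1 / (D[n] + n / mx)
  n <- seq_len(nmax)
  psi <- numeric(nmax); chi <- numeric(nmax)
  psi_m1 <- cos(x); psi_0 <- sin(x)      # psi_{-1}, psi_0
  chi_m1 <- -sin(x); chi_0 <- cos(x)
  pm2 <- psi_m1; pm1 <- psi_0
  cm2 <- chi_m1; cm1 <- chi_0
  for (k in n) {
    psi[k] <- (2 * k - 1) / x * pm1 - pm2
    chi[k] <- (2 * k - 1) / x * cm1 - cm2
    pm2 <- pm1; pm1 <- psi[k]
    cm2 <- cm1; cm1 <- chi[k]
  }
  psi_prev <- c(psi_0, psi[-nmax])
  chi_prev <- c(chi_0, chi[-nmax])
  xi <- complex(real = psi, imaginary = -chi)
  xi_prev <- complex(real = psi_prev, imaginary = -chi_prev)
  Dn <- D[n]
  fa <- Dn / m + n / x
  fb <- Dn * m + n / x
  a <- (fa * psi - psi_prev) / (fa * xi - xi_prev)
  b <- (fb * psi - psi_prev) / (fb * xi - xi_prev)
  list(a = a, b = b, nmax = nmax)
}

#' Mie extinction and scattering efficiencies of a homogeneous sphere
#'
#' Evaluates the exact Mie partial-wave series for a non-absorbing sphere with
#' real relative refractive index `m`, truncated at the Wiscombe cutoff
#' `ceiling(x + 4 x^(1/3) + 2)`, with the logarithmic derivative computed by
#' downward recurrence.
#'
#' @param x size parameter (see [sizeParameter()]); must satisfy
#'   `0 < x <= 1e4`.
#' @param m relative refractive index `n_particle / n_medium` (> 0, real).
#' @param scatterer optional [Scatterer-class]; when supplied, the physical
#'   extinction cross-section (cm^2) is filled into the result.
#' @return A [ScatteringResult-class] with efficiencies `q_ext`, `q_sca` and
#'   (if a scatterer was given) `sigma_ext` in cm^2.
#' @examples
#' r <- mieEfficiencies(6.70, 1.59 / 1.333)
#' qExt(r)
#' @export
mieEfficiencies <- function(x, m, scatterer = NULL) {
  if (!is.finite(x) || x <= 0) stopDomain("'x' must be a positive number")
  if (x > 1e4)
    stopDomain("size parameter x > 1e4 is outside the supported range")
  if (!is.finite(m) || m <= 0) stopDomain("'m' must be a positive real number")
  co <- mieCoefficients(x, m)
  n <- seq_along(co$a)
  q_ext <- (2 / x^2) * sum((2 * n + 1) * Re(co$a + co$b))
  q_sca <- (2 / x^2) * sum((2 * n + 1) * (Mod(co$a)^2 + Mod(co$b)^2))
  sigma <- NA_real_
  if (!is.null(scatterer))
    sigma <- q_ext * pi * (scatterer@diameter / 2)^2 * UM2_TO_CM2
  ScatteringResult(q_ext = max(q_ext, 0), q_sca = max(q_sca, 0),
                   sigma_ext = sigma)
}

#' Rayleigh scattering efficiency
#'
#' Small-particle limit `(8/3) x^4 |(m^2 - 1)/(m^2 + 2)|^2`, intended for
#' `x` below about 0.3.
#'
#' @inheritParams mieEfficiencies
#' @return The dimensionless scattering efficiency.
#' @examples
#' rayleighQsca(0.1, 1.1929)
#' @export
rayleighQsca <- function(x, m) {
  if (any(!is.finite(x)) || any(x < 0)) stopDomain("'x' must be >= 0")
  if (any(!is.finite(m)) || any(m <= 0)) stopDomain("'m' must be > 0")
  (8 / 3) * x^4 * abs((m^2 - 1) / (m^2 + 2))^2
}

#' Anomalous-diffraction extinction efficiency (soft spheres)
#'
#' van de Hulst's anomalous-diffraction result for optically soft spheres
#' (`m` close to 1), in terms of the phase shift `rho = 2 x (m - 1)`:
#' `q = 2 - (4/rho) sin(rho) + (4/rho^2)(1 - cos(rho))`. For small phase
#' shifts this reduces to `rho^2 / 2`, the regime in which the extinction
#' cross-section scales as the fourth power of the radius.
#'
#' @inheritParams mieEfficiencies
#' @return The dimensionless extinction efficiency (0 at `rho = 0`).
#' @examples
#' adaQext(8.4, 1.05)  # rho = 0.84
#' @export
adaQext <- function(x, m) {
  if (any(!is.finite(x)) || any(x < 0)) stopDomain("'x' must be >= 0")
  if (any(m < 1))
    stopDomain("'m' must be >= 1 (soft-particle convention: particle denser ",
               "than medium)")
  rho <- 2 * x * (m - 1)
  out <- numeric(length(rho))
  small <- rho < 1e-2
  # series branch avoids 0/0 cancellation: q = rho^2/2 - rho^4/36 + O(rho^6)
  out[small] <- rho[small]^2 / 2 - rho[small]^4 / 36
  rb <- rho[!small]
  out[!small] <- 2 - (4 / rb) * sin(rb) + (4 / rb^2) * (1 - cos(rb))
  out
}

#' Small-phase-shift extinction cross-section
#'
#' In the small-phase-shift regime (`rho = 2 x (m - 1)` small) the
#' anomalous-diffraction efficiency is `rho^2 / 2`, giving an extinction
#' cross-section `sigma = (rho^2 / 2) * pi r^2` that scales exactly as `r^4`
#' at fixed indices and wavelength. This is the classical soft-sphere
#' approximation for bacteria with size of order the wavelength, and the
#' origin of the strong cell-size dependence of OD calibrations.
#'
#' @param scatterer a [Scatterer-class].
#' @param context an [OpticalContext-class].
#' @return Extinction cross-section in cm^2.
#' @examples
#' jobstSigma(Scatterer(0.6, 1.40), OpticalContext(600, 1.333))
#' @export
jobstSigma <- function(scatterer, context = OpticalContext()) {
  x <- sizeParameter(scatterer, context)
  m <- scatterer@n_particle / context@n_medium
  if (m < 1) stopDomain("'m' must be >= 1")
  rho <- 2 * x * (m - 1)
  if (rho > 0.5)
    warning("phase shift rho = ", signif(rho, 3),
            " > 0.5: outside the small-phase-shift regime")
  r_um <- scatterer@diameter / 2
  (rho^2 / 2) * pi * r_um^2 * UM2_TO_CM2
}

# Mie amplitude functions S1, S2 at cos(theta) = mu (vectorized over mu)
mieAmplitudes <- function(co, mu) {
  nmax <- length(co$a)
  S1 <- S2 <- complex(length(mu))
  pi_nm1 <- numeric(length(mu))     # pi_0 = 0
  pi_n <- rep(1, length(mu))        # pi_1 = 1
  for (n in seq_len(nmax)) {
    tau_n <- n * mu * pi_n - (n + 1) * pi_nm1
    f <- (2 * n + 1) / (n * (n + 1))
    S1 <- S1 + f * (co$a[n] * pi_n + co$b[n] * tau_n)
    S2 <- S2 + f * (co$a[n] * tau_n + co$b[n] * pi_n)
    pi_np1 <- ((2 * n + 1) * mu * pi_n - (n + 1) * pi_nm1) / n
    pi_nm1 <- pi_n
    pi_n <- pi_np1
  }
  list(S1 = S1, S2 = S2)
}

# scattered power within polar angle [0, theta_max], as an efficiency
qScatteredWithin <- function(co, x, theta_max, nodes) {
  gl <- pracma::gaussLegendre(nodes, 0, theta_max)
  amp <- mieAmplitudes(co, cos(gl$x))
  integrand <- (Mod(amp$S1)^2 + Mod(amp$S2)^2) * sin(gl$x)
  sum(gl$w * integrand) / x^2
}

#' Detector-acceptance-corrected extinction efficiency
#'
#' A real spectrophotometer collects forward-scattered light within the
#' acceptance half-angle of its aperture, so the measured extinction is the
#' true extinction minus the scattering that lands on the detector. The
#' within-aperture scattering is integrated from the Mie phase function
#' (amplitude functions S1, S2) by Gauss-Legendre quadrature over the polar
#' angle, with node doubling until the result is stable to 1e-6 relative.
#'
#' @inheritParams mieEfficiencies
#' @param geometry a [DetectorGeometry-class], or `NULL` for an ideal
#'   instrument (zero acceptance angle: the full extinction efficiency).
#' @param theta_acc acceptance half-angle in radians, overriding `geometry`;
#'   may span the full sphere (`pi`), in which case all scattered light is
#'   collected and the effective extinction of a non-absorbing particle
#'   vanishes.
#' @param nodes starting number of quadrature nodes (>= 64).
#' @return Effective extinction efficiency in `[0, q_ext]`.
#' @examples
#' acceptanceCorrection(6.7, 1.19, DetectorGeometry(1, 30))
#' @export
acceptanceCorrection <- function(x, m, geometry = NULL, theta_acc = NULL,
                                 nodes = 64L) {
  res <- mieEfficiencies(x, m)
  if (is.null(theta_acc)) {
    if (is.null(geometry)) return(res@q_ext)
    stopifnot(is(geometry, "DetectorGeometry"))
    theta_acc <- atan(geometry@aperture_radius / geometry@detector_distance)
  }
  if (theta_acc < 0 || theta_acc > pi)
    stopDomain("'theta_acc' must lie in [0, pi]")
  if (theta_acc == 0) return(res@q_ext)
  nodes <- max(64L, as.integer(nodes))
  co <- mieCoefficients(x, m)
  q1 <- qScatteredWithin(co, x, theta_acc, nodes)
  q2 <- qScatteredWithin(co, x, theta_acc, 2L * nodes)
  if (abs(q2 - q1) > 1e-6 * max(abs(q2), 1e-12)) {
    q3 <- qScatteredWithin(co, x, theta_acc, 4L * nodes)
    if (abs(q3 - q2) > 1e-6 * max(abs(q3), 1e-12))
      stop("acceptance quadrature did not converge; increase 'nodes'")
    q2 <- q3
  }
  eff <- res@q_ext - q2
  min(max(eff, 0), res@q_ext)
}

# Gauss-Hermite average of the extinction cross-section over a lognormal
# diameter distribution with mean D and coefficient of variation cv.
polydisperseSigma <- function(scatterer, context, geometry, npts = 11L) {
  cv <- scatterer@size_cv
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(scatterer@diameter) - sdlog^2 / 2
  gh <- pracma::gaussHermite(npts)
  d_nodes <- exp(meanlog + sqrt(2) * sdlog * gh$x)
  w <- gh$w / sqrt(pi)
  m <- scatterer@n_particle / context@n_medium
  sig <- vapply(d_nodes, function(d) {
    x <- pi * d * context@n_medium / (context@wavelength_nm / 1000)
    q <- acceptanceCorrection(x, m, geometry)
    q * pi * (d / 2)^2 * UM2_TO_CM2
  }, numeric(1))
  sum(w * sig)
}

#' Effective extinction cross-section of a scatterer population
#'
#' Combines the exact Mie efficiency, the detector-acceptance correction and
#' (when `size_cv > 0`) averaging over a lognormal size distribution by
#' 11-point Gauss-Hermite quadrature, returning the per-particle cross-section
#' that enters the turbidity forward model.
#'
#' @param scatterer a [Scatterer-class].
#' @param context an [OpticalContext-class].
#' @param geometry optional [DetectorGeometry-class] (`NULL` = ideal).
#' @return A [ScatteringResult-class]; `sigma_ext` is the effective
#'   cross-section in cm^2 (acceptance-corrected, size-averaged).
#' @export
effectiveSigma <- function(scatterer, context = OpticalContext(),
                           geometry = NULL) {
  x <- sizeParameter(scatterer, context)
  m <- scatterer@n_particle / context@n_medium
  res <- mieEfficiencies(x, m, scatterer = scatterer)
  if (scatterer@size_cv > 0) {
    sigma <- polydisperseSigma(scatterer, context, geometry)
  } else {
    q_eff <- acceptanceCorrection(x, m, geometry)
    sigma <- q_eff * pi * (scatterer@diameter / 2)^2 * UM2_TO_CM2
  }
  ScatteringResult(q_ext = res@q_ext, q_sca = res@q_sca, sigma_ext = sigma)
}
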