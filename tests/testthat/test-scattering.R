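test_that("size parameter follows the optics convention and rejects bad input", {
  x <- sizeParameter(Scatterer(0.96, 1.59), OpticalContext(600, 1.333))
  expect_equal(x, pi * 0.96 * 1.333 / 0.600, tolerance = 1e-12)
  expect_equal(round(x, 2), 6.70)
  # identity case: circumference equal to the in-medium wavelength
  d_unit <- 0.600 / (pi * 1.333)
  expect_equal(sizeParameter(Scatterer(d_unit, 1.5), OpticalContext()), 1)
  expect_error(Scatterer(0, 1.59), "diameter")
  expect_error(sizeParameter(Scatterer(1, 1.5), OpticalContext(-600, 1.333)))
})

test_that("Mie efficiencies match the independent Bessel-function oracle", {
  grid <- expand.grid(x = c(0.05, 0.2, 0.5, 1, 2, 3.5, 6.7, 10, 15, 25, 40,
                            60, 80, 100),
                      m = c(1.05, 1.19))
  grid <- rbind(grid, data.frame(x = c(6.7, 12, 20, 30, 50, 75),
                                 m = 1.59 / 1.333))
  expect_gte(nrow(grid), 20)
  for (i in seq_len(nrow(grid))) {
    got <- qExt(mieEfficiencies(grid$x[i], grid$m[i]))
    want <- oracleMieQ(grid$x[i], grid$m[i])[["q_ext"]]
    expect_equal(got, want, tolerance = 1e-6,
                 label = sprintf("q_ext(x=%g, m=%g)", grid$x[i], grid$m[i]))
  }
})

test_that("non-absorbing spheres have equal extinction and scattering", {
  for (x in c(0.01, 0.1, 1, 6.7, 20, 100)) {
    r <- mieEfficiencies(x, 1.2)
    expect_lt(abs(qExt(r) - qSca(r)), 1e-8 * qExt(r) + 1e-300)
  }
})

test_that("Mie reduces to Rayleigh for small particles", {
  for (x in c(0.01, 0.03, 0.05)) for (m in c(1.05, 1.19, 1.3)) {
    expect_equal(qSca(mieEfficiencies(x, m)), rayleighQsca(x, m),
                 tolerance = 5e-3)
  }
  # closed-form spot value
  expect_equal(rayleighQsca(0.1, 1.1929), 4.0724e-6, tolerance = 1e-4)
  expect_equal(rayleighQsca(0.1, 1), 0)   # index-matched
  expect_equal(rayleighQsca(0, 1.2), 0)
})

test_that("Mie approaches the anomalous-diffraction form for soft particles", {
  for (x in c(5, 10, 20, 50)) for (m in c(1.01, 1.03, 1.05)) {
    expect_equal(qExt(mieEfficiencies(x, m)), adaQext(x, m),
                 tolerance = 0.15,
                 label = sprintf("x=%g m=%g", x, m))
  }
})

test_that("anomalous-diffraction efficiency matches its closed form", {
  rho <- 0.84
  q <- 2 - (4 / rho) * sin(rho) + (4 / rho^2) * (1 - cos(rho))
  expect_equal(adaQext(8.4, 1.05), q, tolerance = 1e-12)
  expect_equal(adaQext(8.4, 1.05), 0.3392, tolerance = 1e-4)
  # small-phase-shift limit q -> rho^2/2
  for (rho0 in c(0.0005, 0.005, 0.05, 0.2)) {
    got <- adaQext(rho0 / 0.02, 1.01)  # x chosen so 2x(m-1) = rho0
    expect_equal(got, rho0^2 / 2, tolerance = 1e-2)
  }
  # full-period phase shift, against the closed form directly
  rho <- 2 * pi
  x <- rho / (2 * 0.05)
  expect_equal(adaQext(x, 1.05),
               2 - (4 / rho) * sin(rho) + (4 / rho^2) * (1 - cos(rho)),
               tolerance = 1e-12)
  expect_error(adaQext(5, 0.98), "soft-particle")
})

test_that("extinction paradox: q_ext tends to 2 for large spheres", {
  expect_equal(qExt(mieEfficiencies(500, 1.19)), 2, tolerance = 0.1)
})

test_that("x outside the supported range and bad m are refused", {
  expect_error(mieEfficiencies(2e4, 1.2), "outside the supported")
  expect_error(mieEfficiencies(5, -1), "'m'")
  expect_error(mieEfficiencies(0, 1.2), "'x'")
})

test_that("small-phase-shift cross-section scales exactly as r^4", {
  ctx <- OpticalContext(600, 1.333)
  radii <- c(0.2, 0.3, 0.4, 0.5, 0.6)
  sig <- suppressWarnings(vapply(radii, function(r)
    jobstSigma(Scatterer(2 * r, 1.05 * 1.333), ctx), numeric(1)))
  slope <- coef(lm(log(sig) ~ log(radii)))[2]
  expect_equal(unname(slope), 4, tolerance = 1e-9)
  # doubling the radius multiplies sigma by 16 exactly
  s1 <- jobstSigma(Scatterer(0.6, 1.40), ctx)
  s2 <- suppressWarnings(jobstSigma(Scatterer(1.2, 1.40), ctx))
  expect_equal(s2 / s1, 16, tolerance = 1e-12)
  # index-matched particle has zero cross-section
  expect_equal(jobstSigma(Scatterer(0.6, 1.333), ctx), 0)
  # hand-evaluated closed form at r = 0.3 um, m = 1.05
  r <- 0.3; m <- 1.05
  x <- pi * 0.6 * 1.333 / 0.600
  rho <- 2 * x * (m - 1)
  expect_equal(jobstSigma(Scatterer(0.6, m * 1.333), ctx),
               (rho^2 / 2) * pi * r^2 * 1e-8, tolerance = 1e-12)
  expect_warning(jobstSigma(Scatterer(3, 1.59), ctx), "small-phase-shift")
})

test_that("acceptance correction obeys its limiting cases and monotonicity", {
  x <- 6.7; m <- 1.19
  q_full <- qExt(mieEfficiencies(x, m))
  # vanishing aperture: the ideal instrument sees the full extinction
  eff0 <- acceptanceCorrection(x, m, DetectorGeometry(1e-9, 1000))
  expect_equal(eff0, q_full, tolerance = 1e-9)
  expect_identical(acceptanceCorrection(x, m, NULL), q_full)
  # full-sphere collection of a non-absorbing particle leaves no extinction
  effpi <- acceptanceCorrection(x, m, theta_acc = pi)
  expect_lt(abs(effpi), 1e-6 * q_full)
  # wider acceptance angles can only reduce the effective extinction
  degs <- c(1, 2, 5, 10) * pi / 180
  effs <- vapply(degs, function(th)
    acceptanceCorrection(x, m, theta_acc = th), numeric(1))
  expect_true(all(diff(effs) < 0))
  expect_true(all(effs >= 0 & effs <= q_full))
})

test_that("polydisperse cross-section averages over the size distribution", {
  ctx <- OpticalContext()
  mono <- sigmaExt(effectiveSigma(Scatterer(0.96, 1.59, 0), ctx))
  poly <- sigmaExt(effectiveSigma(Scatterer(0.96, 1.59, 0.07 / 0.96), ctx))
  expect_false(isTRUE(all.equal(mono, poly)))
  expect_equal(poly / mono, 1, tolerance = 0.1)  # small dispersion, small shift
  tiny <- sigmaExt(effectiveSigma(Scatterer(0.96, 1.59, 1e-6), ctx))
  expect_equal(tiny, mono, tolerance = 1e-4)
})
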