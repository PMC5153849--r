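makeSeries <- function(conc, od, ...) DilutionSeries(conc, od, ...)

test_that("saturation trimming removes whole concentration points", {
  conc <- 10^seq(6, 10, length.out = 10)
  od <- c(seq(0.1, 2.9, length.out = 7), 3.6, 3.8, 4.0)
  s <- makeSeries(conc, od)
  # nothing to trim below the threshold
  s_keep <- trimSaturated(makeSeries(conc[1:7], od[1:7]), od_sat = 3.5)
  expect_equal(nrow(seriesData(s_keep)), 7)
  expect_equal(attr(s_keep, "n_trimmed"), 0)
  # three saturated points dropped
  s_trim <- trimSaturated(s, od_sat = 3.5)
  expect_equal(nrow(seriesData(s_trim)), 7)
  expect_equal(attr(s_trim, "n_trimmed"), 3)
  expect_true(all(diff(seriesData(s_trim)$concentration_per_ml) > 0))
  # everything saturated: insufficient data
  expect_error(trimSaturated(makeSeries(conc, rep(4, 10)), 3.5),
               "fewer than 4")
})

test_that("noiseless quadratic data are recovered essentially exactly", {
  conc <- seq(1e8, 5e9, length.out = 12)
  truth <- c(0.01, 1e-10, -1e-21)
  od <- truth[1] + truth[2] * conc + truth[3] * conc^2
  cv <- fitCalibration(makeSeries(conc, od))
  expect_equal(unname(coef(cv)), truth, tolerance = 1e-6)
  expect_lt(cv@rmse, 1e-10)
})

test_that("coefficients are recovered within 5% under 2% noise", {
  truth <- beadFixtureTruth()
  cv <- suppressWarnings(fitCalibration(trimSaturated(beadFixture(seed = 11))))
  expect_equal(unname(coef(cv)[2]), unname(truth[2]), tolerance = 0.05)
  expect_equal(unname(coef(cv)[3]), unname(truth[3]), tolerance = 0.05)
  expect_lt(abs(coef(cv)[1]), 0.05)  # intercept stays near blank level
})

test_that("bisquare resists gross outliers where least squares does not", {
  truth <- beadFixtureTruth()
  s <- beadFixture(seed = 3, n_replicates = 1)
  d <- seriesData(s)
  d$od[c(6, 17)] <- d$od[c(6, 17)] * 3
  s_out <- makeSeries(d$concentration_per_ml, d$od)
  cv <- suppressWarnings(fitCalibration(s_out))
  err_bis <- max(abs((coef(cv)[2:3] - truth[2:3]) / truth[2:3]))
  u <- d$concentration_per_ml / max(d$concentration_per_ml)
  ols <- lm(d$od ~ u + I(u^2))
  p_ols <- coef(ols) / c(1, max(d$concentration_per_ml),
                         max(d$concentration_per_ml)^2)
  err_ols <- max(abs((p_ols[2:3] - truth[2:3]) / truth[2:3]))
  expect_lt(err_bis, 0.08)
  expect_gt(err_ols, 0.15)
})

test_that("breakdown: 20% gross outliers barely move the bisquare fit", {
  s <- beadFixture(seed = 5)
  clean <- suppressWarnings(fitCalibration(s))
  d <- seriesData(s)
  n_out <- round(0.2 * nrow(d))
  set.seed(101)
  idx <- sample(nrow(d), n_out)
  d$od[idx] <- d$od[idx] * 3
  dirty <- makeSeries(d$concentration_per_ml, d$od)
  cv <- suppressWarnings(fitCalibration(dirty))
  move_bis <- max(abs((coef(cv)[2:3] - coef(clean)[2:3]) / coef(clean)[2:3]))
  u <- d$concentration_per_ml / max(d$concentration_per_ml)
  ols <- lm(d$od ~ u + I(u^2))
  p_ols <- coef(ols) / c(1, max(d$concentration_per_ml),
                         max(d$concentration_per_ml)^2)
  move_ols <- max(abs((p_ols[2:3] - coef(clean)[2:3]) / coef(clean)[2:3]))
  expect_lt(move_bis, 0.10)
  expect_gt(move_ols, 0.25)
})

test_that("bisquare IRLS agrees with the reference robust regression", {
  skip_if_not_installed("MASS")
  s <- beadFixture(seed = 7, n_replicates = 1)
  d <- seriesData(s)
  d$od[10] <- d$od[10] * 3
  s_out <- makeSeries(d$concentration_per_ml, d$od)
  cv <- suppressWarnings(fitCalibration(s_out))
  u <- d$concentration_per_ml / max(d$concentration_per_ml)
  rf <- MASS::rlm(d$od ~ u + I(u^2), psi = MASS::psi.bisquare, c = 4.685,
                  maxit = 100)
  p_ref <- coef(rf) / c(1, max(d$concentration_per_ml),
                        max(d$concentration_per_ml)^2)
  expect_equal(unname(coef(cv)[2:3]), unname(p_ref[2:3]), tolerance = 0.02)
})

test_that("fit refuses underdetermined or collinear designs", {
  expect_error(fitCalibration(makeSeries(c(1e8, 2e8, 3e8), c(.1, .2, .3))),
               "distinct concentrations")
})

test_that("inversion returns the increasing-branch root and round-trips", {
  cv <- suppressWarnings(fitCalibration(trimSaturated(beadFixture(seed = 2))))
  ods <- seq(odValidRange(cv)[1] * 1.01, odValidRange(cv)[2] * 0.99,
             length.out = 25)
  cc <- invertCalibration(cv, ods)
  expect_equal(predictCalibration(cv, cc), ods, tolerance = 1e-9)
  # and the concentration-side round trip on the valid branch
  cgrid <- seq(cValidRange(cv)[1], cValidRange(cv)[2], length.out = 20)
  back <- invertCalibration(cv, predictCalibration(cv, cgrid),
                            extrapolate = TRUE)
  expect_equal(back, cgrid, tolerance = 1e-9)
  # curve monotonicity holds by derivative sign across the valid range
  p <- coef(cv)
  dv <- p[2] + 2 * p[3] * cgrid
  expect_true(all(dv > 0))
})

test_that("inversion closed form matches hand arithmetic", {
  cv <- new("CalibrationCurve",
            coefficients = c(p0 = 0, p1 = 1e-10, p2 = 1e-21),
            od_valid_range = c(0, 2), c_valid_range = c(0, 1e10),
            weights = numeric(), rmse = 0,
            fit = list(method = "exact", tuning = NA, iterations = 0L,
                       converged = TRUE, n_points = 0L, n_trimmed = 0L),
            scatterer = NULL, instrument_id = "synthetic", date = "")
  got <- invertCalibration(cv, 0.5)
  want <- (-1e-10 + sqrt(1e-20 + 4e-21 * 0.5)) / (2e-21)
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(round(got / 1e9, 2), 4.77)
  # blank level inverts to zero concentration
  expect_equal(invertCalibration(cv, 0), 0)
})

test_that("inversion distinguishes saturated from below-blank failures", {
  cv <- new("CalibrationCurve",
            coefficients = c(p0 = 0.05, p1 = 1e-9, p2 = -1.25e-19),
            od_valid_range = c(0.05, 2.0), c_valid_range = c(0, 3.9e9),
            weights = numeric(), rmse = 0,
            fit = list(method = "exact", tuning = NA, iterations = 0L,
                       converged = TRUE, n_points = 0L, n_trimmed = 0L),
            scatterer = NULL, instrument_id = "synthetic", date = "")
  expect_error(invertCalibration(cv, 3.0), "saturated")
  expect_error(invertCalibration(cv, 0.01), "below blank")
  # above the parabola vertex even with extrapolation: saturated
  expect_error(invertCalibration(cv, 2.5, extrapolate = TRUE), "saturated")
})

test_that("concentration table inverts curves and flags out-of-range cells", {
  diameters <- c(0.51, 0.96, 3.00, 10.0, 15.7)
  q <- 0.1
  curves <- lapply(diameters, function(d) {
    sig <- sigmaExt(effectiveSigma(Scatterer(d, 1.59), OpticalContext()))
    conc <- tauForOd(seq(0.04, 2.5, length.out = 24), q) * log(10) / sig
    suppressWarnings(fitCalibration(
      makeBeadSeries(d, concentrations = conc, noise_cv = 0.01,
                     n_replicates = 3, seed = 17,
                     params = MultipleScattering(q))))
  })
  tab <- concentrationTable(curves)   # default OD set 0.05, 0.1, 0.5, 1, 10
  expect_identical(names(tab), c("od_0.05", "od_0.1", "od_0.5", "od_1",
                                 "od_10"))
  # OD 10 is beyond every curve: flagged missing, never extrapolated
  expect_true(all(is.na(tab$od_10)))
  expect_true(all(attr(tab, "flags")[, "od_10"] == "out_of_range"))
  # each in-range column decreases with diameter
  for (cl in c("od_0.05", "od_0.1", "od_0.5", "od_1"))
    expect_true(all(diff(tab[[cl]]) < 0), label = cl)
  # single curve, single OD reduces to plain inversion
  t1 <- concentrationTable(curves[2], od_values = 0.5)
  expect_equal(t1[1, 1], invertCalibration(curves[[2]], 0.5))
})

test_that("cross-calibration recovers proportionality between instruments", {
  cc <- crossCalibrate(c(0.1, 0.2, 0.4), c(0.2, 0.4, 0.8))
  expect_equal(cc@scale, 2)
  expect_equal(cc@rmse, 0)
  cc2 <- crossCalibrate(c(0.1, 0.2, 0.4), c(0.15, 0.30, 0.60))
  expect_equal(cc2@scale, 1.5, tolerance = 1e-12)
  # uncorrelated readings still return a scale, with a large residual
  set.seed(8)
  a <- seq(0.1, 1, length.out = 20)
  b <- abs(rnorm(20, 0.5, 0.3))
  cc3 <- crossCalibrate(a, b)
  expect_gt(cc3@rmse / mean(b), 0.2)
  expect_error(crossCalibrate(rep(0, 5), rep(0.1, 5)), "zero")
  expect_error(crossCalibrate(c(0.1, 0.2), c(0.1, 0.2)), "3 paired")
})

test_that("OD/count alignment recovers the scale factor", {
  t_s <- seq(0, 5 * 3600, by = 450)
  counts <- 1e7 * exp(0.7 * t_s / 3600)
  od <- 1e-9 * counts
  al <- alignODCounts(t_s, od, t_s, counts)
  expect_equal(al$scale, 1e-9, tolerance = 1e-12)
  expect_lt(al$rmse, 1e-12)
  expect_error(alignODCounts(t_s, od, t_s + 1e6, counts), "overlapping")
})

test_that("alignment residuals diverge only after cell size changes", {
  # constant size through exponential phase, volume loss in stationary phase
  gr <- simulateGrowth("logistic", n0 = 1e7, mu_hr = 0.7, capacity = 1e9,
                       size_trajectory = SizeTrajectory("stationary_shrink",
                                                        baseline_diameter = 1,
                                                        shrink_fraction = 0.4),
                       t_grid_s = seq(0, 16 * 3600, by = 450))
  gc <- simulateODReadout(gr, path = scenarioPath, noise_cv = 0.005, seed = 9)
  od <- odMatrix(gc)[, 1]
  expo <- gr$n_per_ml < 0.15 * 1e9   # single-scattering exponential phase
  al <- alignODCounts(gr$time_s[expo], od[expo], gr$time_s[expo],
                      gr$n_per_ml[expo])
  rel_expo <- al$rmse / mean(od[expo])
  expect_lt(rel_expo, 0.05)
  # apply the exponential-phase scale to stationary phase: misfit grows
  stat <- gr$n_per_ml > 0.9 * 1e9
  resid_stat <- od[stat] - al$scale * gr$n_per_ml[stat]
  expect_gt(mean(abs(resid_stat)) / mean(od[stat]), 0.1)
})

test_that("sequential F-tests prefer the quadratic in at least 9/10 runs", {
  degrees <- vapply(1:10, function(sd)
    selectCalibrationDegree(beadFixture(seed = sd, n_replicates = 1)),
    numeric(1))
  expect_gte(sum(degrees == 2), 9)
})
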