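test_that("rate estimator is exact on noiseless exponentials", {
  t_s <- seq(0, 6 * 3600, by = 450)
  mu <- 0.69
  v <- 0.02 * exp(mu * t_s / 3600)
  for (w in c(3, 5, 9)) {
    rs <- growthRateSeries(t_s, v, window_points = w)
    expect_equal(rs$rate_hr[!is.na(rs$rate_hr)],
                 rep(mu, sum(!is.na(rs$rate_hr))), tolerance = 1e-9)
  }
  # constant series: rate zero everywhere
  rs0 <- growthRateSeries(t_s, rep(0.5, length(t_s)))
  expect_equal(rs0$rate_hr[!is.na(rs0$rate_hr)],
               rep(0, sum(!is.na(rs0$rate_hr))), tolerance = 1e-12)
  expect_error(growthRateSeries(t_s[1:3], v[1:3], window_points = 5),
               "shorter than the window")
  # non-positive values: window skipped with warning
  v2 <- v; v2[10] <- 0
  expect_warning(rs2 <- growthRateSeries(t_s, v2), "skipped")
  expect_true(any(is.na(rs2$rate_hr[8:12])))
})

test_that("peak rate of a logistic curve matches the analytic maximum", {
  mu <- 0.8; K <- 1e9; n0 <- 1e6
  t_s <- seq(0, 20 * 3600, by = 120)   # dense grid
  n <- K / (1 + (K / n0 - 1) * exp(-mu * t_s / 3600))
  rs <- growthRateSeries(t_s, n, window_points = 5)
  # analytic maximum specific rate is mu * (1 - n0/K) at t = 0
  expect_equal(max(rs$rate_hr, na.rm = TRUE), mu * (1 - n0 / K),
               tolerance = 0.02)
})

test_that("growth metrics recover construction parameters", {
  t_s <- seq(0, 8 * 3600, by = 450)
  mu <- 0.7
  # pure exponential: no lag, mu_max = mu
  m1 <- growthMetrics(0.05 * exp(mu * t_s / 3600), time_s = t_s)
  expect_equal(metricsSummary(m1)$mu_max_hr, mu, tolerance = 1e-6)
  expect_lt(metricsSummary(m1)$lag_hr, 0.2)
  # 2 h baseline hold then exponential: lag recovered within one interval
  v <- ifelse(t_s / 3600 < 2, 0.05, 0.05 * exp(mu * (t_s / 3600 - 2)))
  m2 <- growthMetrics(v, time_s = t_s)
  expect_equal(metricsSummary(m2)$lag_hr, 2, tolerance = 450 / 3600 / 2 + 0.01)
  # flat curve: no growth, lag undefined
  m3 <- growthMetrics(rep(0.4, length(t_s)), time_s = t_s)
  expect_lt(abs(metricsSummary(m3)$mu_max_hr), 1e-9)
  expect_true(is.na(metricsSummary(m3)$lag_hr))
})

test_that("metrics are invariant to uniform rescaling of the values", {
  t_s <- seq(0, 8 * 3600, by = 450)
  # baseline hold, then logistic growth: the rate peak is unique
  hr <- t_s / 3600
  v <- ifelse(hr < 1.5, 0.04,
              2 / (1 + (2 / 0.04 - 1) * exp(-0.6 * (hr - 1.5))))
  m_a <- metricsSummary(growthMetrics(v, time_s = t_s))
  m_b <- metricsSummary(growthMetrics(v * 3.7e8, time_s = t_s))
  expect_equal(m_a$mu_max_hr, m_b$mu_max_hr, tolerance = 1e-9)
  expect_equal(m_a$t_mu_max_hr, m_b$t_mu_max_hr)
  expect_equal(m_a$lag_hr, m_b$lag_hr, tolerance = 1e-9)
  expect_equal(m_b$yield / m_a$yield, 3.7e8, tolerance = 1e-12)
})

test_that("OD conversion flags out-of-range points and preserves replicates", {
  cv <- suppressWarnings(fitCalibration(trimSaturated(beadFixture(seed = 4))))
  rng <- odValidRange(cv)
  t_s <- seq(0, 3 * 3600, by = 900)
  od <- matrix(seq(rng[1] * 0.5, rng[2] * 1.1, length.out = 2 * length(t_s)),
               ncol = 2)
  gc <- GrowthCurve(t_s, od, well = c("a1", "a2"))
  cc <- odToConcentration(gc, cv)
  fl <- flagMatrix(cc)
  expect_identical(dim(fl), dim(od))
  expect_true(any(fl == "below_range") && any(fl == "above_range"))
  expect_true(all(is.na(concentrationMatrix(cc)[fl != "ok"])))
  ok <- fl == "ok"
  expect_equal(predictCalibration(cv, concentrationMatrix(cc)[ok]),
               od[ok], tolerance = 1e-9)
})

test_that("round trip through readout and inversion recovers true C(t)", {
  sc <- constantSizeScenario(seed = 21)
  sig <- sigmaExt(effectiveSigma(Scatterer(1, 1.40), OpticalContext()))
  conc_grid <- tauForOd(seq(0.03, 2.4, length.out = 24), 0.1) * log(10) /
    (sig * 0.58)
  series <- makeBeadSeries(1, n_particle = 1.40,
                           concentrations = conc_grid, path = scenarioPath,
                           noise_cv = 0.02, seed = 31)
  cv <- suppressWarnings(fitCalibration(series))
  cc <- odToConcentration(sc$od, cv)
  ok <- flagMatrix(cc)[, 1] == "ok"
  rel <- concentrationMatrix(cc)[ok, 1] / sc$growth$n_per_ml[ok] - 1
  expect_lt(stats::median(abs(rel)), 0.05)
  # and the converted curve carries the same growth rate as the truth
  m_cc <- growthMetrics(cc, window_points = 9L)
  m_true <- growthMetrics(sc$growth$n_per_ml, time_s = sc$growth$time_s,
                          window_points = 9L)
  expect_equal(metricsSummary(m_cc)$mu_max_hr,
               metricsSummary(m_true)$mu_max_hr, tolerance = 0.05)
})

test_that("the calibration curve chosen materially changes lag and yield", {
  sc <- constantSizeScenario(seed = 13)
  q <- 0.1
  curves <- lapply(c(0.6, 1.0, 3.0), function(d) {
    sig <- sigmaExt(effectiveSigma(Scatterer(d, 1.40), OpticalContext()))
    conc <- tauForOd(seq(0.03, 2.4, length.out = 24), q) * log(10) /
      (sig * 0.58)
    suppressWarnings(fitCalibration(
      makeBeadSeries(d, n_particle = 1.40, concentrations = conc,
                     path = scenarioPath, noise_cv = 0.01, n_replicates = 3,
                     seed = 41, params = MultipleScattering(q))))
  })
  yields <- vapply(curves, function(cv) {
    m <- growthMetrics(odToConcentration(sc$od, cv))
    metricsSummary(m)$yield
  }, numeric(1))
  # small vs large scatterer calibrations disagree by far more than noise
  expect_gt(max(yields) / min(yields), 2)
})

test_that("identical curves compare as equal rate estimates", {
  t_s <- seq(0, 10 * 3600, by = 450)
  # logistic: declining specific rate gives a unique peak window
  od <- 2 / (1 + (2 / 0.03 - 1) * exp(-0.7 * t_s / 3600))
  g1 <- GrowthCurve(t_s, od)
  g2 <- ConcentrationCurve(t_s, od * 1e9)
  r <- compareRateEstimates(g1, g2)
  expect_equal(r$mu_ratio, 1, tolerance = 1e-9)
  expect_equal(r$delta_t_hr, 0)
})
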