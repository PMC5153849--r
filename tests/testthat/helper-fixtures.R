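# Shared fixtures, built in code.

# turbidity that produces a given OD under the quadratic correction
tauForOd <- function(od, q) {
  if (q == 0) od else (1 - sqrt(1 - 4 * q * od)) / (2 * q)
}

# effective cross-section of the standard 0.96 um polystyrene bead at OD600
# in water (cached across tests)
beadSigma <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- sigmaExt(effectiveSigma(Scatterer(0.96, 1.59),
                                        OpticalContext()))
    cache
  }
})

# standard synthetic dilution series: 24 concentrations spanning OD 0.05-2.5
# through the forward model with q = 0.1, 2% multiplicative noise
beadFixture <- function(seed, n_replicates = 5L, noise_cv = 0.02,
                        quad_coeff = 0.1) {
  sig <- beadSigma()
  conc <- tauForOd(seq(0.05, 2.5, length.out = 24), quad_coeff) *
    log(10) / sig
  makeBeadSeries(0.96, concentrations = conc, noise_cv = noise_cv,
                 n_replicates = n_replicates, seed = seed,
                 params = MultipleScattering(quad_coeff))
}

# ground-truth forward-model coefficients for the bead fixture
beadFixtureTruth <- function(quad_coeff = 0.1) {
  sig <- beadSigma()
  c(p0 = 0, p1 = sig / log(10), p2 = -quad_coeff * (sig / log(10))^2)
}

scenarioPath <- PathConfig(0.58)  # ~200 ul in a 96-well plate

# constant-cell-size growth scenario (minimal-medium-like): logistic model,
# OD read every 7.5 min, sacrificial wells counted every 30 min
constantSizeScenario <- function(seed) {
  gr <- simulateGrowth("logistic", n0 = 3e8, mu_hr = 0.7, capacity = 6e9,
                       size_trajectory = SizeTrajectory("constant",
                                                        baseline_diameter = 1),
                       t_grid_s = seq(0, 8 * 3600, by = 450))
  gc <- simulateODReadout(gr, path = scenarioPath, seed = seed)
  count_idx <- which(gr$time_s %% 1800 == 0)
  cnt <- simulateCounting(gr$n_per_ml[count_idx],
                          CountingSetup(n_fields = 50L),
                          seed = seed + 1000L)
  list(growth = gr, od = gc,
       counts = ConcentrationCurve(gr$time_s[count_idx], cnt$c_hat))
}

# beta-lactam filamentation scenario: division halts at 3 h, per-cell volume
# keeps growing to 6 h; counting starts once OD has risen above baseline
filamentationScenario <- function(seed, t_end_hr = 6, count_from_hr = 1.5) {
  traj <- SizeTrajectory("filamentation", baseline_diameter = 0.8,
                         pulse_start_hr = 3, pulse_end_hr = 6,
                         relax_hr = 0.3)
  gr <- simulateGrowth("exponential", n0 = 5e7, mu_hr = 0.7,
                       size_trajectory = traj,
                       t_grid_s = seq(0, t_end_hr * 3600, by = 450))
  gc <- simulateODReadout(gr, path = scenarioPath, seed = seed)
  keep <- gr$time_s >= count_from_hr * 3600
  cnt <- simulateCounting(gr$n_per_ml[keep], CountingSetup(n_fields = 50L),
                          seed = seed + 1000L)
  list(growth = gr, od = gc,
       counts = ConcentrationCurve(gr$time_s[keep], cnt$c_hat))
}
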