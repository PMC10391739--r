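test_that("VVACF of a pure cosine is exact over full periods", {
  ## period 64 fs; the number of origins is a multiple of the half-period,
  ## so the residual cross term cancels exactly
  dt <- 1; N <- 4096; L <- 512
  stopifnot((N - L) %% 32 == 0)
  om <- 2 * pi / 64
  vel <- array(0, c(1, 3, N))
  vel[1, 1, ] <- 3 * cos(om * (0:(N - 1)) * dt)
  tr <- makeVelocityTrajectory(vel, masses = 5, dt = dt)
  cf <- vvacf(tr, 1, maxLag = L)
  expect_equal(cf@values, (9 / 2) * cos(om * cf@lags), tolerance = 1e-10)
  norm <- vvacf(tr, 1, maxLag = L, normalization = "normalized-at-zero")
  expect_equal(norm@values[1], 1)
})

test_that("VVACF(0) satisfies equipartition for a thermostated atom", {
  top <- makeTopology("O", matrix(c(0, 0, 0), 1),
                      data.frame(i = integer(0), j = integer(0),
                                 k = numeric(0), r0 = numeric(0),
                                 class = character(0)))
  tr <- integrateLangevin(top, thermostatSpec(298, 0.02, 9), dt = 0.5,
                          nSteps = 60000, sampleEvery = 2)
  cf <- vvacf(tr, 1)
  expect_equal(cf@values[1], 3 * kBfix * 298 / 15.999, tolerance = 0.05)
})

test_that("a simulated harmonic oscillator shows its analytic frequency", {
  ## small-oscillation regime: amplitudes low enough that the pair spring is
  ## effectively linear and the rotational sidebands stay within resolution
  top <- makeDimer(elements = c("O", "O"), r = 1.5, nu = 800)
  tr <- integrateNVE(top, dt = 0.5, nSteps = 30000, Tinit = 50, seed = 4,
                     sampleEvery = 2)
  sp <- powerSpectrum(vvacf(tr, 1, maxLag = 3000), window = "hann",
                      zeroPadFactor = 4)
  ## restrict to the vibrational region: the free COM mode sits at 0
  sel <- sp@wavenumbers > 100
  peak <- sp@wavenumbers[sel][which.max(sp@power[sel])]
  expect_lt(abs(peak - 800), sp@resolution)
})

test_that("MMCCF with i = j reduces to m^2 times the VVACF", {
  top <- makeDimer()
  tr <- integrateNVE(top, dt = 0.25, nSteps = 4000, Tinit = 250, seed = 6)
  auto <- mmccf(tr, 1, 1, mode = "dot")
  vv <- vvacf(tr, 1)
  expect_equal(auto@values, tr@masses[1]^2 * vv@values, tolerance = 1e-12)
})

test_that("independent thermostated atoms have no momentum correlation", {
  top <- makeTopology(c("O", "O"), rbind(c(0, 0, 0), c(30, 0, 0)),
                      data.frame(i = integer(0), j = integer(0),
                                 k = numeric(0), r0 = numeric(0),
                                 class = character(0)))
  tr <- integrateLangevin(top, thermostatSpec(298, 0.05, 11), dt = 0.5,
                          nSteps = 60000, sampleEvery = 2)
  cross <- mmccf(tr, 1, 2, mode = "dot")
  floorScale <- sqrt(mmccf(tr, 1, 1)@values[1] * mmccf(tr, 2, 2)@values[1])
  expect_lt(sqrt(mean(cross@values^2)) / floorScale, 0.05)
  expect_lt(max(abs(cross@values)) / floorScale, 0.15)
})

test_that("coupled identical oscillators show the two-normal-mode beat", {
  ## analytic two-mode velocities: symmetric mode at nu1, antisymmetric at
  ## nu2; the cross correlation is (cos(w1 t) - cos(w2 t)) / 2
  dt <- 1; N <- 8192; L <- 1024
  nu1 <- 200; nu2 <- 400
  w1 <- 2 * pi * cFix * nu1; w2 <- 2 * pi * cFix * nu2
  tgrid <- (0:(N - 1)) * dt
  vel <- array(0, c(2, 3, N))
  vel[1, 1, ] <- cos(w1 * tgrid) + cos(w2 * tgrid)
  vel[2, 1, ] <- cos(w1 * tgrid) - cos(w2 * tgrid)
  tr <- makeVelocityTrajectory(vel, masses = c(1, 1), dt = dt)
  cc <- mmccf(tr, 1, 2, mode = "dot", maxLag = L)
  expected <- (cos(w1 * cc@lags) - cos(w2 * cc@lags)) / 2
  expect_gt(stats::cor(cc@values, expected), 0.999)
  ## spectrum: positive peak at nu1, negative at nu2 (the beat signature)
  sp <- powerSpectrum(cc, window = "hann", zeroPadFactor = 4)
  near <- function(nu) abs(sp@wavenumbers - nu) < 3 * sp@resolution
  expect_gt(max(sp@power[near(nu1)]), 0)
  expect_lt(min(sp@power[near(nu2)]), 0)
  expect_lt(abs(sp@wavenumbers[which.max(sp@power)] - nu1), sp@resolution)
  expect_lt(abs(sp@wavenumbers[which.min(sp@power)] - nu2), sp@resolution)
})

test_that("power spectra locate a pure tone and flatten white noise", {
  dt <- 1; N <- 8192
  om <- 2 * pi * cFix * 300
  vel <- array(0, c(1, 3, N))
  vel[1, 1, ] <- cos(om * (0:(N - 1)) * dt)
  tr <- makeVelocityTrajectory(vel, masses = 1, dt = dt)
  sp <- powerSpectrum(vvacf(tr, 1), window = "hann")
  expect_lt(abs(sp@wavenumbers[which.max(sp@power)] - 300), sp@resolution)
  ## white noise: flat spectrum (delta-like correlation). A short maximum
  ## lag relative to the series keeps the estimator variance low.
  set.seed(31)
  veln <- array(rnorm(3 * N), c(1, 3, N))
  trn <- makeVelocityTrajectory(veln, masses = 1, dt = dt)
  spn <- powerSpectrum(vvacf(trn, 1, maxLag = N / 16), window = "hann")
  mid <- spn@power[spn@wavenumbers > 500 & spn@wavenumbers < 15000]
  expect_lt(stats::sd(mid) / mean(mid), 0.2)
})

test_that("unwindowed spectra integrate back to C(0) (Parseval)", {
  top <- makeDimer(elements = c("O", "O"), r = 1.5, nu = 600)
  tr <- integrateNVE(top, dt = 0.5, nSteps = 4000, Tinit = 300, seed = 8)
  cf <- vvacf(tr, 1)
  sp <- powerSpectrum(cf, window = "none")
  integral <- sum(sp@power) * diff(sp@wavenumbers)[1]
  expect_equal(integral, cf@values[1], tolerance = 1e-8)
  expect_error(powerSpectrum(new("CorrelationFunction", lags = 0, values = 1,
                                 kind = "vvacf", atoms = 1L,
                                 normalization = "raw")), "empty correlation")
})

test_that("thermal wavenumber/temperature conversions match kT arithmetic", {
  expect_equal(round(temperatureToWavenumber(298)), 207)
  expect_equal(round(wavenumberToTemperature(245)), 353)
  expect_equal(round(wavenumberToTemperature(100)), 144)
  expect_equal(wavenumberToTemperature(0), 0)
  expect_equal(temperatureToWavenumber(0), 0)
  nus <- c(1, 50, 207, 3600)
  expect_equal(temperatureToWavenumber(wavenumberToTemperature(nus)), nus,
               tolerance = 1e-14)
  expect_error(wavenumberToTemperature(-1), "negative")
  expect_error(temperatureToWavenumber(-1), "negative")
})

test_that("momentum sum rule holds on NVE trajectories", {
  ## with zero COM momentum, sum_{j != i} C_ij(0) = -C_ii(0)
  top <- fixtureTopology()
  tr <- integrateNVE(top, dt = 0.5, nSteps = 600, Tinit = 298, seed = 17,
                     sampleEvery = 2)
  i <- top@tags$anchor_Fe
  others <- setdiff(seq_len(nAtoms(tr)), i)
  s <- sum(vapply(others, function(j) mmccf(tr, i, j, maxLag = 0)@values[1],
                  numeric(1)))
  cii <- mmccf(tr, i, i, maxLag = 0)@values[1]
  expect_lt(abs(s + cii) / abs(cii), 1e-8)
})

test_that("spectral peaks of small networks match the spring-matrix modes", {
  ## braced 4-atom cluster: every visible peak must coincide with a
  ## mass-weighted Hessian eigenfrequency within one resolution element.
  ## The network must be structurally rigid (no floppy reorientation) and the
  ## run cold enough that the pair springs respond linearly.
  top <- makeTetrahedron()
  modes <- normalModes(top)$wavenumbers
  tr <- integrateNVE(top, dt = 0.5, nSteps = 60000, Tinit = 50, seed = 12,
                     sampleEvery = 2)
  for (atom in 1:4) {
    sp <- powerSpectrum(vvacf(tr, atom, maxLag = 3000), window = "hann",
                        zeroPadFactor = 4)
    peaks <- spectralPeaks(sp)
    expect_gt(length(peaks), 0)
    for (w in peaks)
      expect_lt(min(abs(modes - w)), sp@resolution)
  }
})

test_that("maxLag beyond half the trajectory is rejected", {
  tr <- integrateNVE(makeDimer(), dt = 0.5, nSteps = 100, Tinit = 200,
                     seed = 1)
  expect_error(vvacf(tr, 1, maxLag = 40), "max_lag too long")
})
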