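# Shared fixtures, all generated in code. Expensive objects are memoized for
# the duration of the test run.

.fixtureEnv <- new.env(parent = emptyenv())

memoize <- function(key, builder) {
  if (!exists(key, envir = .fixtureEnv)) assign(key, builder(), .fixtureEnv)
  get(key, envir = .fixtureEnv)
}

kBfix <- 8.31446262e-07       # amu A^2 fs^-2 K^-1
cFix <- 2.99792458e-05        # cm/fs

fixtureCell <- function(f = 0.83) spinelCell(a = 8.3561, u = 0.2549, f = f)

# assembled study system: slab + vacancies + silane + 41 waters (284 atoms)
fixtureAssembledSlab <- function() memoize("slab284", function() {
  slab <- build111Slab(fixtureCell(f = 0.9), thickness = 14,
                       hydroxylCount = 4L, vacuum = 12)
  slab <- assignVacancies(slab, f = 0.9, seed = 11)
  slab <- attachSilane(slab)
  solvate(slab, nWaters = 41, dMin = 2.6, seed = 12)
})

fixtureTopology <- function() memoize("top284", function()
  topologyFromSlab(fixtureAssembledSlab()))

# the production trajectory of the study conditions: 2 ps Langevin
# equilibration at 298 K, then 15 ps NVE continued from the equilibrated
# state (COM motion removed), sampled every 2 fs
fixtureProductionTrajectory <- function() memoize("traj15ps", function() {
  top <- fixtureTopology()
  eq <- integrateLangevin(top, thermostatSpec(298, 0.001, 14), dt = 0.5,
                          nSteps = 4000L, sampleEvery = 4000L)
  top@positions <- eq@positions[, , nFrames(eq)]
  integrateNVE(top, dt = 0.5, nSteps = 30000L, Tinit = 298, seed = 13,
               sampleEvery = 4L, vInit = eq@velocities[, , nFrames(eq)])
})

# ~200-site test cluster
fixtureCluster <- function() memoize("cluster200", function()
  cutSphere(fixtureCell(f = 0.83), D = 1.58))

# a bare topology from explicit parts
makeTopology <- function(elements, positions, springs, tags = list(),
                         box = numeric(0)) {
  new("Topology", elements = elements, masses = nanotherm:::.elementMass(elements),
      positions = positions, springs = springs, tags = tags, box = box)
}

# harmonic dimer with pair wavenumber nu (1/cm)
makeDimer <- function(elements = c("O", "H"), r = 0.96, nu = 3600) {
  m <- nanotherm:::.elementMass(elements)
  mu <- prod(m) / sum(m)
  k <- mu * (2 * pi * cFix * nu)^2
  makeTopology(elements, rbind(c(0, 0, 0), c(r, 0, 0)),
               data.frame(i = 1L, j = 2L, k = k, r0 = r, class = "covalent"))
}

# braced tetrahedral cluster: 4 atoms, 6 edge springs, no floppy internal
# modes, so small-oscillation spectra match the Hessian eigenfrequencies
makeTetrahedron <- function() {
  el <- c("Fe", "O", "O", "Si")
  m <- nanotherm:::.elementMass(el)
  pos <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * 1.1
  pairs <- t(utils::combn(4, 2))
  r0 <- sqrt(rowSums((pos[pairs[, 1], ] - pos[pairs[, 2], ])^2))
  mu <- m[pairs[, 1]] * m[pairs[, 2]] / (m[pairs[, 1]] + m[pairs[, 2]])
  nuP <- c(450, 500, 380, 420, 520, 480)
  makeTopology(el, pos,
               data.frame(i = pairs[, 1], j = pairs[, 2],
                          k = mu * (2 * pi * cFix * nuP)^2, r0 = r0,
                          class = "covalent"))
}

# local maxima above 5% of the strongest peak, away from the DC region
spectralPeaks <- function(sp) {
  p <- sp@power / max(sp@power)
  idx <- which(diff(sign(diff(p))) == -2) + 1
  idx <- idx[p[idx] > 0.05 & sp@wavenumbers[idx] > 2 * sp@resolution]
  sp@wavenumbers[idx]
}

# trajectory object wrapping explicit velocity series (natoms x 3 x nframes)
makeVelocityTrajectory <- function(vel, masses, dt = 1) {
  n <- dim(vel)[1]
  new("Trajectory", dt = dt, positions = array(0, dim(vel)),
      velocities = vel, masses = masses,
      elements = rep("O", n), box = numeric(0), tags = list(), meta = list())
}

# box spectrum: unit power on [lo, hi], zero elsewhere, on a 1 1/cm grid
makeBoxSpectrum <- function(lo, hi, wmax = 500) {
  w <- seq(0, wmax, by = 1)
  new("Spectrum", wavenumbers = w,
      power = as.numeric(w >= lo & w <= hi),
      resolution = 1, window = "none")
}
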