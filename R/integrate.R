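## Velocity-Verlet / Langevin dynamics on the harmonic network.
## Units: angstrom, fs, amu; kB = 8.31446e-7 amu A^2 fs^-2 K^-1.

## pair forces and potential energy for positions `pos` (n x 3)
.springForces <- function(pos, sp, box, n) {
  d <- .mimDisp(pos[sp$i, , drop = FALSE], pos[sp$j, , drop = FALSE], box)
  r <- sqrt(rowSums(d^2))
  u <- d / r
  fmag <- sp$k * (r - sp$r0)        # pull i toward j when stretched
  Fi <- u * fmag
  f <- matrix(0, n, 3)
  agg <- rowsum(rbind(Fi, -Fi), c(sp$i, sp$j))
  f[as.integer(rownames(agg)), ] <- agg
  list(f = f, pe = 0.5 * sum(sp$k * (r - sp$r0)^2))
}

## Maxwell-Boltzmann velocities at T with mass-weighted COM motion removed
.maxwellVelocities <- function(masses, T) {
  n <- length(masses)
  if (T <= 0) return(matrix(0, n, 3))
  v <- matrix(stats::rnorm(3 * n), n, 3) * sqrt(.kB * T / masses)
  vc <- colSums(v * masses) / sum(masses)
  sweep(v, 2, vc)
}

.kineticEnergy <- function(v, masses) 0.5 * sum(masses * rowSums(v^2))

.runDynamics <- function(top, dt, nSteps, sampleEvery, seed, T0,
                         thermostat = NULL, vInit = NULL) {
  n <- length(top@masses)
  sp <- top@springs
  box <- top@box
  m <- top@masses
  sampleIdx <- seq(sampleEvery, nSteps, by = sampleEvery)
  nf <- length(sampleIdx)
  pos <- array(0, c(n, 3, nf)); vel <- array(0, c(n, 3, nf))
  ke <- pe <- numeric(nf)
  .withSeed(seed, {
    x <- top@positions
    v <- if (is.null(vInit)) .maxwellVelocities(m, T0) else vInit
    if (is.null(thermostat) && !is.null(vInit)) {
      ## NVE conserves momentum, so start the production run COM-free
      vc <- colSums(v * m) / sum(m)
      v <- sweep(v, 2, vc)
    }
    fr <- .springForces(x, sp, box, n)
    e0 <- .kineticEnergy(v, m) + fr$pe
    if (!is.null(thermostat)) {
      c1 <- exp(-thermostat@gamma * dt)
      c2 <- sqrt(pmax(1 - c1^2, 0))
      sig <- sqrt(.kB * thermostat@T / m)
    }
    fi <- 0L
    for (step in seq_len(nSteps)) {
      v <- v + (0.5 * dt) * fr$f / m
      if (is.null(thermostat)) {
        x <- x + dt * v
      } else {
        x <- x + (0.5 * dt) * v
        v <- c1 * v + c2 * sig * matrix(stats::rnorm(3 * n), n, 3)
        x <- x + (0.5 * dt) * v
      }
      fr <- .springForces(x, sp, box, n)
      v <- v + (0.5 * dt) * fr$f / m
      if (step %% 250L == 0L) {
        e <- .kineticEnergy(v, m) + fr$pe
        if (!is.finite(e) || e > 1e4 * (abs(e0) + .kB * 300 * n))
          stop("unstable dt: energy blow-up detected at step ", step)
      }
      if (step == sampleIdx[fi + 1L]) {
        fi <- fi + 1L
        pos[, , fi] <- x
        vel[, , fi] <- v
        ke[fi] <- .kineticEnergy(v, m)
        pe[fi] <- fr$pe
        if (fi == nf) sampleIdx <- c(sampleIdx, -1L)  # sentinel
      }
    }
  })
  temp <- 2 * ke / (3 * n * .kB)
  new("Trajectory", dt = dt * sampleEvery, positions = pos, velocities = vel,
      masses = m, elements = top@elements, box = box, tags = top@tags,
      meta = list(dtIntegration = dt, nSteps = nSteps,
                  sampleEvery = sampleEvery, seed = seed, Tinit = T0,
                  thermostat = if (is.null(thermostat)) NULL else
                    list(T = thermostat@T, gamma = thermostat@gamma),
                  energies = data.frame(step = sampleIdx[seq_len(nf)],
                                        kinetic = ke, potential = pe,
                                        temperature = temp)))
}

#' Microcanonical (NVE) dynamics by velocity Verlet
#'
#' Integrates the harmonic network with the velocity-Verlet scheme. Initial
#' velocities are Maxwell-Boltzmann at `Tinit` with center-of-mass momentum
#' removed; a `Tinit` of zero from the equilibrium geometry yields a static
#' trajectory. An energy guard aborts on blow-up from an unstable timestep.
#'
#' @param top a [Topology-class]
#' @param dt timestep (fs); keep dt * omega_max well below the Verlet
#'   stability limit (a guideline is dt * omega_max < 0.1 for high accuracy)
#' @param nSteps number of integration steps
#' @param Tinit initial temperature (K)
#' @param seed integer seed for the initial velocities
#' @param sampleEvery store every this-many steps
#' @param vInit optional nAtoms x 3 matrix of initial velocities (angstrom/fs),
#'   e.g. the final frame of an equilibration run; overrides the
#'   Maxwell-Boltzmann draw
#' @return a [Trajectory-class]; per-frame energies are in `meta$energies`
#' @export
integrateNVE <- function(top, dt = 0.5, nSteps = 1000L, Tinit = 298,
                         seed = 1L, sampleEvery = 1L, vInit = NULL) {
  stopifnot(is(top, "Topology"))
  if (dt <= 0) stop("dt must be > 0")
  .runDynamics(top, dt, as.integer(nSteps), as.integer(sampleEvery), seed,
               Tinit, vInit = vInit)
}

#' Langevin thermostat specification
#'
#' @param T target temperature (K)
#' @param gamma friction coefficient (1/fs)
#' @param seed integer seed for the noise stream
#' @return a [ThermostatSpec-class]
#' @export
thermostatSpec <- function(T = 298, gamma = 0.001, seed = 1L) {
  new("ThermostatSpec", T = T, gamma = gamma, seed = seed)
}

#' Canonical (NVT) dynamics by BAOAB Langevin integration
#'
#' Integrates the harmonic network with the BAOAB splitting of Langevin
#' dynamics: half kick, half drift, Ornstein-Uhlenbeck velocity update, half
#' drift, half kick. After equilibration the time-averaged kinetic
#' temperature matches the thermostat target within sampling error. Runs are
#' bit-reproducible for identical seeds.
#'
#' @param top a [Topology-class]
#' @param thermo a [ThermostatSpec-class]
#' @param dt timestep (fs)
#' @param nSteps number of integration steps
#' @param Tinit initial temperature (K); defaults to the thermostat target
#' @param sampleEvery store every this-many steps
#' @return a [Trajectory-class]
#' @export
integrateLangevin <- function(top, thermo = thermostatSpec(), dt = 0.5,
                              nSteps = 1000L, Tinit = thermo@T,
                              sampleEvery = 1L) {
  stopifnot(is(top, "Topology"), is(thermo, "ThermostatSpec"))
  if (dt <= 0) stop("dt must be > 0")
  if (thermo@gamma <= 0) stop("gamma must be > 0 for Langevin dynamics")
  .runDynamics(top, dt, as.integer(nSteps), as.integer(sampleEvery),
               thermo@seed, Tinit, thermostat = thermo)
}
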