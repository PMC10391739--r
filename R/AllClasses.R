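#' @import methods
NULL

.siteClasses <- c("tet_Fe", "oct_Fe", "lattice_O", "hydroxyl_O", "hydroxyl_H",
                  "organic", "water")
.knownElements <- c("Fe", "O", "H", "Si", "C", "N")

## shared validity for an atom table: element, x, y, z, occupancy, siteClass
.validAtoms <- function(atoms) {
  need <- c("element", "x", "y", "z", "occupancy", "siteClass")
  if (!is.data.frame(atoms)) return("'atoms' must be a data.frame")
  if (!all(need %in% names(atoms)))
    return(paste("atoms table needs columns:", paste(need, collapse = ", ")))
  if (nrow(atoms) == 0L) return(TRUE)
  if (!all(atoms$element %in% .knownElements))
    return("element must be one of Fe, O, H, Si, C, N")
  if (!all(atoms$siteClass %in% .siteClasses))
    return("unknown siteClass label")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    return("non-finite coordinates")
  if (any(atoms$occupancy <= 0 | atoms$occupancy > 1))
    return("occupancy must be in (0, 1]")
  TRUE
}

#' Cubic Fd-3m spinel cell description
#'
#' Describes a vacancy-disordered spinel iron oxide in space group Fd-3m
#' (origin choice 2): cell edge `a`, oxygen 32e positional parameter `u`, and
#' the octahedral (16d) site occupancy factor `f`. One unit cell realizes 8
#' tetrahedral (8a) sites, 16 octahedral (16d) sites and 32 oxygen (32e)
#' sites, so the stoichiometry is Fe\eqn{_{1+2f}}O\eqn{_4}.
#'
#' @slot a cell edge length (angstrom)
#' @slot u oxygen positional parameter (dimensionless, 0 < u < 0.5)
#' @slot f octahedral site occupancy factor in (0, 1]
#' @slot originChoice label for the Fd-3m origin setting
#' @export
setClass("SpinelCell",
  representation(a = "numeric", u = "numeric", f = "numeric",
                 originChoice = "character"),
  prototype(a = 8.3561, u = 0.2549, f = 5/6, originChoice = "2"),
  validity = function(object) {
    if (length(object@a) != 1L || object@a <= 0) return("a must be > 0")
    if (length(object@u) != 1L || object@u <= 0 || object@u >= 0.5)
      return("u must be in (0, 0.5)")
    if (length(object@f) != 1L || object@f <= 0 || object@f > 1)
      return("f must be in (0, 1]")
    TRUE
  })

#' Explicit-atom nanocrystal model
#'
#' An explicit list of atomic sites (element, Cartesian coordinates in
#' angstrom, occupancy, site class) for a finite spinel nanocrystal, together
#' with its nominal diameter and the generating cell.
#'
#' @slot atoms data.frame with columns element, x, y, z, occupancy, siteClass
#' @slot diameter nominal sphere diameter (nm); NA for non-spherical models
#' @slot cell the generating [SpinelCell-class]
#' @export
setClass("NanocrystalModel",
  representation(atoms = "data.frame", diameter = "numeric",
                 cell = "SpinelCell"),
  validity = function(object) {
    ok <- .validAtoms(object@atoms)
    if (!isTRUE(ok)) return(ok)
    if (length(object@diameter) != 1L) return("diameter must be length 1")
    if (!is.na(object@diameter) && object@diameter < 0)
      return("diameter must be >= 0")
    TRUE
  })

#' Functionalized (111) slab model
#'
#' An orthorhombic surface supercell exposing the (111) facet, with explicit
#' atoms and bookkeeping of bonded fragments (hydroxyls, silane) attached to
#' surface iron atoms. For a 1x1 (111) orthorhombic surface cell the in-plane
#' edges satisfy Lx = a*sqrt(3/2), Ly = a*sqrt(2).
#'
#' @slot box orthorhombic edges c(Lx, Ly, Lz) in angstrom
#' @slot atoms data.frame with columns element, x, y, z, occupancy, siteClass
#' @slot attachments list of records: list(kind, anchor, fragment) with atom
#'   row indices into `atoms`
#' @slot cell the generating [SpinelCell-class]
#' @export
setClass("SlabModel",
  representation(box = "numeric", atoms = "data.frame", attachments = "list",
                 cell = "SpinelCell"),
  validity = function(object) {
    if (length(object@box) != 3L || any(object@box <= 0))
      return("box must be 3 positive edge lengths")
    ok <- .validAtoms(object@atoms)
    if (!isTRUE(ok)) return(ok)
    n <- nrow(object@atoms)
    for (att in object@attachments) {
      if (!all(c("kind", "anchor", "fragment") %in% names(att)))
        return("attachment records need kind, anchor, fragment")
      if (any(c(att$anchor, att$fragment) > n) ||
          any(c(att$anchor, att$fragment) < 1L))
        return("attachment indices out of range")
    }
    TRUE
  })

#' Target geometry of the Fe-O-Si silane bridge
#'
#' Build targets for [attachSilane()]: the Fe-O and O-Si bond lengths and the
#' Fe-O-Si bridge angle.
#'
#' @slot rFeO Fe-O bond target (angstrom)
#' @slot rOSi O-Si bond target (angstrom)
#' @slot angleFeOSi bridge angle target (degrees), in (90, 180)
#' @export
setClass("SilaneGeometry",
  representation(rFeO = "numeric", rOSi = "numeric", angleFeOSi = "numeric"),
  prototype(rFeO = 1.91, rOSi = 1.62, angleFeOSi = 138),
  validity = function(object) {
    if (object@rFeO <= 0 || object@rOSi <= 0) return("bond targets must be > 0")
    if (object@angleFeOSi <= 90 || object@angleFeOSi >= 180)
      return("angleFeOSi must be in (90, 180) degrees")
    TRUE
  })

#' Log-normal nanocrystal size distribution
#'
#' Number-based log-normal distribution of sphere diameters, truncated at
#' `Dmax`. Parameterized by the number-based mean and standard deviation
#' (`meanN`, `sdN` in nm) of the *untruncated* log-normal; the log-parameters
#' (mu, sigma) are available via [logParams()].
#'
#' @slot meanN number-based mean diameter (nm)
#' @slot sdN number-based standard deviation (nm)
#' @slot Dmax truncation diameter (nm)
#' @export
setClass("SizeDistribution",
  representation(meanN = "numeric", sdN = "numeric", Dmax = "numeric"),
  validity = function(object) {
    if (object@meanN <= 0 || object@sdN <= 0) return("meanN, sdN must be > 0")
    if (object@Dmax <= object@meanN) return("Dmax must exceed meanN")
    TRUE
  })

#' Powder total-scattering pattern
#'
#' Intensity I(q) on a strictly increasing q-grid (inverse angstrom), with a
#' metadata list recording the generating parameters.
#'
#' @slot q scattering-vector grid (1/angstrom), strictly increasing, > 0
#' @slot I intensity per q (arbitrary units)
#' @slot meta list of generating parameters
#' @export
setClass("ScatteringPattern",
  representation(q = "numeric", I = "numeric", meta = "list"),
  validity = function(object) {
    if (length(object@q) != length(object@I)) return("q and I lengths differ")
    if (length(object@q) && (any(object@q <= 0) || any(diff(object@q) <= 0)))
      return("q must be positive and strictly increasing")
    if (any(!is.finite(object@I))) return("non-finite intensities")
    TRUE
  })

#' Pattern refinement result
#'
#' @slot par named list of refined parameters (scale, a, f, meanN, sdN)
#' @slot residual goodness-of-fit value (sum of squared residuals), >= 0
#' @slot converged logical convergence flag
#' @slot meta list with optimizer details
#' @export
setClass("FitResult",
  representation(par = "list", residual = "numeric", converged = "logical",
                 meta = "list"),
  validity = function(object) {
    if (object@residual < 0) return("residual must be >= 0")
    TRUE
  })

#' Harmonic oscillator-network topology
#'
#' Atoms (element, mass, equilibrium position) connected by harmonic springs,
#' with named atom tag sets and an optional orthorhombic box. The classical
#' stand-in for the quantum force field: springs are created per pair class
#' (covalent, Fe-O lattice, hydrogen bond) by [topologyFromSlab()].
#'
#' @slot elements character vector of chemical symbols
#' @slot masses atomic masses (amu)
#' @slot positions N x 3 matrix of equilibrium positions (angstrom)
#' @slot springs data.frame with columns i, j, k (amu/fs^2), r0 (angstrom),
#'   class
#' @slot tags named list of integer atom-index vectors
#' @slot box orthorhombic edges (angstrom) or numeric(0) for no box
#' @export
setClass("Topology",
  representation(elements = "character", masses = "numeric",
                 positions = "matrix", springs = "data.frame",
                 tags = "list", box = "numeric"),
  validity = function(object) {
    n <- length(object@elements)
    if (length(object@masses) != n || nrow(object@positions) != n)
      return("elements, masses, positions sizes differ")
    if (any(object@masses <= 0)) return("masses must be > 0")
    s <- object@springs
    if (nrow(s)) {
      if (!all(c("i", "j", "k", "r0") %in% names(s)))
        return("springs need columns i, j, k, r0")
      if (any(s$k <= 0)) return("spring constants must be > 0")
      if (any(s$i < 1 | s$i > n | s$j < 1 | s$j > n | s$i == s$j))
        return("spring endpoints out of range")
    }
    for (tg in object@tags)
      if (any(tg < 1L | tg > n)) return("tag indices out of range")
    if (!length(object@box) %in% c(0L, 3L)) return("box must be length 0 or 3")
    TRUE
  })

#' Atomistic trajectory with velocities
#'
#' Time series of positions and velocities for a fixed set of atoms.
#' Positions are in angstrom, velocities in angstrom/fs; `dt` is the frame
#' spacing in fs.
#'
#' @slot dt frame spacing (fs)
#' @slot positions array of dim c(nAtoms, 3, nFrames)
#' @slot velocities array of dim c(nAtoms, 3, nFrames)
#' @slot masses atomic masses (amu)
#' @slot elements chemical symbols
#' @slot box orthorhombic edges (angstrom) or numeric(0)
#' @slot tags named list of integer atom-index vectors
#' @slot meta list (integrator settings, seeds, energies, temperature)
#' @export
setClass("Trajectory",
  representation(dt = "numeric", positions = "array", velocities = "array",
                 masses = "numeric", elements = "character", box = "numeric",
                 tags = "list", meta = "list"),
  validity = function(object) {
    if (object@dt <= 0) return("dt must be > 0")
    dp <- dim(object@positions); dv <- dim(object@velocities)
    if (length(dp) != 3L || !identical(dp, dv))
      return("positions/velocities must be c(nAtoms, 3, nFrames) arrays")
    if (dp[2] != 3L) return("second dim must be 3")
    if (dp[1] != length(object@masses)) return("masses length != nAtoms")
    if (any(!is.finite(object@positions))) return("non-finite coordinates")
    TRUE
  })

#' Langevin thermostat specification
#'
#' @slot T target temperature (K), >= 0
#' @slot gamma friction (1/fs), >= 0
#' @slot seed integer seed for the noise stream
#' @export
setClass("ThermostatSpec",
  representation(T = "numeric", gamma = "numeric", seed = "numeric"),
  validity = function(object) {
    if (object@T < 0) return("T must be >= 0")
    if (object@gamma < 0) return("gamma must be >= 0")
    TRUE
  })

#' Lagged time-correlation function
#'
#' VVACF or MMCCF values on a uniform lag grid starting at zero.
#'
#' @slot lags time grid (fs), starting at 0, uniform spacing
#' @slot values correlation value per lag
#' @slot kind "vvacf" or "mmccf"
#' @slot atoms integer index (vvacf) or index pair (mmccf)
#' @slot normalization "raw" or "normalized-at-zero"
#' @export
setClass("CorrelationFunction",
  representation(lags = "numeric", values = "numeric", kind = "character",
                 atoms = "integer", normalization = "character"),
  validity = function(object) {
    if (length(object@lags) != length(object@values))
      return("lags and values lengths differ")
    if (length(object@lags)) {
      if (object@lags[1] != 0) return("lags must start at 0")
      if (length(object@lags) > 2 &&
          diff(range(diff(object@lags))) > 1e-9 * object@lags[2])
        return("lags must be uniformly spaced")
    }
    if (!object@kind %in% c("vvacf", "mmccf")) return("kind must be vvacf/mmccf")
    if (object@kind == "vvacf" && length(object@values) &&
        object@values[1] < 0) return("vvacf at lag 0 must be >= 0")
    TRUE
  })

#' One-sided vibrational power spectrum
#'
#' @slot wavenumbers grid (1/cm), non-negative, increasing
#' @slot power spectral density per wavenumber
#' @slot resolution spectral resolution 1/(c * T_corr) (1/cm)
#' @slot window window label ("hann" or "none")
#' @export
setClass("Spectrum",
  representation(wavenumbers = "numeric", power = "numeric",
                 resolution = "numeric", window = "character"),
  validity = function(object) {
    if (length(object@wavenumbers) != length(object@power))
      return("wavenumbers and power lengths differ")
    if (length(object@wavenumbers) &&
        (any(object@wavenumbers < 0) || any(diff(object@wavenumbers) <= 0)))
      return("wavenumbers must be >= 0 and increasing")
    if (any(!is.finite(object@power))) return("non-finite power")
    TRUE
  })

#' Wavenumber band
#'
#' @slot lo lower bound (1/cm), >= 0
#' @slot hi upper bound (1/cm), > lo
#' @export
setClass("Band",
  representation(lo = "numeric", hi = "numeric"),
  validity = function(object) {
    if (object@lo < 0 || object@hi <= object@lo)
      return("need 0 <= lo < hi")
    TRUE
  })

#' Resonance overlap report
#'
#' Per-pair spectral overlap coefficients and band-power fractions in a
#' wavenumber band, with trajectory provenance.
#'
#' @slot band the [Band-class] analyzed
#' @slot entries data.frame: pair label, atom indices, VVACF overlap
#'   coefficient in [0,1], band-power fraction of each spectrum, MMCCF band
#'   fraction
#' @slot provenance list of trajectory metadata
#' @export
setClass("OverlapReport",
  representation(band = "Band", entries = "data.frame", provenance = "list"),
  validity = function(object) {
    e <- object@entries
    if (nrow(e)) {
      num <- intersect(c("vvacfOverlap", "bandFraction1", "bandFraction2",
                         "mmccfBandFraction"), names(e))
      for (cl in num) {
        v <- e[[cl]]
        if (any(v < -1e-9 | v > 1 + 1e-9)) return("coefficients must be in [0,1]")
      }
    }
    TRUE
  })
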