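---
title: "Modelling resonant heat transfer from functionalized maghemite nanoparticles"
author: "nanotherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling resonant heat transfer from functionalized maghemite nanoparticles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

Magnetic iron oxide nanoparticles heat their surroundings when driven by an
alternating magnetic field, and the heating is strictly local — it fades
within a few nanometers of the particle surface, faster than Fourier
diffusion predicts. `nanotherm` implements a two-stage computational account
of how that heat leaves the particle:

1. **Characterize the particles.** Wide-angle X-ray total scattering of
   colloidal iron oxide nanocrystals is modelled with the Debye scattering
   equation over an explicit-atom population of spherical nanocrystals,
   refining the cubic cell edge, the octahedral-site occupancy (the handle on
   the magnetite-to-maghemite composition series Fe$_x$O$_4$), and a
   log-normal size distribution.

2. **Analyze the interface dynamics.** A maghemite (111) slab functionalized
   with a protonated aminodialkoxysilane and solvated by water is the model
   interface. Linear response theory connects its equilibrium dynamics to its
   response to a weak periodic drive: velocity–velocity autocorrelation
   functions (VVACF) give per-atom vibrational power spectra, and
   momentum–momentum cross-correlation functions (MMCCF) indicate at which
   frequencies momentum is exchanged between two atoms. If the power spectra
   of an iron cation and a distant tether or solvent atom overlap in the
   thermally populated band around $k_BT$ (207 cm$^{-1}$ at 298 K), energy
   can flow between them by resonance.

## Stage one: spinel crystallography and the Debye engine

### Vacancy-disordered spinel arithmetic

The spinel cell (space group $Fd\bar 3m$, origin choice 2) has 8 tetrahedral
(8a), 16 octahedral (16d) and 32 oxygen (32e) sites. With full tetrahedral
occupancy and octahedral occupancy $f$ the stoichiometry is
$x = 1 + 2f$ iron per 4 oxygen; charge balance with all Fe$^{3+}$ forces
$f = 5/6$ (maghemite, Fe$_{8/3}$O$_4$), while $f = 1$ is magnetite. These
one-line relations (`xFromSof`, `sofFromX`, `maghemiteSof`, `xFromCounts`)
carry the composition bookkeeping for both stages. The default oxygen
parameter $u = 0.2549$ is the standard magnetite refinement value; it is
configurable and only weakly affects any reported quantity.

### Debye intensities

For a finite cluster the orientation-averaged intensity is
$$ I(q) = \sum_i o_i f_i^2(q)
  + 2 \sum_{i<j} o_i o_j f_i(q) f_j(q) \frac{\sin q r_{ij}}{q r_{ij}}, $$
with occupancies $o_i$ and International-Tables 4-Gaussian form factors.
Vacancy disorder enters the forward model deterministically through
occupancy-weighted form factors; a test verifies that this equals the seed
average over explicit vacancy realizations within Monte-Carlo error.

Two numerical choices matter:

* **Weighted-centroid binning.** Histogram mode bins pair distances, but a
  crystal's pair distances are discrete, so representing a bin by its center
  leaves a first-order phase error $q\,\delta r$. Each bin therefore stores
  the occupancy-weighted *mean* distance of its pairs, which collapses the
  error to below $10^{-5}$ relative at a 0.01 Å bin — against a brute-force
  double sum on a ~200-atom cluster — while keeping the
  $O(N^2) \to O(N_{\mathrm{bins}})$ speedup.

* **Finite-coherence approximation for large spheres.** A 40 nm sphere holds
  ~2 million atoms; enumerating its pairs is pointless for a desk-scale
  package. Diameter classes above `exactMaxD` (default 4.5 nm) use the bulk
  per-cell pair histogram out to a coherence radius (default 110 Å), scaled
  by the cell count and the sphere autocorrelation
  $\gamma(r/D) = 1 - \tfrac32 (r/D) + \tfrac12 (r/D)^3$. This reproduces the
  exact pattern to a few percent at the crossover diameter and preserves
  Scherrer narrowing up to roughly the coherence radius; classes much larger
  than it show resolution-limited rather than true peak widths. The
  number-weighted class weights themselves are always exact.

### Population patterns and refinement

`populationPattern` sums per-diameter patterns over a log-spaced,
$D_{max}$-truncated (default 40 nm) discretized log-normal, number-weighted
and normalized. `massMoments` integrates the $D^3$-weighted distribution
numerically; for the study distribution (number mean 2.1 nm, sd 1.9 nm,
truncated at 40 nm) the mass-based mean and spread land near 11.3 and
7.8 nm.

`fitPattern` refines $\{$scale, $a$, $f$, mean, sd$\}$ by bounded
Levenberg–Marquardt least squares with the scale profiled out analytically.
The forward model is cached once per fit: per diameter class, pair histograms
are split by site-class pair (8a–8a, 8a–16d, …), so the occupancy enters as
analytic weights ($1, f, f^2$) and the cell edge as a pure distance scaling.
Cluster membership is frozen at the initial cell edge; since $a$ moves by
well under a percent, the membership error is far below the fit tolerances.
Noiseless self-consistency experiments recover $a$ to 0.02%, $f$ to 0.015
and the mean diameter to 0.2%; with 2% multiplicative noise and three random
restarts the recovery stays within 2% / 0.05.

## Stage two: the interface model and its dynamics

### Building the slab

The (111) surface supercell is orthorhombic with
$L_x = a\sqrt{3/2} = 10.234$ Å and $L_y = a\sqrt2 = 11.817$ Å for
$a = 8.3561$ Å. Along the normal, spinel (111) stacking alternates kagome
octahedral layers, close-packed O layers and mixed tet–oct–tet layers every
$a/\sqrt3$. No stack of complete layers reproduces the target oxide
composition (76 lattice O is not a multiple of the 16-per-layer O density),
so the builder terminates the slab with reduced-occupancy surfaces — the
bottom kagome layer keeps 2/3 of its sites and the top O layer 3/4, the
usual stabilization of polar spinel (111) terminations — selected by a
deterministic farthest-point rule. With the default 14 Å thickness budget
this realizes exactly 16 tetrahedral Fe, 40 octahedral Fe and 76 O spanning
10.8 Å.

Four hydroxyls go to the most exposed Fe; four octahedral vacancies are drawn
by seeded rejection sampling with a minimum vacancy–vacancy separation of
$a\sqrt2/4$ (the nearest 16d–16d contact — "no adjacent vacancies" is the
minimal reading of avoided close contacts), giving the
[Fe$_{52}$O$_{76}$(OH)$_4$] oxide, i.e. Fe$_{2.60}$O$_4$. The
aminodialkoxysilane is attached through a *new* bridging oxygen placed at
the Fe–O = 1.91 Å, O–Si = 1.62 Å, Fe–O–Si = 138° build targets: counting the
bridge O as an added atom is the only bookkeeping consistent with the
assembled tally of 284 atoms (52 Fe, 124 O, 101 H, 1 N, 5 C, 1 Si) once 41
rigid waters are placed in the solvent gap by seeded rejection sampling
(minimum heavy-atom distance 2.6 Å). The 26 Å box height follows from the
14 Å thickness budget plus a 12 Å solvent gap.

### The harmonic-network stand-in

The reference dynamics for this interface is first-principles molecular
dynamics, which is out of reach for a reusable test bed. The synthetic
generator replaces it with a harmonic pair-spring network built from the
assembled geometry: covalent bonds, Fe–O lattice contacts and
O–H$\cdots$O / N–H$\cdots$O hydrogen bonds, each class with a distance
window and a characteristic pair wavenumber (Fe–O 400, hydrogen bonds 180,
O–H 3600, N–H 3300, C–H 2950 cm$^{-1}$, …). Spring constants are
$k = \mu\omega^2$ with the pair reduced mass, and rest lengths equal the
as-built distances, so the built geometry is the network's equilibrium.
These values place the characteristic bands in physically sensible infrared
ranges; they are configuration, not a fitted force field, and the spectra
they produce are not claimed to reproduce the quantum reference line shapes.
What the network *does* reproduce — by construction of its physics, not by
tuning — is the feature the resonance argument needs: iron cations (through
the soft lattice and hydrogen-bond contacts) and the tether and water atoms
all populate the low-frequency region around $k_BT$.

What the generator deliberately omits: anharmonic force fields (a cubic bond
option exists but is off by default), bond making/breaking, angular terms
(chains are transversely floppy), electrostatics and spin. Passing tests
therefore validate the estimators and the resonance machinery, not any
quantitative prediction about real maghemite interfaces.

### Integration

Velocity Verlet (NVE) and the BAOAB splitting of Langevin dynamics (NVT)
integrate the network at a default 0.5 fs timestep. All stochastic entry
points take explicit seeds and are bit-reproducible. Initial velocities are
Maxwell–Boltzmann with the center-of-mass motion removed; production runs
continue from the Langevin-equilibrated state (positions and velocities,
COM-free). Energy drift — measured as the difference between time-averaged
total energy in the first and last windows, the meaningful quantity for a
symplectic integrator whose instantaneous energy merely oscillates — stays
below $10^{-4}$ relative over $10^5$ steps on the full 284-atom network.
NVE mean temperatures fluctuate seed-to-seed by the expected
$T\sqrt{2/3N} \approx 14$ K because the conserved energy is drawn once at
equilibration.

## The spectral engine

Correlation estimators use FFT cross-correlation with a masked origin set:
origins are spaced by `originStride` and restricted so every origin has all
lags, which makes analytic cases (a cosine velocity, coupled oscillators)
exact over full periods. The default maximum lag is half the trajectory.
Power spectra come from the even extension of the (Hann-windowed, optionally
zero-padded) correlation; with no window the spectrum integrates back to
$C(0)$ exactly (Parseval), and the resolution is $1/(c\,T_{corr})$ — about
2.2 cm$^{-1}$ for a 15 ps span.

The MMCCF is reported in two modes. Dot mode,
$C_{ij}(t) = \langle \mathbf p_i(t_0{+}t)\cdot\mathbf p_j(t_0)\rangle$, is
the default and the unambiguous reading. A "projection on the momentum of
the other atom" phrasing admits a second reading; restoring the reference
magnitude to the projected component makes it algebraically identical to dot
mode, so the projection mode implemented here is the magnitude-free variant
$\langle \mathbf p_i(t_0{+}t)\cdot\hat{\mathbf p}_j(t_0)\rangle$. Which
normalization the original analysis used is not decidable from its
description; all band metrics in this package use dot mode.

Two validated invariants anchor the engine: the momentum sum rule
$\sum_{j\ne i} C_{ij}(0) = -C_{ii}(0)$ on COM-free NVE runs (exact to
$10^{-8}$), and normal-mode recovery — every spectral peak of a small
network matches a mass-weighted Hessian eigenfrequency within one resolution
element. The latter holds in the linear-response regime it describes:
structurally rigid (braced) networks at low amplitude. Stretch-only chains
are *not* such networks — their floppy transverse modes let the geometry
reorient until the springs decouple, a real nonlinear effect, not an
estimator artifact — so the tests use braced clusters at 50 K.

## Resonance metrics

`bandFraction` integrates the spectrum magnitude over a band relative to the
whole range. `spectralOverlap` quantifies the qualitative "the spectra
overlap" argument as the cosine similarity of band-restricted spectra after
resampling to the finer grid: symmetric, scale-invariant, 1 exactly for
proportional spectra. This bounded coefficient is this package's own
quantification; no threshold for "significant" overlap is implied, and the
analysis band 100–350 cm$^{-1}$ (containing $k_BT$ at 298 K) is the default
everywhere. On the default synthetic trajectory the anchor-Fe/amine-N VVACF
overlap in the thermal band exceeds their overlap in the 2000–3000 cm$^{-1}$
region by roughly a factor of two, mirroring the covalent-channel resonance
finding; the subsurface-Fe/water-O pair shows the same ordering through the
hydrogen-bond network.

## Problem sizes and reproducibility

The shipped defaults are the study conditions: cell edge 8.3561 Å, pattern
occupancy 0.83, the 284-atom solvated interface, 298 K, and a 15 ps
production trajectory (2 ps equilibration), which runs in well under a
minute on one CPU. Scattering defaults use a 0.5–12 Å$^{-1}$ grid at
0.005 Å$^{-1}$, 40 size classes to 40 nm with the finite-coherence
approximation above the exact-enumeration crossover. Fit experiments in the
tests use a smaller population (mean 2 nm, sd 0.5 nm, truncated at 5 nm, 14
classes) — chosen as a desk-scale self-consistency design, since the fitted
values for the real samples required synchrotron data that has no deposited
accession. Every stochastic stage (vacancies, solvation, velocities,
thermostat, restarts) takes an explicit seed, and `runPipeline` writes a
manifest recording all of them alongside a hash of the configuration.

## Known limitations

* The harmonic network is a stand-in: no quantum effects, no anharmonic
  line shifts, no hydrogen-bond breaking, no spin or magnetization physics.
* The finite-coherence scattering approximation saturates peak widths for
  diameters far beyond the coherence radius.
* The (111) termination reproduces the documented composition but the
  original surface cut is not uniquely specified by it.
* MMCCF "projection" normalization is ambiguous in prose descriptions; both
  implemented modes are documented, dot mode is canonical here.
* Mass-based size moments depend on the truncation and weighting convention;
  the implemented convention ($D^3$-weighted, truncated numerical
  integration) lands near, but is not calibrated to, tabulated values.
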