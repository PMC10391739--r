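# Physical constants and crystallographic/tabulated data used across modules.
#
# Internal unit system: length in angstrom (A), time in fs, mass in amu.
# Energy unit is then amu * A^2 / fs^2 (= 1.66054e-17 J).

## Boltzmann constant in amu A^2 fs^-2 K^-1
.kB <- 8.31446262e-07

## speed of light in cm / fs (for wavenumber axes)
.c_cm_fs <- 2.99792458e-05

## second radiation constant hc/kB in cm K: maps wavenumber to temperature
.c2_cmK <- 1.4387769

## atomic masses (amu), IUPAC 2021 standard weights
.atomicMasses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   Si = 28.085, Fe = 55.845)

.elementMass <- function(element) {
  m <- .atomicMasses[element]
  if (anyNA(m)) stop("unknown element(s): ",
                     paste(unique(element[is.na(m)]), collapse = ", "))
  unname(m)
}

## International Tables vol. C (1992) 4-Gaussian + constant X-ray form factor
## coefficients f(q) = sum_i a_i exp(-b_i (q/4pi)^2) + c for neutral atoms.
.formFactorTable <- list(
  H  = list(a = c(0.493002, 0.322912, 0.140191, 0.040810),
            b = c(10.5109, 26.1257, 3.14236, 57.7997), c = 0.003038),
  C  = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
            b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N  = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
            b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.5290),
  O  = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
            b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  Si = list(a = c(6.29150, 3.03530, 1.98910, 1.54100),
            b = c(2.43860, 32.3337, 0.678500, 81.6937), c = 1.14070),
  Fe = list(a = c(11.7695, 7.35730, 3.52220, 2.30450),
            b = c(4.76110, 0.307200, 15.3535, 76.8805), c = 1.03690)
)

## Fd-3m (no. 227, origin choice 2) Wyckoff orbits for the spinel structure.
## 8a: tetrahedral cations; 16d: octahedral cations; 32e: oxygen, affine in
## the positional parameter u (fractional coordinate = sign * u + offset).
.wyckoff8a <- matrix(c(
  0.125, 0.125, 0.125,  0.125, 0.625, 0.625,  0.375, 0.375, 0.875,
  0.375, 0.875, 0.375,  0.625, 0.125, 0.625,  0.625, 0.625, 0.125,
  0.875, 0.375, 0.375,  0.875, 0.875, 0.875), ncol = 3, byrow = TRUE)

.wyckoff16d <- matrix(c(
  0.00, 0.00, 0.50,  0.00, 0.25, 0.75,  0.00, 0.50, 0.00,  0.00, 0.75, 0.25,
  0.25, 0.00, 0.75,  0.25, 0.25, 0.50,  0.25, 0.50, 0.25,  0.25, 0.75, 0.00,
  0.50, 0.00, 0.00,  0.50, 0.25, 0.25,  0.50, 0.50, 0.50,  0.50, 0.75, 0.75,
  0.75, 0.00, 0.25,  0.75, 0.25, 0.00,  0.75, 0.50, 0.75,  0.75, 0.75, 0.50),
  ncol = 3, byrow = TRUE)

.wyckoff32eSign <- matrix(c(
   1, 1,-1,  1,-1, 1,  1, 1,-1,  1,-1, 1, -1, 1, 1, -1,-1,-1, -1, 1, 1, -1,-1,-1,
   1, 1, 1,  1,-1,-1,  1, 1, 1,  1,-1,-1, -1, 1,-1, -1,-1, 1, -1, 1,-1, -1,-1, 1,
   1, 1,-1,  1,-1, 1,  1, 1,-1,  1,-1, 1, -1, 1, 1, -1,-1,-1, -1, 1, 1, -1,-1,-1,
   1, 1, 1,  1,-1,-1,  1, 1, 1,  1,-1,-1, -1, 1,-1, -1,-1, 1, -1, 1,-1, -1,-1, 1),
  ncol = 3, byrow = TRUE)

.wyckoff32eOffset <- matrix(c(
  0.75,0.75,0.00, 0.75,0.50,0.25, 0.75,0.25,0.50, 0.75,0.00,0.75,
  0.50,0.75,0.25, 0.50,0.50,0.00, 0.50,0.25,0.75, 0.50,0.00,0.50,
  0.00,0.00,0.00, 0.00,0.75,0.75, 0.00,0.50,0.50, 0.00,0.25,0.25,
  0.75,0.00,0.75, 0.75,0.75,0.00, 0.75,0.50,0.25, 0.75,0.25,0.50,
  0.25,0.75,0.50, 0.25,0.50,0.75, 0.25,0.25,0.00, 0.25,0.00,0.25,
  0.00,0.75,0.75, 0.00,0.50,0.50, 0.00,0.25,0.25, 0.00,0.00,0.00,
  0.50,0.00,0.50, 0.50,0.75,0.25, 0.50,0.50,0.00, 0.50,0.25,0.75,
  0.25,0.00,0.25, 0.25,0.75,0.50, 0.25,0.50,0.75, 0.25,0.25,0.00),
  ncol = 3, byrow = TRUE)

## fractional coordinates of the 32e oxygen orbit for a given u
.oxygenOrbit <- function(u) (.wyckoff32eSign * u + .wyckoff32eOffset) %% 1

## Run `expr` with a private, seeded RNG stream; the caller's RNG state is
## untouched. All stochastic builders funnel through this.
.withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
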