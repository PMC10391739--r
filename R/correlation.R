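## Linear-response spectral engine: VVACF / MMCCF estimators, power spectra,
## and thermal wavenumber/temperature conversions.

## Masked-origin cross-correlation via FFT:
## C(t) = (1/nOrigins) sum_{t0 in origins} ref(t0) * lead(t0 + t), t = 0..L.
## Origins are 1, 1+stride, ... up to N - L, so every origin has all lags.
.maskedCrossCorr <- function(lead, ref, L, stride) {
  N <- length(lead)
  M <- N - L
  if (M < 1) stop("max_lag too long: insufficient sampling")
  origins <- seq(1L, M, by = stride)
  mask <- numeric(N)
  mask[origins] <- 1
  np <- stats::nextn(N + L + 1L)
  fa <- stats::fft(c(ref * mask, numeric(np - N)))
  fb <- stats::fft(c(lead, numeric(np - N)))
  cc <- Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / np
  cc[1:(L + 1L)] / length(origins)
}

.lagCount <- function(traj, maxLag) {
  N <- nFrames(traj)
  Lhalf <- floor(N / 2)
  if (is.null(maxLag)) return(Lhalf)
  L <- round(maxLag / traj@dt)
  if (L > N - 1 || N - L < 1 || L > Lhalf)
    stop("max_lag too long: insufficient sampling (", maxLag, " fs vs ",
         N * traj@dt, " fs trajectory)")
  as.integer(L)
}

#' Velocity-velocity autocorrelation function
#'
#' C(t) = < v(t0 + t) . v(t0) >, averaged over time origins t0 taken every
#' `originStride` frames, with the three Cartesian components summed. The
#' Fourier transform of the VVACF ([powerSpectrum()]) gives the atom's
#' vibrational power spectrum. At lag zero, C(0) = <v^2> = 3 kB T / m by
#' equipartition.
#'
#' @param traj a [Trajectory-class] with velocities
#' @param atom atom index
#' @param maxLag maximum lag (fs); default (and upper limit) is half the
#'   trajectory span, so every origin has all lags available
#' @param originStride origin spacing in frames
#' @param normalization "raw" (A^2/fs^2) or "normalized-at-zero"
#' @return a [CorrelationFunction-class] of kind "vvacf"
#' @export
vvacf <- function(traj, atom, maxLag = NULL, originStride = 1L,
                  normalization = c("raw", "normalized-at-zero")) {
  stopifnot(is(traj, "Trajectory"))
  normalization <- match.arg(normalization)
  L <- .lagCount(traj, maxLag)
  vals <- numeric(L + 1L)
  for (c_ in 1:3) {
    v <- traj@velocities[atom, c_, ]
    vals <- vals + .maskedCrossCorr(v, v, L, originStride)
  }
  if (normalization == "normalized-at-zero") vals <- vals / vals[1]
  new("CorrelationFunction", lags = (0:L) * traj@dt, values = vals,
      kind = "vvacf", atoms = as.integer(atom),
      normalization = normalization)
}

#' Momentum-momentum cross-correlation function
#'
#' Correlates the momentum of atom `i` at lag t against the momentum of atom
#' `j` at the time origin. The MMCCF probes momentum transfer between the two
#' atoms; its Fourier transform indicates the frequencies at which the
#' transfer occurs.
#'
#' Modes: `"dot"` computes C_ij(t) = < p_i(t0+t) . p_j(t0) > (the default and
#' the unambiguous reading; symmetric under i <-> j at t = 0). `"projection"`
#' correlates the scalar projection of p_i(t0+t) onto the unit direction of
#' the reference momentum, C_ij(t) = < p_i(t0+t) . p_j(t0)/|p_j(t0)| >;
#' restoring the reference magnitude |p_j(t0)| in the average makes the two
#' modes algebraically identical, so the projection mode here is the
#' magnitude-free variant. With `i == j` in dot mode the MMCCF reduces to
#' m^2 times the VVACF.
#'
#' @param traj a [Trajectory-class] with velocities
#' @param i,j atom indices (i != j for a cross correlation)
#' @param mode "dot" or "projection"
#' @param maxLag,originStride as in [vvacf()]
#' @return a [CorrelationFunction-class] of kind "mmccf"
#' @export
mmccf <- function(traj, i, j, mode = c("dot", "projection"), maxLag = NULL,
                  originStride = 1L) {
  stopifnot(is(traj, "Trajectory"))
  mode <- match.arg(mode)
  L <- .lagCount(traj, maxLag)
  pi_ <- traj@masses[i] * traj@velocities[i, , ]   # 3 x N
  pj <- traj@masses[j] * traj@velocities[j, , ]
  if (mode == "projection") {
    nrm <- sqrt(colSums(pj^2))
    nrm[nrm == 0] <- 1
    pj <- sweep(pj, 2, nrm, "/")
  }
  vals <- numeric(L + 1L)
  for (c_ in 1:3)
    vals <- vals + .maskedCrossCorr(pi_[c_, ], pj[c_, ], L, originStride)
  new("CorrelationFunction", lags = (0:L) * traj@dt, values = vals,
      kind = "mmccf", atoms = as.integer(c(i, j)), normalization = "raw")
}

#' One-sided power spectrum of a correlation function
#'
#' Fourier transform of the (windowed, optionally zero-padded) correlation
#' function via even extension, on a wavenumber axis nu = k / (c M dt) in
#' 1/cm. The spectral resolution is 1/(c T_corr) for a correlation span
#' T_corr (about 2.2 1/cm for a 15 ps span); zero padding refines the plotted
#' grid without adding resolution. With `window = "none"` the integral of the
#' spectrum over wavenumber equals C(0) (Parseval); the default Hann window
#' suppresses truncation ripple.
#'
#' @param corr a [CorrelationFunction-class] on a uniform lag grid
#' @param window "hann" or "none"
#' @param zeroPadFactor pad the correlation to this multiple of its length
#' @return a [Spectrum-class]
#' @export
powerSpectrum <- function(corr, window = c("hann", "none"),
                          zeroPadFactor = 1) {
  stopifnot(is(corr, "CorrelationFunction"))
  window <- match.arg(window)
  N <- length(corr@values)
  if (N < 2) stop("empty correlation")
  dt <- corr@lags[2] - corr@lags[1]
  vals <- corr@values
  if (window == "hann")
    vals <- vals * (0.5 * (1 + cos(pi * (0:(N - 1)) / (N - 1))))
  Np <- max(N, ceiling(N * zeroPadFactor))
  vals <- c(vals, numeric(Np - N))
  y <- c(vals, rev(vals[2:(Np - 1L)]))       # even extension, length M
  M <- length(y)
  Fk <- Re(stats::fft(y))
  half <- M / 2
  k <- 0:half
  ## density per wavenumber (1/cm): c dt F_k, doubled for interior bins of
  ## the one-sided spectrum, so that integral(P dnu) = C(0) when unwindowed
  scale <- .c_cm_fs * dt * c(1, rep(2, half - 1), 1)
  new("Spectrum",
      wavenumbers = k / (.c_cm_fs * M * dt),
      power = Fk[k + 1L] * scale,
      resolution = 1 / (.c_cm_fs * (N - 1) * dt),
      window = window)
}

#' Convert a wavenumber to its equivalent temperature
#'
#' Equates the thermal energy kB T with the photon energy h c nu:
#' T = (hc/kB) nu = 1.4387769 cm K * nu. At 298 K the thermal wavenumber is
#' 207 1/cm; 245 1/cm corresponds to 353 K and 100 1/cm to 144 K.
#'
#' @param nu wavenumber (1/cm), >= 0
#' @return temperature (K)
#' @export
wavenumberToTemperature <- function(nu) {
  if (any(nu < 0)) stop("negative input: nu must be >= 0")
  .c2_cmK * nu
}

#' @rdname wavenumberToTemperature
#' @param T temperature (K), >= 0
#' @return wavenumber (1/cm)
#' @export
temperatureToWavenumber <- function(T) {
  if (any(T < 0)) stop("negative input: T must be >= 0")
  T / .c2_cmK
}

#' Write a correlation function or spectrum as two-column text
#'
#' @param x a [CorrelationFunction-class] or [Spectrum-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeTwoColumn <- function(x, path) {
  if (is(x, "CorrelationFunction")) {
    writeLines(c(sprintf("# nanotherm %s, lags(fs) value", x@kind),
                 sprintf("%.8g %.10g", x@lags, x@values)), path)
  } else if (is(x, "Spectrum")) {
    writeLines(c("# nanotherm spectrum, wavenumber(1/cm) power",
                 sprintf("%.8g %.10g", x@wavenumbers, x@power)), path)
  } else stop("unsupported object")
  invisible(path)
}
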