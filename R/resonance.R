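## Resonance-overlap metrics: band power fractions and spectral overlap of
## tagged atom pairs in the thermally populated low-wavenumber region.

#' Construct a wavenumber band
#'
#' The default analysis band 100-350 1/cm is the thermally populated
#' low-energy region around kT (207 1/cm at 298 K) in which the atoms of the
#' oxide, the tether and the solvation shell share vibrational weight.
#'
#' @param lo,hi band bounds in 1/cm, 0 <= lo < hi
#' @return a [Band-class]
#' @export
band <- function(lo = 100, hi = 350) new("Band", lo = lo, hi = hi)

## trapezoidal integral of |power| over [lo, hi], with linear interpolation
## at the band edges
.bandIntegral <- function(s, lo, hi) {
  w <- s@wavenumbers; p <- abs(s@power)
  xs <- sort(unique(c(lo, hi, w[w > lo & w < hi])))
  ys <- stats::approx(w, p, xout = xs, rule = 2)$y
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

#' Fraction of spectral power inside a band
#'
#' Integral of the spectrum magnitude over the band divided by the integral
#' over the full spectral range; in [0, 1].
#'
#' @param s a [Spectrum-class]
#' @param bnd a [Band-class] inside the spectral range
#' @return band-power fraction
#' @export
bandFraction <- function(s, bnd) {
  stopifnot(is(s, "Spectrum"), is(bnd, "Band"))
  w <- s@wavenumbers
  if (bnd@lo < min(w) - 1e-9 || bnd@hi > max(w) + 1e-9)
    stop("band outside spectral range")
  tot <- .bandIntegral(s, min(w), max(w))
  if (tot <= 0) stop("all-zero spectrum")
  min(.bandIntegral(s, bnd@lo, bnd@hi) / tot, 1)
}

#' Spectral overlap coefficient of two spectra in a band
#'
#' Cosine similarity of the band-restricted spectra,
#' integral(s1 s2) / sqrt(integral(s1^2) integral(s2^2)), evaluated on the
#' finer of the two wavenumber grids (the other spectrum is linearly
#' interpolated). The coefficient is symmetric, invariant under rescaling of
#' either spectrum, lies in [0, 1] for non-negative spectra, and equals 1
#' exactly when the band-restricted spectra are proportional.
#'
#' @param s1,s2 [Spectrum-class] objects
#' @param bnd a [Band-class] covered by both spectra
#' @return overlap coefficient in [0, 1]
#' @export
spectralOverlap <- function(s1, s2, bnd) {
  stopifnot(is(s1, "Spectrum"), is(s2, "Spectrum"), is(bnd, "Band"))
  for (s in list(s1, s2))
    if (bnd@lo < min(s@wavenumbers) - 1e-9 ||
        bnd@hi > max(s@wavenumbers) + 1e-9)
      stop("band outside spectral range")
  ## resample onto the finer grid, restricted to the band
  d1 <- stats::median(diff(s1@wavenumbers))
  d2 <- stats::median(diff(s2@wavenumbers))
  ref <- if (d1 <= d2) s1 else s2
  xs <- ref@wavenumbers[ref@wavenumbers >= bnd@lo & ref@wavenumbers <= bnd@hi]
  xs <- sort(unique(c(bnd@lo, xs, bnd@hi)))
  y1 <- stats::approx(s1@wavenumbers, abs(s1@power), xout = xs, rule = 2)$y
  y2 <- stats::approx(s2@wavenumbers, abs(s2@power), xout = xs, rule = 2)$y
  n1 <- sqrt(sum(y1^2)); n2 <- sqrt(sum(y2^2))
  if (n1 == 0 || n2 == 0) stop("all-zero spectrum in band")
  max(0, min(1, sum(y1 * y2) / (n1 * n2)))
}

## resolve a tag to one atom index; multi-atom tags pick the member closest
## (minimum image) to `partner` in the first frame
.resolveTag <- function(traj, tag, partner = NULL) {
  idx <- traj@tags[[tag]]
  if (is.null(idx)) {
    ti <- suppressWarnings(as.integer(tag))
    if (!is.na(ti) && ti >= 1 && ti <= nAtoms(traj)) return(ti)
    stop("unresolvable tag: ", tag)
  }
  if (length(idx) == 1L || is.null(partner)) return(idx[1])
  p0 <- traj@positions[partner, , 1]
  xyz <- t(traj@positions[idx, , 1])
  d2 <- .mimd2(p0, t(xyz), traj@box)
  idx[which.min(d2)]
}

#' Resonance-overlap report for tagged atom pairs
#'
#' For each pair of atom tags, computes the VVACF power spectra of the two
#' atoms, their spectral overlap inside the band, each spectrum's band-power
#' fraction, and the band-power fraction of the pair's MMCCF (dot mode)
#' spectrum. Multi-atom tags (e.g. `water_O`) resolve to the member closest
#' to the partner atom in the first frame. The report is deterministic given
#' the trajectory. As a sanity check, the thermal wavenumber of the
#' trajectory temperature (207 1/cm at 298 K) is recorded and must lie
#' inside the default band.
#'
#' @param traj a [Trajectory-class] with tags
#' @param pairs list of 2-element character vectors of tag names
#' @param bnd the analysis [Band-class]
#' @param maxLag,window passed to [vvacf()] / [powerSpectrum()]
#' @return an [OverlapReport-class]
#' @export
resonanceReport <- function(traj,
                            pairs = list(c("anchor_Fe", "amine_N"),
                                         c("subsurface_Fe", "water_O")),
                            bnd = band(100, 350), maxLag = NULL,
                            window = "hann") {
  stopifnot(is(traj, "Trajectory"))
  Tref <- traj@meta$thermostat$T
  if (is.null(Tref)) Tref <- traj@meta$Tinit
  if (is.null(Tref)) Tref <- 298
  ktNu <- temperatureToWavenumber(Tref)
  if (bnd@lo == 100 && bnd@hi == 350 && (ktNu < bnd@lo || ktNu > bnd@hi))
    stop("thermal wavenumber fell outside the default band; check units")
  rows <- lapply(pairs, function(pr) {
    i <- .resolveTag(traj, pr[1])
    j <- .resolveTag(traj, pr[2], partner = i)
    i <- .resolveTag(traj, pr[1], partner = j)
    si <- powerSpectrum(vvacf(traj, i, maxLag = maxLag), window = window)
    sj <- powerSpectrum(vvacf(traj, j, maxLag = maxLag), window = window)
    sx <- powerSpectrum(mmccf(traj, i, j, mode = "dot", maxLag = maxLag),
                        window = window)
    data.frame(pair = paste(pr[1], pr[2], sep = "-"),
               atom1 = i, atom2 = j,
               vvacfOverlap = spectralOverlap(si, sj, bnd),
               bandFraction1 = bandFraction(si, bnd),
               bandFraction2 = bandFraction(sj, bnd),
               mmccfBandFraction = bandFraction(sx, bnd),
               stringsAsFactors = FALSE)
  })
  new("OverlapReport", band = bnd, entries = do.call(rbind, rows),
      provenance = list(nFrames = nFrames(traj), dt = traj@dt,
                        nAtoms = nAtoms(traj), temperature = Tref,
                        thermalWavenumber = ktNu,
                        seed = traj@meta$seed))
}

#' Write an overlap report as JSON and CSV
#'
#' @param report an [OverlapReport-class]
#' @param path output path stem; writes `<path>.json` and `<path>.csv`
#' @return the JSON path, invisibly
#' @export
writeOverlapReport <- function(report, path) {
  stopifnot(is(report, "OverlapReport"))
  obj <- list(band = list(lo = report@band@lo, hi = report@band@hi),
              entries = report@entries,
              provenance = report@provenance)
  jsonlite::write_json(obj, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  utils::write.csv(report@entries, paste0(path, ".csv"), row.names = FALSE)
  invisible(paste0(path, ".json"))
}
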