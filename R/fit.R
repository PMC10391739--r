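## Least-squares refinement of a polydisperse Debye forward model.
##
## The forward model is cached: per diameter class, pair-distance histograms
## are split by site-class pair (tet/oct/O), so that the octahedral occupancy
## enters as analytic weights and the cell edge as a pure distance scaling.
## Cluster membership is frozen at the initial cell edge; since the fit moves
## `a` by well under a percent of itself, the membership error is negligible
## next to the distance scaling that carries the peak positions.

.siteCode <- c(tet_Fe = "t", oct_Fe = "o", lattice_O = "x")
.codeElement <- c(t = "Fe", o = "Fe", x = "O")

.buildFitCache <- function(cell0, D, binWidth, exactMaxD = 4.5,
                           coherenceRadius = 110) {
  bulk <- NULL
  classes <- lapply(D, function(Dk) {
    if (Dk <= exactMaxD) {
      mk <- cutSphere(cell0, Dk)
      at <- mk@atoms
      code <- .siteCode[at$siteClass]
      xyz <- as.matrix(at[, c("x", "y", "z")])
      hl <- .pairData(xyz, code, rep(1, nrow(at)), "histogram", binWidth)
      counts <- c(t = sum(code == "t"), o = sum(code == "o"),
                  x = sum(code == "x"))
    } else {
      if (is.null(bulk))
        bulk <<- .cellPairHistogram(cell0, "site", coherenceRadius, binWidth)
      nCells <- (pi / 6) * (Dk * 10)^3 / cell0@a^3
      hl <- .coherencePairs(bulk, Dk * 10, nCells)
      counts <- c(t = 8, o = 16, x = 32) * nCells
    }
    ## keep both weights and weighted distance sums so that class histograms
    ## can be combined on the common bin grid without losing the weighted
    ## centroid distances
    hl <- lapply(hl, function(p) list(bin = as.integer(round(p$r / binWidth)),
                                      w = p$w, wr = p$w * p$r))
    list(hist = hl, counts = counts)
  })
  maxBin <- max(vapply(classes, function(cl)
    max(c(0L, unlist(lapply(cl$hist, `[[`, "bin")))), integer(1)))
  list(classes = classes, D = D, binWidth = binWidth, a0 = cell0@a,
       maxBin = maxBin)
}

## model intensity on grid q for parameters p = (a, f, meanN, sdN)
.fitModelIntensity <- function(cache, edges, q, a, f, meanN, sdN) {
  a <- unname(a); f <- unname(f); meanN <- unname(meanN); sdN <- unname(sdN)
  s2 <- log(1 + (sdN / meanN)^2)
  mu <- log(meanN) - s2 / 2
  wts <- diff(stats::plnorm(edges, mu, sqrt(s2)))
  if (sum(wts) < 1e-12) return(rep(1e10, length(q)))
  wts <- wts / sum(wts)
  nb <- cache$maxBin + 1L
  ## site-pair keys are alphabetically ordered: t = 8a Fe, o = 16d Fe, x = O
  types <- c("o o", "o t", "o x", "t t", "t x", "x x")
  W <- matrix(0, nb, length(types), dimnames = list(NULL, types))
  WR <- matrix(0, nb, length(types), dimnames = list(NULL, types))
  counts <- c(t = 0, o = 0, x = 0)
  for (k in seq_along(cache$classes)) {
    cl <- cache$classes[[k]]
    counts <- counts + wts[k] * cl$counts
    for (nm in names(cl$hist)) {
      h <- cl$hist[[nm]]
      W[h$bin + 1L, nm] <- W[h$bin + 1L, nm] + wts[k] * h$w
      WR[h$bin + 1L, nm] <- WR[h$bin + 1L, nm] + wts[k] * h$wr
    }
  }
  occCoef <- c("o o" = f^2, "o t" = f, "o x" = f,
               "t t" = 1, "t x" = 1, "x x" = 1)
  fFe <- formFactor("Fe", q); fO <- formFactor("O", q)
  fprod <- list("o o" = fFe * fFe, "o t" = fFe * fFe, "o x" = fFe * fO,
                "t t" = fFe * fFe, "t x" = fFe * fO, "x x" = fO * fO)
  I <- (counts["t"] + f * counts["o"]) * fFe^2 + counts["x"] * fO^2
  for (nm in types) {
    nz <- which(W[, nm] > 0)
    if (!length(nz)) next
    r <- (WR[nz, nm] / W[nz, nm]) * (a / cache$a0)
    qr <- outer(q, r)
    S <- ifelse(qr < 1e-12, 1, sin(qr) / pmax(qr, 1e-300))
    I <- I + 2 * occCoef[nm] * fprod[[nm]] * as.vector(S %*% W[nz, nm])
  }
  unname(I)
}

#' Refine cell, occupancy and size parameters against a pattern
#'
#' Bounded Levenberg-Marquardt least-squares refinement of
#' \{scale, a, f, meanN, sdN\} against an observed total-scattering pattern,
#' using the polydisperse occupancy-weighted Debye forward model of
#' [populationPattern()]. The overall scale is profiled out analytically at
#' each step; optional random multi-start restarts perturb the initial
#' estimate and the best residual wins.
#'
#' @param observed a [ScatteringPattern-class]
#' @param initial named list with elements a, f, meanN, sdN (and optionally
#'   Dmax; defaults to the observed pattern's metadata, then 40 nm)
#' @param bounds optional list(lower, upper), each a named numeric over
#'   (a, f, meanN, sdN); defaults to a +/- 3%, f in [0.5, 1],
#'   meanN in [0.5, 2] x initial, sdN in [0.3, 3] x initial
#' @param nClasses number of diameter classes in the forward model
#' @param binWidth pair-distance histogram bin width (angstrom)
#' @param weightCutoff classes below this initial weight are dropped
#' @param nStarts number of random restarts (1 = none)
#' @param seed seed for the restart perturbations
#' @param exactMaxD,coherenceRadius large-class handling, as in
#'   [populationPattern()]
#' @return a [FitResult-class]
#' @export
fitPattern <- function(observed, initial, bounds = NULL, nClasses = 24,
                       binWidth = 0.02, weightCutoff = 1e-6, nStarts = 1,
                       seed = 1L, exactMaxD = 4.5, coherenceRadius = 110) {
  stopifnot(is(observed, "ScatteringPattern"))
  if (any(!is.finite(observed@I))) stop("non-finite observed intensities")
  need <- c("a", "f", "meanN", "sdN")
  if (!all(need %in% names(initial)))
    stop("initial needs elements: ", paste(need, collapse = ", "))
  Dmax <- initial$Dmax
  if (is.null(Dmax)) Dmax <- observed@meta$Dmax
  if (is.null(Dmax)) Dmax <- 40
  if (is.null(bounds))
    bounds <- list(
      lower = c(a = initial$a * 0.97, f = 0.5, meanN = initial$meanN * 0.5,
                sdN = initial$sdN * 0.3),
      upper = c(a = initial$a * 1.03, f = 1.0, meanN = initial$meanN * 2,
                sdN = initial$sdN * 3))
  if (!length(bounds$lower) || !length(bounds$upper)) stop("empty bounds")

  cell0 <- spinelCell(a = initial$a, f = 1)
  dist0 <- sizeDistribution(initial$meanN, initial$sdN, Dmax)
  cls <- .sizeClasses(dist0, nClasses)
  keep <- cls$w >= weightCutoff
  ## keep contiguous edge coverage for the retained classes
  kidx <- range(which(keep))
  keepSeq <- kidx[1]:kidx[2]
  D <- cls$D[keepSeq]
  edges <- cls$edges[c(keepSeq, kidx[2] + 1L)]
  cache <- .buildFitCache(cell0, D, binWidth, exactMaxD, coherenceRadius)

  obsI <- observed@I
  nrmI <- obsI / max(abs(obsI))
  q <- observed@q
  residFn <- function(p) {
    Im <- .fitModelIntensity(cache, edges, q, p[1], p[2], p[3], p[4])
    sc <- sum(nrmI * Im) / sum(Im * Im)
    nrmI - sc * Im
  }
  p0 <- c(a = initial$a, f = initial$f, meanN = initial$meanN,
          sdN = initial$sdN)
  starts <- list(p0)
  if (nStarts > 1) {
    jit <- .withSeed(seed, lapply(seq_len(nStarts - 1), function(i)
      pmin(pmax(p0 * stats::runif(4, 0.9, 1.1), bounds$lower), bounds$upper)))
    starts <- c(starts, jit)
  }
  best <- NULL
  for (st in starts) {
    fit <- minpack.lm::nls.lm(
      par = st, lower = bounds$lower[need], upper = bounds$upper[need],
      fn = residFn,
      control = minpack.lm::nls.lm.control(maxiter = 100, ptol = 1e-10))
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  p <- best$par
  Im <- .fitModelIntensity(cache, edges, q, p[1], p[2], p[3], p[4])
  scale <- sum(obsI * Im) / sum(Im * Im)
  new("FitResult",
      par = list(scale = scale, a = unname(p[1]), f = unname(p[2]),
                 meanN = unname(p[3]), sdN = unname(p[4])),
      residual = best$deviance,
      converged = best$info %in% 1:4,
      meta = list(info = best$info, message = best$message,
                  niter = best$niter, nClasses = length(D), Dmax = Dmax,
                  classD = D))
}
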