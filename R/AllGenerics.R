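#' Atom table of a structural model
#'
#' @param x a [NanocrystalModel-class] or [SlabModel-class]
#' @return data.frame with columns element, x, y, z, occupancy, siteClass
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "NanocrystalModel", function(x) x@atoms)

#' @rdname atoms
#' @export
setMethod("atoms", "SlabModel", function(x) x@atoms)

#' Number of atoms / frames
#'
#' @param x a structural model or [Trajectory-class]
#' @return integer count
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "NanocrystalModel", function(x) nrow(x@atoms))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "SlabModel", function(x) nrow(x@atoms))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Trajectory", function(x) dim(x@positions)[1])

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Topology", function(x) length(x@elements))

#' @rdname nAtoms
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nAtoms
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@positions)[3])

#' Element tally of a model
#'
#' @param x a structural model
#' @return named integer vector of per-element atom counts
#' @export
setGeneric("elementCounts", function(x) standardGeneric("elementCounts"))

.tallyElements <- function(el) {
  tab <- table(factor(el, levels = .knownElements))
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[counts > 0]
}

#' @rdname elementCounts
#' @export
setMethod("elementCounts", "NanocrystalModel", function(x)
  .tallyElements(x@atoms$element))

#' @rdname elementCounts
#' @export
setMethod("elementCounts", "SlabModel", function(x)
  .tallyElements(x@atoms$element))

#' @rdname elementCounts
#' @export
setMethod("elementCounts", "Trajectory", function(x)
  .tallyElements(x@elements))

#' Per-site-class tally of a model
#'
#' @param x a structural model
#' @return named integer vector of per-site-class counts
#' @export
setGeneric("siteClassCounts", function(x) standardGeneric("siteClassCounts"))

.tallyClasses <- function(cl) {
  tab <- table(factor(cl, levels = .siteClasses))
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts
}

#' @rdname siteClassCounts
#' @export
setMethod("siteClassCounts", "NanocrystalModel", function(x)
  .tallyClasses(x@atoms$siteClass))

#' @rdname siteClassCounts
#' @export
setMethod("siteClassCounts", "SlabModel", function(x)
  .tallyClasses(x@atoms$siteClass))

#' Box edges of a model or trajectory
#'
#' @param x a [SlabModel-class], [Topology-class] or [Trajectory-class]
#' @return numeric c(Lx, Ly, Lz) in angstrom (or numeric(0) if unset)
#' @export
setGeneric("boxEdges", function(x) standardGeneric("boxEdges"))

#' @rdname boxEdges
#' @export
setMethod("boxEdges", "SlabModel", function(x) x@box)

#' @rdname boxEdges
#' @export
setMethod("boxEdges", "Topology", function(x) x@box)

#' @rdname boxEdges
#' @export
setMethod("boxEdges", "Trajectory", function(x) x@box)

#' Named atom tag sets
#'
#' @param x a [Topology-class] or [Trajectory-class]
#' @return named list of integer atom indices
#' @export
setGeneric("atomTags", function(x) standardGeneric("atomTags"))

#' @rdname atomTags
#' @export
setMethod("atomTags", "Topology", function(x) x@tags)

#' @rdname atomTags
#' @export
setMethod("atomTags", "Trajectory", function(x) x@tags)

#' Log-parameters (mu, sigma) of a size distribution
#'
#' Converts the number-based (meanN, sdN) parameterization of a
#' [SizeDistribution-class] to the log-normal parameters: sigma^2 =
#' log(1 + (sdN/meanN)^2), mu = log(meanN) - sigma^2/2. The conversion
#' round-trips with [sizeDistribution()].
#'
#' @param x a [SizeDistribution-class]
#' @return named numeric c(mu, sigma)
#' @export
setGeneric("logParams", function(x) standardGeneric("logParams"))

#' @rdname logParams
#' @export
setMethod("logParams", "SizeDistribution", function(x) {
  s2 <- log(1 + (x@sdN / x@meanN)^2)
  c(mu = log(x@meanN) - s2 / 2, sigma = sqrt(s2))
})

## ---- show methods -------------------------------------------------------

setMethod("show", "SpinelCell", function(object) {
  cat(sprintf("SpinelCell: a = %.4f A, u = %.4f, f(16d) = %.4f (Fe_%.3fO4), origin %s\n",
              object@a, object@u, object@f, 1 + 2 * object@f,
              object@originChoice))
})

setMethod("show", "NanocrystalModel", function(object) {
  ec <- elementCounts(object)
  cat(sprintf("NanocrystalModel: %d sites%s\n  elements: %s\n",
              nrow(object@atoms),
              if (is.na(object@diameter)) "" else
                sprintf(", nominal diameter %.2f nm", object@diameter),
              paste(names(ec), ec, sep = ":", collapse = " ")))
})

setMethod("show", "SlabModel", function(object) {
  ec <- elementCounts(object)
  cat(sprintf("SlabModel: box %.3f x %.3f x %.3f A, %d atoms, %d attachments\n  elements: %s\n",
              object@box[1], object@box[2], object@box[3], nrow(object@atoms),
              length(object@attachments),
              paste(names(ec), ec, sep = ":", collapse = " ")))
})

setMethod("show", "SizeDistribution", function(object) {
  lp <- logParams(object)
  cat(sprintf("SizeDistribution: <D>_N = %.2f nm, sd_N = %.2f nm, Dmax = %.1f nm (mu = %.3f, sigma = %.3f)\n",
              object@meanN, object@sdN, object@Dmax, lp["mu"], lp["sigma"]))
})

setMethod("show", "ScatteringPattern", function(object) {
  cat(sprintf("ScatteringPattern: %d q-points on [%.3f, %.3f] 1/A\n",
              length(object@q), min(object@q), max(object@q)))
})

setMethod("show", "FitResult", function(object) {
  cat("FitResult:", if (object@converged) "converged" else "NOT converged",
      sprintf("(residual %.4g)\n", object@residual))
  p <- object@par
  cat(sprintf("  a = %.4f A, f = %.4f, meanN = %.3f nm, sdN = %.3f nm, scale = %.4g\n",
              p$a, p$f, p$meanN, p$sdN, p$scale))
})

setMethod("show", "Topology", function(object) {
  cat(sprintf("Topology: %d atoms, %d springs, tags: %s\n",
              length(object@elements), nrow(object@springs),
              paste(names(object@tags), collapse = ", ")))
})

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@positions)
  cat(sprintf("Trajectory: %d atoms, %d frames, dt = %.3g fs (%.3f ps total)\n",
              d[1], d[3], object@dt, d[3] * object@dt / 1000))
})

setMethod("show", "CorrelationFunction", function(object) {
  cat(sprintf("CorrelationFunction (%s): %d lags, span %.1f fs, atoms [%s]\n",
              object@kind, length(object@lags),
              if (length(object@lags)) max(object@lags) else 0,
              paste(object@atoms, collapse = ", ")))
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %d points to %.0f 1/cm, resolution %.2f 1/cm, window %s\n",
              length(object@wavenumbers), max(object@wavenumbers),
              object@resolution, object@window))
})

setMethod("show", "Band", function(object) {
  cat(sprintf("Band: [%g, %g] 1/cm\n", object@lo, object@hi))
})

setMethod("show", "OverlapReport", function(object) {
  cat(sprintf("OverlapReport on band [%g, %g] 1/cm:\n",
              object@band@lo, object@band@hi))
  print(object@entries, digits = 3)
})
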