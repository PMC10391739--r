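## geometry helpers ---------------------------------------------------------

.unitv <- function(v) v / sqrt(sum(v^2))

## two unit vectors orthogonal to v (right-handed with v)
.perpBasis <- function(v) {
  v <- .unitv(v)
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unitv(ref - sum(ref * v) * v)
  e2 <- c(v[2] * e1[3] - v[3] * e1[2],
          v[3] * e1[1] - v[1] * e1[3],
          v[1] * e1[2] - v[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

## unit vector at `angleDeg` from direction `axis`, azimuth phiDeg around it
.coneDir <- function(axis, angleDeg, phiDeg = 0) {
  b <- .perpBasis(axis)
  th <- angleDeg * pi / 180; ph <- phiDeg * pi / 180
  .unitv(cos(th) * .unitv(axis) +
           sin(th) * (cos(ph) * b$e1 + sin(ph) * b$e2))
}

## greedy farthest-point subset: keep `nKeep` of the rows of xy, spreading
## them as evenly as possible under in-plane periodicity. Deterministic.
.spreadSubset <- function(xy, nKeep, boxXY) {
  n <- nrow(xy)
  if (nKeep >= n) return(seq_len(n))
  d2 <- function(i, j) {
    d <- xy[i, ] - xy[j, ]
    d <- d - round(d / boxXY) * boxXY
    sum(d^2)
  }
  start <- order(xy[, 1], xy[, 2])[1]
  sel <- start
  dist2 <- vapply(seq_len(n), function(i) d2(i, start), numeric(1))
  while (length(sel) < nKeep) {
    nxt <- which.max(dist2)
    sel <- c(sel, nxt)
    dist2 <- pmin(dist2, vapply(seq_len(n), function(i) d2(i, nxt), numeric(1)))
  }
  sort(sel)
}

## Rotated-lattice enumeration: all spinel sites of the (111)-oriented
## orthorhombic surface cell with z in [zlo, zhi]. Columns of the rotation
## take cubic axes to x || [11-2], y || [-110], z || [111].
.slab111Sites <- function(cell, zlo, zhi) {
  a <- cell@a
  R <- rbind(c(1, 1, -2) / sqrt(6), c(-1, 1, 0) / sqrt(2), c(1, 1, 1) / sqrt(3))
  Lx <- a * sqrt(1.5); Ly <- a * sqrt(2); Lrep <- a * sqrt(3)
  p <- .unitCellFractional(cell)
  nmax <- ceiling((abs(zhi) + abs(zlo)) / a) + 3L
  rng <- -nmax:nmax
  cells <- as.matrix(expand.grid(rng, rng, rng))
  nb <- nrow(p$frac); nc <- nrow(cells)
  frac <- p$frac[rep(seq_len(nb), times = nc), , drop = FALSE] +
    cells[rep(seq_len(nc), each = nb), , drop = FALSE]
  rot <- (frac * a) %*% t(R)
  ## wrap into the surface cell in x, y and one repeat in z, then deduplicate
  fr <- cbind(rot[, 1] / Lx, rot[, 2] / Ly, rot[, 3] / Lrep) %% 1
  fr <- round(fr, 6) %% 1
  key <- paste(fr[, 1], fr[, 2], fr[, 3], sep = ",")
  keep <- !duplicated(key)
  fr <- fr[keep, , drop = FALSE]
  siteClass <- rep(p$siteClass, times = nc)[keep]
  element <- rep(p$element, times = nc)[keep]
  occupancy <- rep(p$occupancy, times = nc)[keep]
  ## unfold in z over enough repeats to cover [zlo, zhi]
  reps <- floor(zlo / Lrep):ceiling(zhi / Lrep)
  nuq <- nrow(fr)
  z <- rep(fr[, 3] * Lrep, times = length(reps)) +
    rep(reps * Lrep, each = nuq)
  x <- rep(fr[, 1] * Lx, times = length(reps))
  y <- rep(fr[, 2] * Ly, times = length(reps))
  inz <- z >= zlo - 1e-6 & z <= zhi + 1e-6
  list(xyz = cbind(x, y, z)[inz, , drop = FALSE],
       siteClass = rep(siteClass, length(reps))[inz],
       element = rep(element, length(reps))[inz],
       occupancy = rep(occupancy, length(reps))[inz],
       Lx = Lx, Ly = Ly, Lrep = Lrep)
}

#' Build a (111) maghemite surface slab
#'
#' Constructs an orthorhombic 1x1 (111) surface supercell with in-plane edges
#' Lx = a*sqrt(3/2) and Ly = a*sqrt(2). Along the surface normal the spinel
#' (111) stacking alternates kagome octahedral layers, close-packed oxygen
#' layers and mixed tet-oct-tet cation layers with sub-repeat a/sqrt(3).
#' The slab comprises the largest number of complete sub-repeats whose span
#' fits within `thickness`, terminated below by a kagome octahedral layer
#' reduced to 2/3 occupancy and above by a close-packed oxygen layer reduced
#' to 3/4 occupancy (reduced-occupancy metal/oxygen terminations, the common
#' stabilization of polar spinel (111) surfaces). With the default cell and
#' thickness this realizes 16 tetrahedral Fe, 40 octahedral Fe and 76 lattice
#' O. `hydroxylCount` OH groups are then placed on the most exposed Fe
#' (largest |z| from the slab midplane), pointing outward.
#'
#' @param cell a [SpinelCell-class]
#' @param thickness maximum slab span along z (angstrom)
#' @param hydroxylCount number of surface OH groups to add
#' @param vacuum vacuum gap added along z (angstrom); the box height is
#'   `thickness + vacuum`
#' @return a [SlabModel-class]; octahedral sites carry the cell occupancy `f`
#'   (use [assignVacancies()] to realize explicit vacancies)
#' @examples
#' slab <- build111Slab(spinelCell(a = 8.3561, f = 0.9), thickness = 14)
#' boxEdges(slab)[1:2]   # 10.234 11.817
#' @export
build111Slab <- function(cell, thickness = 14, hydroxylCount = 4L,
                         vacuum = 12) {
  stopifnot(is(cell, "SpinelCell"))
  if (thickness <= 0) stop("thickness must be > 0")
  a <- cell@a
  Lsub <- a * sqrt(3) / 3              # kagome-to-kagome sub-repeat
  ## height of the O layer sitting just above a kagome layer: for the 32e
  ## orbit the first oxygen plane lies at (3/4 - u) * a * sqrt(3) / 3 ... use
  ## the enumerated geometry instead of a closed form.
  probe <- .slab111Sites(cell, -0.1, Lsub + 0.1)
  zO <- sort(unique(round(probe$xyz[probe$siteClass == "lattice_O", 3], 3)))
  zO1 <- min(zO[zO > 0.1])
  nSub <- floor((thickness - zO1) / Lsub + 1e-9)
  if (nSub < 1)
    stop("degenerate slab: thickness smaller than one (111) repeat (need >= ",
         round(Lsub + zO1, 2), " A)")
  zTop <- nSub * Lsub + zO1
  s <- .slab111Sites(cell, -0.05, zTop + 0.05)
  xyz <- s$xyz; sc <- s$siteClass
  ## terminal layers: bottom kagome (z ~ 0), top oxygen (z ~ zTop)
  botIdx <- which(sc == "oct_Fe" & abs(xyz[, 3]) < 0.3)
  topIdx <- which(sc == "lattice_O" & abs(xyz[, 3] - zTop) < 0.3)
  keepBot <- botIdx[.spreadSubset(xyz[botIdx, 1:2, drop = FALSE],
                                  round(2 / 3 * length(botIdx)),
                                  c(s$Lx, s$Ly))]
  keepTop <- topIdx[.spreadSubset(xyz[topIdx, 1:2, drop = FALSE],
                                  round(3 / 4 * length(topIdx)),
                                  c(s$Lx, s$Ly))]
  keep <- sort(c(setdiff(seq_len(nrow(xyz)), c(botIdx, topIdx)),
                 keepBot, keepTop))
  atomsDf <- .atomsFromParts(s$element[keep], xyz[keep, , drop = FALSE],
                             s$occupancy[keep], sc[keep])
  slab <- new("SlabModel", box = c(s$Lx, s$Ly, thickness + vacuum),
              atoms = atomsDf, attachments = list(), cell = cell)
  if (hydroxylCount > 0) slab <- .hydroxylate(slab, hydroxylCount)
  slab
}

## Place nOH hydroxyls on the most exposed Fe (largest |z - midplane|),
## pointing outward along the surface normal.
.hydroxylate <- function(slab, nOH, rFeO = 1.85, rOH = 0.97) {
  at <- slab@atoms
  fe <- which(at$element == "Fe")
  zc <- mean(range(at$z[at$element %in% c("Fe", "O")]))
  expo <- abs(at$z[fe] - zc)
  ord <- fe[order(-expo, at$x[fe], at$y[fe])]
  chosen <- ord[seq_len(min(nOH, length(ord)))]
  for (i in chosen) {
    outward <- sign(at$z[i] - zc)
    nrm <- c(0, 0, outward)
    opos <- c(at$x[i], at$y[i], at$z[i]) + rFeO * nrm
    tiltH <- .coneDir(nrm, 25, 0)
    hpos <- opos + rOH * tiltH
    at <- rbind(at, .atomsFromParts(c("O", "H"), rbind(opos, hpos),
                                    c(1, 1), c("hydroxyl_O", "hydroxyl_H")))
    slab@attachments <- c(slab@attachments,
                          list(list(kind = "hydroxyl", anchor = i,
                                    fragment = c(nrow(at) - 1L, nrow(at)))))
  }
  rownames(at) <- NULL
  slab@atoms <- at
  slab
}

#' Target geometry for the silane bridge
#'
#' @param rFeO Fe-O bond target (angstrom)
#' @param rOSi O-Si bond target (angstrom)
#' @param angleFeOSi Fe-O-Si bridge angle target (degrees)
#' @return a [SilaneGeometry-class]
#' @export
silaneGeometry <- function(rFeO = 1.91, rOSi = 1.62, angleFeOSi = 138) {
  new("SilaneGeometry", rFeO = rFeO, rOSi = rOSi, angleFeOSi = angleFeOSi)
}

#' Attach the aminodialkoxysilane fragment via an Fe-O-Si bridge
#'
#' Adds a -Si(OCH3)2-(CH2)3-NH3(+) residue to a surface Fe atom through a new
#' bridging oxygen (the bridge O is an atom added here, additional to the
#' slab's lattice and hydroxyl oxygens). Heavy atoms added: 1 bridging O,
#' 1 Si, 2 methoxy O, 5 C, 1 N; hydrogens added: 15 (6 methoxy, 6 methylene,
#' 3 ammonium). Built Fe-O and O-Si bond lengths and the Fe-O-Si angle match
#' the geometry targets by construction.
#'
#' @param slab a [SlabModel-class]
#' @param anchorFe row index of the anchoring surface Fe; by default the most
#'   exposed Fe without an existing attachment
#' @param geometry a [SilaneGeometry-class] of build targets
#' @return the slab with the fragment appended and an attachment record added
#' @export
attachSilane <- function(slab, anchorFe = NULL, geometry = silaneGeometry()) {
  stopifnot(is(slab, "SlabModel"))
  at <- slab@atoms
  zOx <- at$z[at$siteClass %in% c("tet_Fe", "oct_Fe", "lattice_O")]
  zc <- mean(range(zOx))
  if (is.null(anchorFe)) {
    taken <- unlist(lapply(slab@attachments, `[[`, "anchor"))
    fe <- setdiff(which(at$element == "Fe"), taken)
    ## most exposed on the oxygen-terminated (top) side
    fe <- fe[at$z[fe] > zc]
    anchorFe <- fe[order(-at$z[fe], at$x[fe], at$y[fe])][1]
  }
  if (!at$element[anchorFe] %in% "Fe")
    stop("invalid anchor: not an Fe atom")
  if (abs(at$z[anchorFe] - zc) < 0.25 * diff(range(zOx)))
    stop("invalid anchor: anchor Fe is not at the surface")
  fePos <- c(at$x[anchorFe], at$y[anchorFe], at$z[anchorFe])
  up <- c(0, 0, sign(at$z[anchorFe] - zc))

  el <- character(0); xyz <- NULL; push <- function(e, p) {
    el <<- c(el, e); xyz <<- rbind(xyz, p)
  }
  oB <- fePos + geometry@rFeO * up
  push("O", oB)
  ## Fe-O-Si angle: direction from O at (180 - angle) degrees from +up
  dSi <- .coneDir(up, 180 - geometry@angleFeOSi, 0)
  si <- oB + geometry@rOSi * dSi
  push("Si", si)
  ## tetrahedral substituents around Si, relative to the Si->O_bridge bond
  b0 <- .unitv(oB - si)
  dirs <- lapply(c(60, 180, 300), function(phi) .coneDir(b0, 109.47, phi))
  ## order substituents so the propyl chain points away from the surface
  zcomp <- vapply(dirs, function(d) d[3] * up[3], numeric(1))
  ord <- order(-zcomp)
  dChain <- dirs[[ord[1]]]; dOMe <- dirs[ord[2:3]]
  ## two methoxy groups
  for (d in dOMe) {
    om <- si + 1.63 * d
    push("O", om)
    dc <- .coneDir(.unitv(si - om), 120, 90)
    cm <- om + 1.42 * dc
    push("C", cm)
    for (phi in c(0, 120, 240))
      push("H", cm + 1.09 * .coneDir(.unitv(om - cm), 109.47, phi))
  }
  ## propyl chain Si-C1-C2-C3-N, zigzag with tetrahedral angles
  prev <- si; dir <- dChain
  chain <- list(c("C", 1.86), c("C", 1.53), c("C", 1.53), c("N", 1.49))
  chainPos <- list()
  for (kk in seq_along(chain)) {
    pos <- prev + as.numeric(chain[[kk]][2]) * dir
    push(chain[[kk]][1], pos)
    chainPos[[kk]] <- pos
    dir <- .coneDir(dir, 70.53, if (kk %% 2 == 1) 180 else 0)
    prev <- pos
  }
  ## methylene hydrogens: 2 per CH2, straddling the local chain plane at the
  ## tetrahedral half-angle from the backbone bisector
  cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])
  backbone <- c(list(si), chainPos)
  for (kk in 2:4) {  # the three CH2 carbons are backbone items 2..4
    c0 <- backbone[[kk]]
    axis <- .unitv(backbone[[kk + 1]] - backbone[[kk - 1]])
    bis <- .unitv(2 * c0 - backbone[[kk + 1]] - backbone[[kk - 1]])
    side <- .unitv(cross3(axis, bis))
    half <- 54.74 * pi / 180
    for (sgn in c(1, -1))
      push("H", c0 + 1.09 * .unitv(bis * cos(half) + sgn * side * sin(half)))
  }
  ## ammonium hydrogens
  npos <- chainPos[[4]]
  dNH <- .unitv(npos - chainPos[[3]])
  for (phi in c(0, 120, 240)) push("H", npos + 1.03 * .coneDir(dNH, 70.53, phi))

  newAtoms <- .atomsFromParts(el, xyz, rep(1, length(el)),
                              rep("organic", length(el)))
  n0 <- nrow(at)
  slab@atoms <- rbind(at, newAtoms)
  rownames(slab@atoms) <- NULL
  slab@attachments <- c(slab@attachments,
                        list(list(kind = "silane", anchor = anchorFe,
                                  fragment = n0 + seq_len(nrow(newAtoms)))))
  slab
}

#' Solvate the slab with rigid water molecules
#'
#' Places rigid TIP3P-geometry waters (r(OH) = 0.9572 A, angle 104.52 deg)
#' in the region outside the oxide slab by seeded rejection sampling. A
#' candidate is accepted when its oxygen lies at least `dMin` from every
#' existing heavy (non-H) atom and from previously placed water oxygens,
#' under the periodic minimum-image convention. Exactly `nWaters` molecules
#' are placed when given; otherwise the count closest to `targetDensity`.
#'
#' @param slab a [SlabModel-class] with a vacuum region along z
#' @param nWaters number of water molecules (takes precedence)
#' @param targetDensity target water density in g/cm^3
#' @param dMin minimum heavy-atom distance (angstrom)
#' @param seed integer seed
#' @param maxAttempts rejection-sampling retry cap per molecule
#' @return the slab with waters appended
#' @export
solvate <- function(slab, nWaters = NULL, targetDensity = NULL, dMin = 2.6,
                    seed = 1L, maxAttempts = 10000L) {
  stopifnot(is(slab, "SlabModel"))
  if (dMin <= 0) stop("dMin must be > 0")
  box <- slab@box
  at <- slab@atoms
  oxide <- at$siteClass %in% c("tet_Fe", "oct_Fe", "lattice_O")
  zhi <- max(at$z[oxide]); zlo <- min(at$z[oxide])
  gap <- (zlo - 1 + box[3]) - (zhi + 1)
  if (gap <= 2) stop("no vacuum region: slab fills the box")
  if (is.null(nWaters)) {
    if (is.null(targetDensity))
      stop("give nWaters or targetDensity")
    ## molecules per cubic angstrom at the requested mass density
    perA3 <- targetDensity * 6.02214076e23 / 18.01528 * 1e-24
    nWaters <- round(perA3 * box[1] * box[2] * gap)
  }
  if (nWaters == 0) return(slab)
  heavy <- as.matrix(at[at$element != "H", c("x", "y", "z")])
  rOH <- 0.9572; ang <- 104.52 * pi / 180
  placed <- .withSeed(seed, {
    oxys <- NULL; out <- NULL
    for (w in seq_len(nWaters)) {
      ok <- FALSE
      for (try in seq_len(maxAttempts)) {
        o <- c(runif(1) * box[1], runif(1) * box[2],
               (zhi + 1 + runif(1) * gap) %% box[3])
        if (min(.mimd2(o, heavy, box)) < dMin^2) next
        if (!is.null(oxys) && min(.mimd2(o, oxys, box)) < dMin^2) next
        ok <- TRUE; break
      }
      if (!ok) stop("overfilled region: could not place water ", w,
                    " after ", maxAttempts, " attempts")
      ## random rigid orientation
      ax <- .unitv(stats::rnorm(3))
      b <- .perpBasis(ax)
      phi <- runif(1) * 2 * pi
      d1 <- .unitv(cos(phi) * b$e1 + sin(phi) * b$e2)
      h1 <- o + rOH * (cos(ang / 2) * ax + sin(ang / 2) * d1)
      h2 <- o + rOH * (cos(ang / 2) * ax - sin(ang / 2) * d1)
      oxys <- rbind(oxys, o)
      out <- rbind(out, o, h1, h2)
    }
    out
  })
  el <- rep(c("O", "H", "H"), nWaters)
  slab@atoms <- rbind(at, .atomsFromParts(el, placed, rep(1, length(el)),
                                          rep("water", length(el))))
  rownames(slab@atoms) <- NULL
  slab
}
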