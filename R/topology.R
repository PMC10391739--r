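#' Default spring table for the harmonic network
#'
#' Per-pair-class harmonic spring definitions used by [topologyFromSlab()]:
#' element pair, distance window (angstrom) and characteristic wavenumber
#' (1/cm). The spring constant is k = mu * omega^2 with mu the two-atom
#' reduced mass, so an isolated pair oscillates at the listed wavenumber.
#' The values place the characteristic bands in physically sensible infrared
#' ranges (Fe-O lattice modes a few hundred 1/cm, O-H/N-H/C-H stretches at
#' 2900-3600 1/cm, hydrogen bonds 100-300 1/cm); they are configuration, not
#' a fitted force field.
#'
#' @return data.frame with columns class, e1, e2, rmin, rmax, wavenumber
#' @export
springTable <- function() {
  data.frame(
    class = c(rep("covalent", 8), "lattice", "hbond"),
    e1 = c("O", "N", "C", "C", "C", "C", "O", "C", "Fe", "H"),
    e2 = c("H", "H", "H", "C", "N", "O", "Si", "Si", "O", "O"),
    rmin = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1.30),
    rmax = c(1.20, 1.25, 1.25, 1.70, 1.70, 1.60, 1.85, 2.00, 2.35, 2.45),
    wavenumber = c(3600, 3300, 2950, 1000, 1050, 1050, 950, 700, 400, 180),
    stringsAsFactors = FALSE)
}

## spring constant (amu/fs^2) for a pair wavenumber (1/cm) and reduced mass
.kFromWavenumber <- function(nu, mu) {
  omega <- 2 * pi * .c_cm_fs * nu
  mu * omega^2
}

## minimum-image displacement vectors xj - xi (rows), optional box
.mimDisp <- function(xi, xj, box) {
  d <- xj - xi
  if (length(box) == 3L)
    d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
  d
}

.bfsReach <- function(n, i, j, springs) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(springs))) {
    adj[[springs$i[r]]] <- c(adj[[springs$i[r]]], springs$j[r])
    adj[[springs$j[r]]] <- c(adj[[springs$j[r]]], springs$i[r])
  }
  seen <- logical(n); seen[i] <- TRUE; queue <- i
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[v]][!seen[adj[[v]]]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  seen[j]
}

#' Build a harmonic oscillator network from an assembled slab model
#'
#' Creates one harmonic spring for every atom pair whose minimum-image
#' distance falls inside its pair class window (covalent bonds, Fe-O lattice
#' contacts, O-H...O / N-H...O hydrogen bonds). Rest lengths are set to the
#' as-built distances, so the input geometry is the network's equilibrium.
#' Standard tag sets are derived from the model: `anchor_Fe` and `amine_N`
#' (silane attachment), `bridging_O`, `water_O`, and `subsurface_Fe` (the Fe
#' closest to the slab midplane). The function verifies that the spring graph
#' connects anchor_Fe to amine_N (the covalent chain) and the slab surface to
#' at least one water oxygen (the hydrogen-bond network), and signals a
#' cutoff misconfiguration otherwise.
#'
#' @param model an assembled [SlabModel-class] (slab + silane + waters)
#' @param table spring definitions, see [springTable()]
#' @return a [Topology-class]
#' @export
topologyFromSlab <- function(model, table = springTable()) {
  stopifnot(is(model, "SlabModel"))
  at <- model@atoms
  n <- nrow(at)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  box <- model@box
  ## all candidate pairs within the largest cutoff (minimum image)
  rmaxAll <- max(table$rmax)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- .mimDisp(xyz[pr[, 1], , drop = FALSE], xyz[pr[, 2], , drop = FALSE],
                box)
  r <- sqrt(rowSums(d^2))
  near <- r <= rmaxAll
  pi_ <- pr[near, 1]; pj <- pr[near, 2]; rij <- r[near]
  ei <- at$element[pi_]; ej <- at$element[pj]
  springs <- NULL
  for (k in seq_len(nrow(table))) {
    sel <- ((ei == table$e1[k] & ej == table$e2[k]) |
              (ei == table$e2[k] & ej == table$e1[k])) &
      rij > table$rmin[k] & rij <= table$rmax[k]
    if (!any(sel)) next
    mu <- .elementMass(ei[sel]) * .elementMass(ej[sel]) /
      (.elementMass(ei[sel]) + .elementMass(ej[sel]))
    springs <- rbind(springs,
                     data.frame(i = pi_[sel], j = pj[sel],
                                k = .kFromWavenumber(table$wavenumber[k], mu),
                                r0 = rij[sel], class = table$class[k],
                                stringsAsFactors = FALSE))
  }
  if (is.null(springs)) stop("cutoff misconfiguration: no springs created")
  ## tags
  tags <- list()
  sil <- Filter(function(att) att$kind == "silane", model@attachments)
  if (length(sil)) {
    frag <- sil[[1]]$fragment
    tags$anchor_Fe <- as.integer(sil[[1]]$anchor)
    tags$bridging_O <- as.integer(frag[1])
    nIdx <- frag[at$element[frag] == "N"]
    tags$amine_N <- as.integer(nIdx[1])
  }
  watO <- which(at$siteClass == "water" & at$element == "O")
  if (length(watO)) tags$water_O <- as.integer(watO)
  oxide <- at$siteClass %in% c("tet_Fe", "oct_Fe", "lattice_O")
  zc <- mean(range(at$z[oxide]))
  fe <- which(at$element == "Fe")
  tags$subsurface_Fe <- as.integer(fe[order(abs(at$z[fe] - zc),
                                            at$x[fe])][1])
  ## connectivity checks
  if (!is.null(tags$anchor_Fe) && !is.null(tags$amine_N) &&
      !.bfsReach(n, tags$anchor_Fe, tags$amine_N, springs))
    stop("cutoff misconfiguration: anchor_Fe and amine_N are disconnected")
  if (length(watO)) {
    surf <- which(oxide)[which.max(at$z[oxide])]
    if (!any(vapply(watO[seq_len(min(5, length(watO)))], function(w)
      .bfsReach(n, surf, w, springs), logical(1))))
      stop("cutoff misconfiguration: slab surface and water_O are disconnected")
  }
  new("Topology", elements = at$element, masses = .elementMass(at$element),
      positions = xyz, springs = springs, tags = tags, box = box)
}

#' Normal modes of a harmonic network
#'
#' Eigenanalysis of the mass-weighted Hessian of the spring network at its
#' equilibrium geometry. For a pair spring the Hessian block is
#' k u u^T + k (1 - r0/r) (I - u u^T); when rest lengths equal the build
#' distances the transverse term vanishes, leaving floppy transverse modes at
#' zero frequency, as expected for a stretch-only network.
#'
#' @param top a [Topology-class]
#' @param vectors return eigenvectors too?
#' @return list with `wavenumbers` (1/cm, ascending; numerically negative
#'   eigenvalues are clipped to 0) and optionally `vectors`
#' @export
normalModes <- function(top, vectors = FALSE) {
  n <- length(top@masses)
  H <- matrix(0, 3 * n, 3 * n)
  sp <- top@springs
  for (s in seq_len(nrow(sp))) {
    i <- sp$i[s]; j <- sp$j[s]
    d <- .mimDisp(top@positions[i, , drop = FALSE],
                  top@positions[j, , drop = FALSE], top@box)[1, ]
    r <- sqrt(sum(d^2)); u <- d / r
    B <- sp$k[s] * (u %o% u) +
      sp$k[s] * (1 - sp$r0[s] / r) * (diag(3) - u %o% u)
    ii <- (3 * (i - 1) + 1):(3 * i); jj <- (3 * (j - 1) + 1):(3 * j)
    H[ii, ii] <- H[ii, ii] + B
    H[jj, jj] <- H[jj, jj] + B
    H[ii, jj] <- H[ii, jj] - B
    H[jj, ii] <- H[jj, ii] - B
  }
  im <- rep(1 / sqrt(top@masses), each = 3)
  Hm <- H * (im %o% im)
  eg <- eigen((Hm + t(Hm)) / 2, symmetric = TRUE)
  lam <- pmax(rev(eg$values), 0)
  nu <- sqrt(lam) / (2 * pi * .c_cm_fs)
  out <- list(wavenumbers = nu)
  if (vectors) out$vectors <- eg$vectors[, rev(seq_len(3 * n)), drop = FALSE]
  out
}
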