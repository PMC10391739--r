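#' Construct a spinel cell description
#'
#' @param a cell edge (angstrom)
#' @param u oxygen 32e positional parameter; the ideal-spinel value for origin
#'   choice 2 is 0.25, the magnetite refinement default is 0.2549
#' @param f octahedral (16d) site occupancy factor in (0, 1]; maghemite's
#'   charge-balance value is 5/6, magnetite's is 1
#' @param originChoice Fd-3m origin setting label
#' @return a [SpinelCell-class]
#' @examples
#' spinelCell(a = 8.3561, f = 0.83)
#' @export
spinelCell <- function(a = 8.3561, u = 0.2549, f = maghemiteSof(),
                       originChoice = "2") {
  new("SpinelCell", a = a, u = u, f = f, originChoice = originChoice)
}

#' Spinel stoichiometry from the octahedral occupancy
#'
#' For a spinel Fe\eqn{_x}O\eqn{_4} with full tetrahedral occupancy and
#' octahedral occupancy `f`, one unit cell holds 8 + 16 f Fe per 32 O, so
#' x = (8 + 16 f) / 8 = 1 + 2 f.
#'
#' @param f octahedral site occupancy factor, in (0, 1]
#' @return x, the Fe per 4 O
#' @examples
#' xFromSof(0.83)   # 2.66
#' xFromSof(1)      # magnetite, 3
#' @export
xFromSof <- function(f) {
  if (any(!is.finite(f)) || any(f <= 0 | f > 1))
    stop("invalid occupancy: f must be in (0, 1]")
  1 + 2 * f
}

#' Octahedral occupancy from the spinel stoichiometry
#'
#' Inverse of [xFromSof()]: f = (x - 1) / 2.
#'
#' @param x Fe per 4 O, in (1, 3]
#' @return octahedral site occupancy factor
#' @examples
#' sofFromX(2.66)   # 0.83
#' @export
sofFromX <- function(x) {
  if (any(!is.finite(x)) || any(x <= 1 | x > 3))
    stop("non-spinel stoichiometry: x must be in (1, 3]")
  (x - 1) / 2
}

#' Charge-balance occupancy of maghemite
#'
#' With all iron oxidized to Fe(3+) and 32 O(2-) per cell, neutrality forces
#' 3 (8 + 16 f) = 64, i.e. f = 5/6, the ideal maghemite occupancy
#' (Fe\eqn{_{8/3}}O\eqn{_4}).
#'
#' @return the octahedral occupancy 5/6
#' @examples
#' xFromSof(maghemiteSof())   # 2.667 (= 8/3)
#' @export
maghemiteSof <- function() 5 / 6

#' Stoichiometry from explicit atom counts
#'
#' @param nFe number of Fe atoms
#' @param nO number of O atoms (> 0)
#' @return x = 4 nFe / nO, the Fe per 4 O
#' @examples
#' xFromCounts(52, 80)   # 2.60, the functionalized slab stoichiometry
#' @export
xFromCounts <- function(nFe, nO) {
  if (nFe < 0) stop("nFe must be >= 0")
  if (nO <= 0) stop("empty model: nO must be > 0")
  4 * nFe / nO
}

## fractional coordinates + classes of one spinel unit cell
.unitCellFractional <- function(cell) {
  frac <- rbind(.wyckoff8a, .wyckoff16d, .oxygenOrbit(cell@u))
  list(frac = frac,
       siteClass = c(rep("tet_Fe", 8), rep("oct_Fe", 16), rep("lattice_O", 32)),
       element = c(rep("Fe", 24), rep("O", 32)),
       occupancy = c(rep(1, 8), rep(cell@f, 16), rep(1, 32)))
}

.atomsFromParts <- function(element, xyz, occupancy, siteClass) {
  data.frame(element = element, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occupancy = occupancy, siteClass = siteClass,
             stringsAsFactors = FALSE)
}

#' Realize one spinel unit cell as an explicit atom list
#'
#' Places the 8 tetrahedral (8a), 16 octahedral (16d, occupancy `f`) and 32
#' oxygen (32e at parameter `u`) sites of one Fd-3m cell at Cartesian
#' coordinates (fractional times `a`).
#'
#' @param cell a [SpinelCell-class]
#' @return a [NanocrystalModel-class] with 56 sites
#' @examples
#' nAtoms(buildUnitCell(spinelCell()))   # 56
#' @export
buildUnitCell <- function(cell) {
  stopifnot(is(cell, "SpinelCell"))
  p <- .unitCellFractional(cell)
  new("NanocrystalModel",
      atoms = .atomsFromParts(p$element, p$frac * cell@a, p$occupancy,
                              p$siteClass),
      diameter = NA_real_, cell = cell)
}

#' Cut a spherical nanocrystal from the spinel lattice
#'
#' Retains every lattice site within D/2 of the center. Octahedral sites keep
#' the cell's fractional occupancy `f`; vacancies can be made explicit with
#' [assignVacancies()]. Deterministic for fixed inputs; the atom count grows
#' as D^3.
#'
#' @param cell a [SpinelCell-class]
#' @param D sphere diameter in nm
#' @param center center of the sphere in fractional cell coordinates
#' @return a [NanocrystalModel-class]
#' @examples
#' m <- cutSphere(spinelCell(f = 0.83), D = 2)
#' @export
cutSphere <- function(cell, D, center = c(0, 0, 0)) {
  stopifnot(is(cell, "SpinelCell"))
  if (D < 0) stop("D must be >= 0")
  R <- D * 10 / 2  # nm -> angstrom radius
  p <- .unitCellFractional(cell)
  if (R == 0) {
    return(new("NanocrystalModel",
               atoms = .atomsFromParts(character(0),
                                       matrix(0, 0, 3), numeric(0),
                                       character(0)),
               diameter = D, cell = cell))
  }
  nmax <- ceiling(R / cell@a) + 1L
  rng <- -nmax:nmax
  cells <- as.matrix(expand.grid(rng, rng, rng))
  nb <- nrow(p$frac); nc <- nrow(cells)
  frac <- p$frac[rep(seq_len(nb), times = nc), , drop = FALSE] +
    cells[rep(seq_len(nc), each = nb), , drop = FALSE]
  xyz <- sweep(frac, 2, center) * cell@a
  keep <- rowSums(xyz^2) <= R^2
  new("NanocrystalModel",
      atoms = .atomsFromParts(rep(p$element, times = nc)[keep],
                              xyz[keep, , drop = FALSE],
                              rep(p$occupancy, times = nc)[keep],
                              rep(p$siteClass, times = nc)[keep]),
      diameter = D, cell = cell)
}

## minimum-image squared distances from point `p` to rows of `xyz`
.mimd2 <- function(p, xyz, box) {
  d <- sweep(xyz, 2, p)
  if (length(box) == 3L)
    d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
  rowSums(d^2)
}

#' Realize octahedral vacancies explicitly
#'
#' Deletes a fraction (1 - f) of the octahedral Fe sites by seeded rejection
#' sampling, forbidding any two vacancies closer than `dMin` (with periodic
#' minimum-image convention where the model has a box). Remaining sites get
#' occupancy 1. For a [SlabModel-class], sites anchoring an attachment
#' (hydroxyl, silane) are never deleted. The deleted count is
#' round((1 - f) * n_oct), so the realized fraction is exact whenever
#' (1 - f) * n_oct is an integer. Identical seeds give identical output.
#'
#' @param model a [NanocrystalModel-class] or [SlabModel-class]
#' @param f target octahedral occupancy in (0, 1]
#' @param dMin vacancy-vacancy exclusion distance (angstrom); the default,
#'   a * sqrt(2)/4, is the nearest 16d-16d contact, so no two vacancies are
#'   nearest neighbours
#' @param seed integer seed
#' @param maxAttempts rejection-sampling retry cap
#' @return the model with vacant oct_Fe rows removed
#' @export
assignVacancies <- function(model, f, dMin = NULL, seed = 1L,
                            maxAttempts = 10000L) {
  stopifnot(is(model, "NanocrystalModel") || is(model, "SlabModel"))
  if (f <= 0 || f > 1) stop("invalid occupancy: f must be in (0, 1]")
  if (is.null(dMin)) dMin <- model@cell@a * sqrt(2) / 4
  if (dMin < 0) stop("dMin must be >= 0")
  at <- model@atoms
  octIdx <- which(at$siteClass == "oct_Fe")
  nDel <- round((1 - f) * length(octIdx))
  if (nDel == 0L) {
    at$occupancy[octIdx] <- 1
    model@atoms <- at
    return(model)
  }
  protected <- integer(0)
  box <- numeric(0)
  if (is(model, "SlabModel")) {
    protected <- unlist(lapply(model@attachments, `[[`, "anchor"))
    box <- model@box
  }
  pool <- setdiff(octIdx, protected)
  if (length(pool) < nDel) stop("over-constrained vacancy plan: pool too small")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  chosen <- .withSeed(seed, {
    sel <- integer(0)
    attempts <- 0L
    while (length(sel) < nDel) {
      attempts <- attempts + 1L
      if (attempts > maxAttempts)
        stop("over-constrained vacancy plan: no admissible site after ",
             maxAttempts, " attempts")
      cand <- pool[sample.int(length(pool), 1L)]
      if (cand %in% sel) next
      if (length(sel) &&
          min(.mimd2(xyz[cand, ], xyz[sel, , drop = FALSE], box)) < dMin^2)
        next
      sel <- c(sel, cand)
    }
    sel
  })
  keep <- setdiff(seq_len(nrow(at)), chosen)
  remap <- integer(nrow(at)); remap[keep] <- seq_along(keep)
  at <- at[keep, , drop = FALSE]
  rownames(at) <- NULL
  at$occupancy[at$siteClass == "oct_Fe"] <- 1
  model@atoms <- at
  if (is(model, "SlabModel") && length(model@attachments)) {
    model@attachments <- lapply(model@attachments, function(att) {
      att$anchor <- remap[att$anchor]
      att$fragment <- remap[att$fragment]
      att
    })
  }
  model
}
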