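## Extended-XYZ trajectory IO with per-atom velocities.

#' Write a trajectory to extended-XYZ
#'
#' One extended-XYZ frame per stored step, with
#' `Properties=species:S:1:pos:R:3:vel:R:3` and a `Time=` key (fs) in the
#' comment line. Positions/velocities round-trip through [readTrajectory()]
#' to better than 1e-6.
#'
#' @param traj a [Trajectory-class]
#' @param path output file
#' @param stride write every `stride`-th frame
#' @return `path`, invisibly
#' @export
writeTrajectory <- function(traj, path, stride = 1L) {
  stopifnot(is(traj, "Trajectory"))
  nf <- nFrames(traj); n <- nAtoms(traj)
  if (!nf) stop("trajectory non-empty required")
  box <- if (length(traj@box) == 3L) traj@box else c(0, 0, 0)
  frames <- seq(1L, nf, by = as.integer(stride))
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    writeLines(sprintf("%d", n), con)
    writeLines(paste(.latticeString(box),
                     "Properties=species:S:1:pos:R:3:vel:R:3",
                     sprintf("Time=%.6f", (fr - 1) * traj@dt)), con)
    writeLines(sprintf("%-2s %.10g %.10g %.10g %.10g %.10g %.10g",
                       traj@elements,
                       traj@positions[, 1, fr], traj@positions[, 2, fr],
                       traj@positions[, 3, fr],
                       traj@velocities[, 1, fr], traj@velocities[, 2, fr],
                       traj@velocities[, 3, fr]), con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' Frames must carry velocities (a `vel` field in the `Properties` header);
#' a file without velocities signals an error, since the momentum analyses
#' require them. Frames are returned in time order.
#'
#' @param path input extended-XYZ file
#' @return a [Trajectory-class]
#' @export
readTrajectory <- function(path) {
  lines <- readLines(path)
  ptr <- 1L
  posL <- list(); velL <- list(); times <- numeric(0); el <- NULL
  box <- numeric(0)
  while (ptr <= length(lines) && nzchar(trimws(lines[ptr]))) {
    n <- as.integer(trimws(lines[ptr]))
    comment <- lines[ptr + 1L]
    pm <- regmatches(comment, regexec("Properties=([^ ]+)", comment))[[1]]
    if (length(pm) < 2) stop("missing Properties header")
    fields <- strsplit(pm[2], ":")[[1]]
    nm <- fields[seq(1, length(fields), by = 3)]
    cnt <- as.integer(fields[seq(3, length(fields), by = 3)])
    offs <- cumsum(c(1, cnt))[seq_along(cnt)]
    if (!"vel" %in% nm)
      stop("insufficient input for momentum analysis: no velocities in file")
    posCol <- offs[match("pos", nm)]
    velCol <- offs[match("vel", nm)]
    tm <- regmatches(comment, regexec("Time=([0-9eE.+-]+)", comment))[[1]]
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else
      length(times))
    lm <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]]
    if (length(lm) == 2) {
      v <- as.numeric(strsplit(trimws(lm[2]), "\\s+")[[1]])
      if (any(v != 0)) box <- v[c(1, 5, 9)]
    }
    body <- lines[ptr + 1L + seq_len(n)]
    toks <- strsplit(trimws(body), "\\s+")
    if (is.null(el)) el <- vapply(toks, `[[`, "", 1)
    posL[[length(posL) + 1L]] <-
      t(vapply(toks, function(tk)
        as.numeric(tk[posCol + 0:2]), numeric(3)))
    velL[[length(velL) + 1L]] <-
      t(vapply(toks, function(tk)
        as.numeric(tk[velCol + 0:2]), numeric(3)))
    ptr <- ptr + 2L + n
  }
  nf <- length(posL)
  if (!nf) stop("no frames in file")
  ord <- order(times)
  n <- length(el)
  pos <- array(0, c(n, 3, nf)); vel <- array(0, c(n, 3, nf))
  for (k in seq_len(nf)) {
    pos[, , k] <- posL[[ord[k]]]
    vel[, , k] <- velL[[ord[k]]]
  }
  dt <- if (nf > 1) diff(sort(times))[1] else 1
  new("Trajectory", dt = dt, positions = pos, velocities = vel,
      masses = .elementMass(el), elements = el, box = box, tags = list(),
      meta = list(source = path))
}
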