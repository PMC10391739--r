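test_that("form factors reproduce electron counts and decay monotonically", {
  Z <- c(H = 1, C = 6, N = 7, O = 8, Si = 14, Fe = 26)
  for (el in names(Z))
    expect_lt(abs(formFactor(el, 0) - Z[el]) / Z[el], 0.02)
  q <- seq(0, 25, by = 0.05)
  for (el in c("Fe", "O", "Si"))
    expect_true(all(diff(formFactor(el, q)) <= 1e-12))
  expect_error(formFactor("Xx", 1), "unknown element")
  expect_error(formFactor("Fe", -1), "q must be")
})

test_that("Debye intensity limits: single atom and two-atom q -> 0", {
  cell <- fixtureCell()
  one <- buildUnitCell(cell)     # keep a single site
  one@atoms <- one@atoms[1, , drop = FALSE]
  one@atoms$occupancy <- 1
  q <- seq(0.5, 10, by = 0.1)
  p1 <- debyeIntensity(one, q, mode = "direct")
  expect_equal(p1@I, formFactor(one@atoms$element[1], q)^2, tolerance = 1e-12)
  ## two atoms: I(q -> 0+) -> (f1 + f2)^2
  two <- one
  two@atoms <- rbind(one@atoms, one@atoms)
  two@atoms$x[2] <- two@atoms$x[2] + 2.0
  two@atoms$element[2] <- "O"
  pz <- debyeIntensity(two, 1e-5, mode = "direct")
  expect_equal(pz@I, (formFactor("Fe", 1e-5) + formFactor("O", 1e-5))^2,
               tolerance = 1e-6)
  expect_error(debyeIntensity(cutSphere(cell, 0), q), "empty model")
  expect_error(debyeIntensity(one, c(-1, 1)), "q must be")
})

test_that("histogram mode matches the brute-force double sum", {
  cl <- fixtureCluster()
  expect_gte(nAtoms(cl), 200L)
  q <- seq(0.5, 10, by = 0.01)
  direct <- debyeIntensity(cl, q, mode = "direct")@I
  hist01 <- debyeIntensity(cl, q, mode = "histogram", binWidth = 0.01)@I
  expect_lt(max(abs(hist01 - direct) / direct), 1e-3)
  ## binning error is bounded and decreases with bin width
  errs <- vapply(c(0.05, 0.02, 0.01), function(bw)
    max(abs(debyeIntensity(cl, q, mode = "histogram", binWidth = bw)@I -
              direct) / direct), numeric(1))
  expect_true(all(diff(errs) <= errs[-length(errs)] * 0.1))
  expect_lt(errs[1], 0.05)
})

test_that("Debye intensity is invariant under rigid motion", {
  cl <- fixtureCluster()
  q <- seq(0.5, 8, by = 0.05)
  ref <- debyeIntensity(cl, q, mode = "direct")@I
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- cl
  xyz <- as.matrix(atoms(cl)[, c("x", "y", "z")]) %*% t(R)
  rot@atoms$x <- xyz[, 1] + 3.7
  rot@atoms$y <- xyz[, 2] - 11.1
  rot@atoms$z <- xyz[, 3] + 0.4
  moved <- debyeIntensity(rot, q, mode = "direct")@I
  expect_lt(max(abs(moved - ref) / ref), 1e-10)
})

test_that("occupancy weighting equals the explicit-vacancy seed average", {
  ## <= 300-site cluster, 20 explicit realizations with unconstrained
  ## vacancy placement (dMin = 0, matching the independent-site model)
  cell <- fixtureCell(f = 1)
  cl <- cutSphere(cell, D = 1.8)
  expect_lte(nAtoms(cl), 300L)
  nOct <- sum(atoms(cl)$siteClass == "oct_Fe")
  f <- 0.75
  nDel <- round((1 - f) * nOct)
  fReal <- (nOct - nDel) / nOct
  q <- seq(0.5, 8, by = 0.04)
  Is <- vapply(1:20, function(s)
    debyeIntensity(assignVacancies(cl, f = f, dMin = 0, seed = s), q,
                   mode = "histogram")@I, numeric(length(q)))
  mc <- rowMeans(Is)
  occModel <- cl
  occModel@atoms$occupancy[occModel@atoms$siteClass == "oct_Fe"] <- fReal
  Iocc <- debyeIntensity(occModel, q, mode = "histogram")@I
  ## integrated agreement within Monte-Carlo + finite-count error
  expect_lt(sum(abs(mc - Iocc)) / sum(Iocc), 0.02)
  se <- apply(Is, 1, stats::sd) / sqrt(ncol(Is))
  expect_lt(stats::median(abs(mc - Iocc) / (se + 1e-12)), 4)
})

test_that("population pattern reduces to a single diameter as sd -> 0", {
  cell <- fixtureCell()
  q <- seq(0.5, 6, by = 0.02)
  pop <- populationPattern(cell, sizeDistribution(2, 1e-9, 5), q,
                           nClasses = 10)
  single <- debyeIntensity(cutSphere(cell, 2), q, mode = "histogram")@I
  expect_equal(pop@I, single, tolerance = 1e-10)
})

test_that("population class weights are normalized", {
  cls <- nanotherm:::.sizeClasses(sizeDistribution(2.1, 1.9, 40), 40)
  expect_equal(sum(cls$w), 1, tolerance = 1e-12)
  expect_error(populationPattern(fixtureCell(), sizeDistribution(2, 0.5, 5),
                                 seq(0.5, 4, 0.05), nClasses = 0),
               "nClasses")
})

test_that("peak widths shrink with growing mean size (Scherrer behavior)", {
  cell <- fixtureCell()
  q <- seq(2.1, 2.9, by = 0.002)    # window around the strongest reflection
  fwhm <- function(I) {
    I <- I - min(I); pk <- which.max(I); h <- I[pk] / 2
    lo <- max(which(I[seq_len(pk)] < h))
    hi <- pk - 1 + min(which(I[pk:length(I)] < h))
    q[hi] - q[lo]
  }
  widths <- vapply(c(2, 5, 10), function(D)
    fwhm(populationPattern(cell, sizeDistribution(D, 1e-9, 3 * D), q,
                           nClasses = 1)@I), numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("finite-coherence approximation tracks the exact pattern", {
  cell <- fixtureCell()
  q <- seq(0.5, 8, by = 0.02)
  d <- sizeDistribution(4, 1e-9, 8)
  exact <- populationPattern(cell, d, q, nClasses = 1, exactMaxD = 4.5)@I
  approx <- populationPattern(cell, d, q, nClasses = 1, exactMaxD = 3,
                              coherenceRadius = 110)@I
  expect_lt(sqrt(mean((approx - exact)^2)) / mean(exact), 0.05)
})

test_that("mass moments: degenerate, closed-form and truncated cases", {
  ## narrow distribution: mass mean collapses to the number mean
  mmNarrow <- massMoments(sizeDistribution(2, 0.02, 6))
  expect_equal(unname(mmNarrow["meanM"]), 2, tolerance = 1e-3)
  ## untruncated log-normal: mass distribution is log-normal with mu + 3 sigma^2
  d <- sizeDistribution(2.1, 1.9, 4000)
  lp <- logParams(d)
  mm <- massMoments(d)
  muM <- lp["mu"] + 3 * lp["sigma"]^2
  expect_equal(unname(mm["meanM"]), unname(exp(muM + lp["sigma"]^2 / 2)),
               tolerance = 1e-6)
  expect_equal(unname(mm["sdM"]),
               unname(exp(muM + lp["sigma"]^2 / 2) *
                        sqrt(exp(lp["sigma"]^2) - 1)), tolerance = 1e-6)
  ## 40 nm-truncated study distribution lands near the mass-based table values
  mm40 <- massMoments(sizeDistribution(2.1, 1.9, 40))
  expect_gt(mm40["meanM"], 9); expect_lt(mm40["meanM"], 13)
  expect_gt(mm40["sdM"], 6.5); expect_lt(mm40["sdM"], 9.5)
})

test_that("pattern files round-trip through the two-column format", {
  pat <- debyeIntensity(fixtureCluster(), seq(0.5, 6, 0.05),
                        mode = "histogram")
  path <- withr::local_tempfile(fileext = ".txt")
  writePattern(pat, path)
  back <- readPattern(path)
  expect_equal(back@q, pat@q, tolerance = 1e-7)
  expect_equal(back@I, pat@I, tolerance = 1e-7)
  expect_equal(back@meta$mode, "histogram")
})
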