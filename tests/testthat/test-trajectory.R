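test_that("slab topology wires the documented spring network", {
  slab <- fixtureAssembledSlab()
  top <- fixtureTopology()
  at <- atoms(slab)
  sp <- top@springs
  ## exactly 2 intramolecular O-H springs per water
  watO <- which(at$siteClass == "water" & at$element == "O")
  for (o in watO[1:10])
    expect_equal(sum((sp$i == o | sp$j == o) & sp$class == "covalent"), 2L)
  nWatOH <- sum(sp$class == "covalent" &
                  at$siteClass[sp$i] == "water" & at$siteClass[sp$j] == "water")
  expect_equal(nWatOH, 82L)
  ## covalent chain from the anchoring Fe to the ammonium N: on the
  ## hydrogen-bond-free subgraph the shortest route is Fe-O-Si-C-C-C-N
  cov <- sp[sp$class != "hbond", ]
  gcov <- igraph::graph_from_edgelist(cbind(cov$i, cov$j), directed = FALSE)
  dcov <- igraph::distances(gcov, v = top@tags$anchor_Fe,
                            to = top@tags$amine_N)
  expect_equal(unname(dcov[1, 1]), 6)
  ## with hydrogen bonds included, water-mediated routes may be shorter
  g <- igraph::graph_from_edgelist(cbind(sp$i, sp$j), directed = FALSE)
  dall <- igraph::distances(g, v = top@tags$anchor_Fe, to = top@tags$amine_N)
  expect_lte(dall[1, 1], dcov[1, 1])
  ## brute-force pair enumeration reproduces the spring count
  tbl <- springTable()
  xyz <- as.matrix(at[, c("x", "y", "z")])
  box <- boxEdges(slab)
  cnt <- 0L
  for (i in seq_len(nrow(at) - 1)) {
    d <- sweep(xyz[(i + 1):nrow(at), , drop = FALSE], 2, xyz[i, ])
    d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
    r <- sqrt(rowSums(d^2))
    ej <- at$element[(i + 1):nrow(at)]
    for (k in seq_len(nrow(tbl))) {
      match_ <- (at$element[i] == tbl$e1[k] & ej == tbl$e2[k]) |
        (at$element[i] == tbl$e2[k] & ej == tbl$e1[k])
      cnt <- cnt + sum(match_ & r > tbl$rmin[k] & r <= tbl$rmax[k])
    }
  }
  expect_equal(nrow(sp), cnt)
})

test_that("a harmonic dimer oscillates at its analytic eigenfrequency", {
  top <- makeDimer(nu = 3600)
  top@positions[2, 1] <- top@positions[2, 1] + 0.03   # stretch and release
  tr <- integrateNVE(top, dt = 0.01, nSteps = 6000, Tinit = 0, seed = 1)
  blen <- sqrt(colSums((tr@positions[2, , ] - tr@positions[1, , ])^2))
  ## period from successive maxima of the bond length
  pk <- which(diff(sign(diff(blen))) == -2) + 1
  period <- mean(diff(pk)) * tr@dt
  m <- top@masses
  omega <- sqrt(top@springs$k[1] * sum(m) / prod(m))
  expect_lt(abs(period - 2 * pi / omega) / (2 * pi / omega), 1e-3)
})

test_that("zero-temperature equilibrium start stays static", {
  tr <- integrateNVE(makeDimer(), dt = 0.5, nSteps = 200, Tinit = 0, seed = 1)
  expect_lt(max(abs(tr@positions[, , 200] - tr@positions[, , 1])), 1e-12)
  expect_equal(max(abs(tr@velocities)), 0)
})

test_that("NVE conserves energy and COM momentum on the slab network", {
  top <- fixtureTopology()
  tr <- integrateNVE(top, dt = 0.5, nSteps = 100000L, Tinit = 298, seed = 21,
                     sampleEvery = 100L)
  e <- tr@meta$energies
  etot <- e$kinetic + e$potential
  drift <- abs(mean(utils::tail(etot, 50)) - mean(utils::head(etot, 50))) /
    abs(mean(etot))
  expect_lt(drift, 1e-4)
  ## COM momentum removed at initialization and conserved to numerical noise
  pScale <- sum(tr@masses) * sqrt(kBfix * 298 / mean(tr@masses))
  for (fr in c(1, 500, 1000)) {
    p <- colSums(tr@velocities[, , fr] * tr@masses)
    expect_lt(max(abs(p)) / pScale, 1e-10)
  }
})

test_that("unstable timesteps trip the energy guard", {
  expect_error(integrateNVE(makeDimer(nu = 3600), dt = 8, nSteps = 5000,
                            Tinit = 300, seed = 2), "unstable dt")
})

test_that("Langevin dynamics is seed-deterministic and thermostats correctly", {
  top <- fixtureTopology()
  th <- thermostatSpec(298, 0.002, 5)
  t1 <- integrateLangevin(top, th, dt = 0.4, nSteps = 500, sampleEvery = 5)
  t2 <- integrateLangevin(top, th, dt = 0.4, nSteps = 500, sampleEvery = 5)
  expect_identical(t1@positions, t2@positions)
  expect_identical(t1@velocities, t2@velocities)
  ## overdamped zero-temperature limit: velocities decay to zero
  cold <- integrateLangevin(makeDimer(), thermostatSpec(0, 0.5, 1), dt = 0.5,
                            nSteps = 400, Tinit = 300)
  expect_lt(max(abs(cold@velocities[, , 400])),
            1e-6 * max(abs(cold@velocities[, , 1])))
})

test_that("equipartition holds across atom masses in a thermostated run", {
  top <- fixtureTopology()
  tr <- integrateLangevin(top, thermostatSpec(298, 0.002, 14), dt = 0.4,
                          nSteps = 25000L, sampleEvery = 10L)
  skip <- 500   # discard equilibration frames
  v2 <- apply(tr@velocities[, , -(1:skip)]^2, 1, mean)  # per component
  Tatom <- tr@masses * v2 / kBfix
  expect_lt(abs(mean(Tatom) - 298) / 298, 0.03)
  expect_gt(mean(abs(Tatom - 298) / 298 < 0.25), 0.90)
  expect_true(all(abs(Tatom - 298) / 298 < 0.6))
})

test_that("trajectories round-trip through extended XYZ with velocities", {
  top <- makeDimer()
  tr <- integrateNVE(top, dt = 0.4, nSteps = 3, Tinit = 200, seed = 3)
  path <- withr::local_tempfile(fileext = ".extxyz")
  writeTrajectory(tr, path)
  back <- readTrajectory(path)
  expect_equal(nFrames(back), 3L)
  expect_identical(back@elements, tr@elements)
  expect_lt(max(abs(back@positions - tr@positions)), 1e-6)
  expect_lt(max(abs(back@velocities - tr@velocities)), 1e-6)
  expect_equal(back@dt, tr@dt)
})

test_that("trajectory files without velocities are rejected", {
  path <- withr::local_tempfile(fileext = ".extxyz")
  writeLines(c("2",
               'Lattice="10 0 0 0 10 0 0 0 10" Properties=species:S:1:pos:R:3',
               "O 0 0 0", "H 1 0 0"), path)
  expect_error(readTrajectory(path), "no velocities")
})
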