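test_that("(111) surface cell dimensions follow a*sqrt(3/2) x a*sqrt(2)", {
  slab <- build111Slab(spinelCell(a = 8.3561, f = 0.9), 14)
  expect_equal(round(boxEdges(slab)[1], 3), 10.234)
  expect_equal(round(boxEdges(slab)[2], 3), 11.817)
  expect_equal(boxEdges(build111Slab(spinelCell(a = 1, f = 0.9), 2,
                                     hydroxylCount = 0))[1:2],
               c(sqrt(1.5), sqrt(2)), tolerance = 1e-12)
  slab3 <- build111Slab(spinelCell(a = 8.396, f = 0.9), 14)
  expect_equal(round(boxEdges(slab3)[1:2], 3), c(10.283, 11.874))
  for (a in c(5, 8.3561, 12.7)) {
    b <- boxEdges(build111Slab(spinelCell(a = a, f = 0.9), 2.2 * a,
                               hydroxylCount = 0))
    expect_equal(b[2] / b[1], sqrt(4 / 3), tolerance = 1e-12)
  }
})

test_that("slab thickness bounds the atomic span and tiny thickness errors", {
  slab <- build111Slab(fixtureCell(f = 0.9), 14)
  at <- atoms(slab)
  oxide <- at$siteClass %in% c("tet_Fe", "oct_Fe", "lattice_O")
  expect_lte(diff(range(at$z[oxide])), 14)
  expect_error(build111Slab(fixtureCell(), 3), "degenerate slab")
})

test_that("default termination realizes the 16/40/76 oxide composition", {
  slab <- build111Slab(fixtureCell(f = 0.9), 14)
  counts <- siteClassCounts(slab)
  expect_equal(unname(counts[c("tet_Fe", "oct_Fe", "lattice_O",
                               "hydroxyl_O", "hydroxyl_H")]),
               c(16L, 40L, 76L, 4L, 4L))
})

test_that("attachSilane adds the documented fragment with target geometry", {
  slab <- assignVacancies(build111Slab(fixtureCell(f = 0.9), 14), 0.9,
                          seed = 11)
  geo <- silaneGeometry()
  out <- attachSilane(slab, geometry = geo)
  att <- out@attachments[[length(out@attachments)]]
  added <- table(factor(atoms(out)$element[att$fragment],
                        levels = c("Fe", "O", "H", "Si", "C", "N")))
  expect_equal(unname(as.integer(added)),
               c(0L, 3L, 15L, 1L, 5L, 1L))   # bridge O + 2 methoxy O
  expect_equal(att$kind, "silane")
  at <- atoms(out)
  fe <- as.numeric(at[att$anchor, c("x", "y", "z")])
  ob <- as.numeric(at[att$fragment[1], c("x", "y", "z")])
  si <- as.numeric(at[att$fragment[2], c("x", "y", "z")])
  expect_lt(abs(sqrt(sum((fe - ob)^2)) - geo@rFeO), 0.05)
  expect_lt(abs(sqrt(sum((ob - si)^2)) - geo@rOSi), 0.05)
  ang <- acos(sum((fe - ob) * (si - ob)) /
                sqrt(sum((fe - ob)^2) * sum((si - ob)^2))) * 180 / pi
  expect_lt(abs(ang - geo@angleFeOSi), 5)
})

test_that("attachSilane rejects non-surface anchors", {
  slab <- build111Slab(fixtureCell(f = 0.9), 14)
  at <- atoms(slab)
  zc <- mean(range(at$z))
  mid <- which(at$element == "Fe")[which.min(abs(at$z[at$element == "Fe"] - zc))]
  expect_error(attachSilane(slab, anchorFe = mid), "invalid anchor")
})

test_that("solvate places the requested count with spacing respected", {
  slab <- attachSilane(assignVacancies(build111Slab(fixtureCell(0.9), 14),
                                       0.9, seed = 11))
  expect_identical(atoms(solvate(slab, nWaters = 0, seed = 1)), atoms(slab))
  wet <- solvate(slab, nWaters = 41, dMin = 2.6, seed = 12)
  at <- atoms(wet)
  expect_equal(sum(at$siteClass == "water" & at$element == "O"), 41L)
  ## every water O at least dMin from every other heavy atom (minimum image)
  box <- boxEdges(wet)
  heavy <- as.matrix(at[at$element != "H", c("x", "y", "z")])
  wOidx <- which(at$element != "H" & at$siteClass == "water")
  hvyO <- as.matrix(at[wOidx, c("x", "y", "z")])
  for (i in seq_len(nrow(hvyO))) {
    d2 <- nanotherm:::.mimd2(hvyO[i, ], heavy, box)
    expect_gte(sqrt(min(d2[d2 > 1e-9])), 2.6 - 1e-9)
  }
  ## seeded determinism
  wet2 <- solvate(slab, nWaters = 41, dMin = 2.6, seed = 12)
  expect_identical(atoms(wet), atoms(wet2))
})

test_that("solvation by target density places the matching count", {
  slab <- build111Slab(fixtureCell(0.9), 14, hydroxylCount = 0)
  wet <- solvate(slab, targetDensity = 0.5, dMin = 2.6, seed = 9)
  at <- atoms(wet)
  n <- sum(at$siteClass == "water" & at$element == "O")
  ## expected count: density * accessible gap volume / water mass
  oxide <- atoms(slab)
  gap <- (min(oxide$z) - 1 + boxEdges(slab)[3]) - (max(oxide$z) + 1)
  vol <- prod(boxEdges(slab)[1:2]) * gap
  nExp <- round(0.5 * 6.02214076e23 / 18.01528 * 1e-24 * vol)
  expect_equal(n, nExp)
  expect_error(solvate(slab, seed = 1), "nWaters or targetDensity")
})

test_that("the assembled system reproduces the 284-atom composition", {
  slab <- fixtureAssembledSlab()
  expect_equal(nAtoms(slab), 284L)
  ec <- elementCounts(slab)
  expect_equal(unname(ec[c("Fe", "O", "H", "Si", "C", "N")]),
               c(52L, 124L, 101L, 1L, 5L, 1L))
  ## oxide stoichiometry Fe2.60O4 counting lattice + hydroxyl oxygen
  at <- atoms(slab)
  nFe <- sum(at$element == "Fe")
  nOox <- sum(at$siteClass %in% c("lattice_O", "hydroxyl_O"))
  expect_equal(xFromCounts(nFe, nOox), 2.60)
})

test_that("structure files round-trip atom counts, elements, coordinates", {
  slab <- fixtureAssembledSlab()
  for (fmt in c("xyz", "extxyz", "cif")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    writeStructure(slab, path, fmt)
    back <- readStructure(path, fmt)
    expect_equal(nrow(back), 284L)
    expect_identical(back$element, atoms(slab)$element)
    expect_lt(max(abs(as.matrix(back[, c("x", "y", "z")]) -
                        as.matrix(atoms(slab)[, c("x", "y", "z")]))), 1e-4)
  }
  path <- withr::local_tempfile(fileext = ".xyz")
  writeStructure(slab, path, "xyz")
  expect_equal(as.integer(readLines(path, 1)), 284L)
})

test_that("PDB output parses with an independent reader", {
  slab <- fixtureAssembledSlab()
  path <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(slab, path, "pdb")
  pdb <- bio3d::read.pdb(path)
  expect_equal(nrow(pdb$atom), 284L)
  expect_identical(trimws(pdb$atom$elesy), atoms(slab)$element)
})

test_that("degenerate structure outputs behave as documented", {
  empty <- cutSphere(fixtureCell(), 0)
  path <- withr::local_tempfile(fileext = ".xyz")
  writeStructure(empty, path, "xyz")             # zero-atom xyz is valid
  expect_equal(nrow(readStructure(path)), 0L)
  expect_error(writeStructure(empty, path, "cif"), "non-empty")
  expect_error(writeStructure(empty, path, "pdb"), "non-empty")
  expect_error(writeStructure(fixtureCluster(), path, "mol2"))
})
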