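writeFixture <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

test_that("handcrafted ATOM records parse field by field", {
  f <- writeFixture(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  0.80 12.50           C",
    "HETATM    3  O   HOH A 101       1.000   2.000   3.000  1.00  5.00           O",
    "END"))
  m <- readPDB(f)
  a <- atomData(m)
  expect_equal(nAtoms(m), 3)
  expect_equal(a$name, c("N", "CA", "O"))
  expect_equal(a$resname, c("ALA", "ALA", "HOH"))
  expect_equal(a$resseq, c(1L, 1L, 101L))
  expect_equal(a$het, c(FALSE, FALSE, TRUE))
  expect_equal(a$occupancy, c(1, 0.8, 1))
  expect_equal(atomCoords(m)[2, ], c(x = 11.639, y = 6.071, z = -5.147))
})

test_that("read -> write -> read preserves the atom table and coordinates", {
  toy <- makeToyChain(6, resnames = c("ALA", "GLY", "LEU"))
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  writePDB(toy, f1)
  m1 <- readPDB(f1)
  writePDB(m1, f2)
  m2 <- readPDB(f2)
  for (col in c("name", "resname", "chain", "resseq", "icode", "element"))
    expect_identical(atomData(m1)[[col]], atomData(m2)[[col]])
  expect_equal(atomCoords(m1), atomCoords(m2), tolerance = 1e-12)
  # writer rounds to 3 decimals; source coords survive one rewrite to 5e-4
  expect_lt(max(abs(atomCoords(toy) - atomCoords(m1))), 5e-4 + 1e-12)
})

test_that("multi-MODEL files round trip with model structure intact", {
  base <- makeToyChain(1)   # 5 atoms
  xyz <- atomCoords(base)
  multi <- structureModel(atomData(base),
                          list(xyz, xyz + 1, xyz + 2), source = "tri")
  f <- tempfile(fileext = ".pdb")
  writePDB(multi, f)
  expect_equal(sum(grepl("^MODEL", readLines(f))), 3)
  back <- readPDB(f)
  expect_equal(nModels(back), 3)
  expect_equal(nAtoms(back), 5)
  expect_equal(atomCoords(back, 3), atomCoords(back, 1) + 2,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("alternate locations resolve to highest occupancy with ties to A", {
  f <- writeFixture(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60 10.00           C",
    "ATOM      3  CB AALA A   1       3.000   0.000   0.000  0.50 10.00           C",
    "ATOM      4  CB BALA A   1       4.000   0.000   0.000  0.50 10.00           C",
    "END"))
  m <- readPDB(f)
  expect_equal(nAtoms(m), 2)
  a <- atomData(m)
  expect_equal(a$altloc[a$name == "CA"], "B")   # occupancy wins
  expect_equal(a$altloc[a$name == "CB"], "A")   # tie goes to A
  expect_equal(atomCoords(m)[a$name == "CA", "x"], 2, ignore_attr = TRUE)
})

test_that("malformed and overflowing records raise named errors", {
  f <- writeFixture(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1      11.639"))
  expect_error(readPDB(f), "line 2")
  expect_error(readPDB(writeFixture("END")), "no ATOM")

  big <- makeToyChain(2, startRes = 9999L)
  expect_error(writePDB(big, tempfile()), "9999")
})

test_that("atom selection filters, preserves order, and rejects empty results", {
  toy <- makeToyChain(10)
  expect_equal(nAtoms(selectAtoms(toy, atomNames = "CA")), 10)

  # side chains exist for ALA but not GLY
  gly <- makeToyChain(1, resnames = "GLY")
  expect_error(selectAtoms(gly, sideChainOnly = TRUE), "empty selection")
  ala <- makeToyChain(1, resnames = "ALA")
  expect_equal(atomData(selectAtoms(ala, sideChainOnly = TRUE))$name, "CB")

  # inclusive author-numbered window, mirroring a 436-444 hairpin selection
  chain <- makeToyChain(21, startRes = 430L)
  sel <- selectAtoms(chain, residueRange = c(436, 444))
  expect_equal(length(unique(atomData(sel)$resseq)), 9)

  # idempotence and select-all identity
  sel2 <- selectAtoms(sel, residueRange = c(436, 444))
  expect_identical(atomData(sel), atomData(sel2))
  all_ <- selectAtoms(toy, chains = "A")
  expect_identical(atomData(all_), atomData(toy))
  expect_identical(atomCoords(all_), atomCoords(toy))

  expect_error(selectAtoms(toy, chains = "Z"), "empty selection")
})

test_that("elements are inferred from atom names when the element field is blank", {
  f <- writeFixture(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 10.00",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00 10.00",
    "ATOM      3  SG  CYS A   2       1.000   2.000   3.000  1.00 10.00",
    "ATOM      4  1HB ALA A   1       0.000   0.000   0.000  1.00 10.00",
    "END"))
  a <- atomData(readPDB(f))
  expect_equal(a$element, c("N", "C", "S", "H"))
})
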