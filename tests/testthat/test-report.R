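# end-to-end pipeline on simulated inputs

simulateRuns <- function(K, dH, dir, noiseRelative = 0.002, seedBase = 100) {
  runs <- list()
  for (i in seq_along(K)) {
    label <- names(K)[i]
    exp <- simulateThermogram(OneSiteParams(K = K[i], dH = dH[i]),
                              noiseRelative = noiseRelative,
                              seed = seedBase + i, label = label)
    csv <- file.path(dir, paste0(label, ".csv"))
    cfg <- file.path(dir, paste0(label, ".cfg"))
    writeITC(exp, csv, cfg)
    runs[[i]] <- list(label = label, csv = csv, config = cfg)
  }
  runs
}

test_that("configuration schema rejects empty, unknown and incomplete configs", {
  expect_error(validateRunConfig(list()), "schema")
  expect_error(validateRunConfig(list(bogus = 1)), "unknown config key")
  expect_error(validateRunConfig(list(seed = 1)), "no analysis stage")
  expect_error(validateRunConfig(list(itc = list(runs = list()))), "at least one run")
  expect_error(validateRunConfig(
    list(itc = list(runs = list(list(label = "x"))))), "csv")
  expect_error(validateRunConfig(
    list(coupling = list(single_a = "a", single_b = "b", double = "ab"))),
    "no analysis stage")
  expect_error(validateRunConfig(
    list(interface = list(pdb = "x.pdb", group_a = "chain:A"))), "group_b")
})

test_that("the pipeline reproduces single-mutant penalty columns end to end", {
  dir <- withr::local_tempdir()
  runs <- simulateRuns(table2K, table2dH, dir)
  out <- file.path(dir, "out")
  res <- runRepressorReport(list(
    seed = 1, output_dir = out,
    itc = list(runs = runs, reference = "Hairless")))
  tbl <- res$thermo
  expect_equal(round(tbl$ddG[-1], 1), c(2.1, 2.9, 1.0, 1.4, 1.5))
  expect_true(file.exists(file.path(out, "thermo_table.tsv")))
  expect_true(file.exists(file.path(out, "resolved_config.json")))
})

test_that("the pipeline detects double-mutant coupling from simulated titrations", {
  dir <- withr::local_tempdir()
  runs <- simulateRuns(table3K, table3dH, dir, seedBase = 200)
  out <- file.path(dir, "out")
  res <- runRepressorReport(list(
    output_dir = out,
    itc = list(runs = runs, reference = "Hairless"),
    coupling = list(single_a = "SuH-L445A", single_b = "SuH-L514A",
                    double = "SuH-L445A-L514A")))
  # ddG_int = 2.40 - 1.27 - 0.68 ~ 0.45 kcal/mol of nonadditivity
  expect_equal(res$coupling$ddG_interaction, 0.45, tolerance = 0.1)
  expect_gt(res$coupling$ddG_interaction, 0.3)
  cp <- jsonlite::read_json(file.path(out, "coupling.json"))
  expect_equal(cp$ddG_interaction, res$coupling$ddG_interaction,
               tolerance = 1e-6)
})

test_that("structural stages run from PDB input and reruns are byte-identical", {
  dir <- withr::local_tempdir()
  # two-chain toy complex for the interface stage
  a <- makeToyChain(4, chain = "A")
  b <- makeToyChain(4, chain = "B")
  bXyz <- sweep(atomCoords(b), 2, c(0, -4.5, 0), "+")
  complexModel <- structureModel(rbind(atomData(a), atomData(b)),
                                 rbind(atomCoords(a), bXyz))
  pdb <- file.path(dir, "complex.pdb")
  writePDB(complexModel, pdb)

  # small two-state ensemble for the conformation stage
  ref <- caCoords(makeToyChain(6))
  refB <- ref; refB[3, ] <- refB[3, ] + c(0, 0, 3)
  ts <- makeTwoStateEnsemble(ref, refB, 10, 10, sigma = 0.2, seed = 44)
  ensModel <- structureModel(
    atomData(selectAtoms(makeToyChain(6), atomNames = "CA")),
    lapply(seq_len(20), function(f) atomCoords(ts$ensemble, f)))
  traj <- file.path(dir, "traj.pdb")
  writePDB(ensModel, traj)

  cfg <- list(
    seed = 3, output_dir = file.path(dir, "run1"),
    interface = list(pdb = pdb, group_a = "chain:A", group_b = "chain:B"),
    conformation = list(ensemble_pdb = traj, components = 2))
  res1 <- runRepressorReport(cfg)
  expect_gt(res1$interface@bsaTotal, 0)
  expect_equal(length(res1$pca@eigenvalues), 18)

  cfg$output_dir <- file.path(dir, "run2")
  runRepressorReport(cfg)
  for (f in c("interface_residues.tsv", "interface_contacts.tsv",
              "rmsf.tsv", "pca_projections.tsv", "pca_eigenvalues.tsv")) {
    expect_identical(readLines(file.path(dir, "run1", f)),
                     readLines(file.path(dir, "run2", f)))
  }

  # a missing input aborts with the stage name
  cfg$interface$pdb <- file.path(dir, "absent.pdb")
  cfg$output_dir <- file.path(dir, "run3")
  expect_error(runRepressorReport(cfg), "stage 'interface'")
})
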