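test_that("SMILES parsing builds the expected composition and graph", {
  gly <- parseSmiles("C(O)C(O)C(O)", name = "glycerol")
  expect_equal(formulaCounts(gly), c(C = 3L, H = 8L, O = 3L))
  expect_equal(heavyAtomCount(gly), 6L)
  expect_equal(bondCount(gly), 5L)

  water <- parseSmiles("O")
  expect_equal(formulaCounts(water), c(H = 2L, O = 1L))
  expect_equal(heavyAtomCount(water), 1L)
  expect_equal(bondCount(water), 0L)
  expect_equal(vertexDegrees(water), 0L)

  thf <- parseSmiles("C1COCC1")
  expect_equal(heavyAtomCount(thf), 5L)
  expect_equal(bondCount(thf), 5L)
  expect_true(all(vertexDegrees(thf) == 2L))
  expect_equal(ringCount(thf), 1L)
})

test_that("SMILES errors name the offending token and position", {
  expect_error(parseSmiles("C=C"), "'='.*position 2")
  expect_error(parseSmiles("C[NH4+]C"), "position 2")
  expect_error(parseSmiles("C1CC"), "ring-closure")
  expect_error(parseSmiles("C(OC"), "unmatched '\\('")
  expect_error(parseSmiles("CC)C"), "unmatched '\\)'")
  expect_error(parseSmiles("C(C)(C)(C)(C)C"), "valence")
  expect_error(parseSmiles("cc"), "position 1")
})

test_that("stereo markers are stripped with a warning", {
  expect_warning(m <- parseSmiles("OC/C(O)\\CO"), "stereo")
  expect_equal(formulaCounts(m), c(C = 3L, H = 8L, O = 3L))
})

test_that("adjacency input reproduces the drawn xylitol graph", {
  xyl <- moleculeFromAdjacency(
    atoms = c(rep("C", 5), rep("O", 5)),
    bonds = list(c(1, 2), c(2, 3), c(3, 4), c(4, 5),
                 c(1, 6), c(2, 7), c(3, 8), c(4, 9), c(5, 10)),
    name = "xylitol")
  expect_equal(vertexDegrees(xyl)[1:5], c(2L, 3L, 3L, 3L, 2L))
  expect_true(all(vertexDegrees(xyl)[6:10] == 1L))
  expect_equal(formulaCounts(xyl), c(C = 5L, H = 12L, O = 5L))
})

test_that("degenerate adjacency input is rejected", {
  expect_error(moleculeFromAdjacency(character(), list()), "empty")
  expect_error(
    moleculeFromAdjacency(c("C", "C"), list(c(1, 2), c(1, 2))),
    "duplicate")
  expect_error(
    moleculeFromAdjacency(c("C", "C"), list(c(1, 3))), "out of range")
  expect_error(
    moleculeFromAdjacency(c("C", "C"), list(c(1, 1))), "self-loop")
})

test_that("adjacency round-trip preserves degrees and formula", {
  for (nm in builtinSoluteNames()) {
    m <- builtinSolute(nm)
    m2 <- moleculeFromAdjacency(heavyAtoms(m), bondList(m),
                                explicitH = hydrogenCounts(m), name = nm)
    expect_identical(vertexDegrees(m2), vertexDegrees(m))
    expect_identical(formulaCounts(m2), formulaCounts(m))
  }
})

test_that("built-in solutes match the reference molecular properties", {
  props <- referenceSoluteProperties()
  for (i in seq_len(nrow(props))) {
    m <- builtinSolute(props$solute[i])
    expect_equal(heavyAtomCount(m), props$n_heavy[i], label = props$solute[i])
    # reference bond count includes bonds to hydrogen
    expect_equal(bondCount(m) + sum(hydrogenCounts(m)), props$n_bonds[i],
                 label = props$solute[i])
    expect_equal(ringCount(m), props$n_rings[i], label = props$solute[i])
    expect_equal(molecularFormula(m), props$formula[i],
                 label = props$solute[i])
    # for a connected graph the cyclomatic number is E - V + 1
    expect_equal(bondCount(m) - heavyAtomCount(m) + 1L, ringCount(m),
                 label = props$solute[i])
  }
})

test_that("solute lookup is case-insensitive and rejects unknown names", {
  expect_equal(moleculeName(builtinSolute("GLUCOSE")), "glucose")
  expect_error(builtinSolute("maltose"), "glucose.*erythritol")
})

test_that("hydroxyl counting follows the degree-1 oxygen definition", {
  expect_equal(countHydroxyls(builtinSolute("glucose")), 5L)
  expect_equal(countHydroxyls(builtinSolute("fructose")), 5L)
  expect_equal(countHydroxyls(builtinSolute("glycerol")), 3L)
  expect_equal(countHydroxyls(builtinSolute("sucrose")), 8L)
  expect_equal(countHydroxyls(parseSmiles("O")), 0L)  # water O has degree 0
})

test_that("parser agrees with an independent SMILES implementation", {
  # ChemmineR/ChemmineOB as the external oracle on the built-in library
  suppressPackageStartupMessages(requireNamespace("ChemmineR"))
  for (nm in builtinSoluteNames()) {
    smi <- builtinSoluteSmiles()[[nm]]
    m <- parseSmiles(smi, name = nm)
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(smi))
    expect_equal(heavyAtomCount(m),
                 sum(ChemmineR::atomcount(sdf)[[1]]), label = nm)
    expect_equal(bondCount(m), nrow(ChemmineR::bondblock(sdf[[1]])),
                 label = nm)
    expect_equal(molecularFormula(m),
                 unname(ChemmineR::MF(sdf, addH = TRUE)), label = nm)
  }
})

test_that("SMILES and adjacency files round-trip through readers", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("# comment", "glycerol\tOCC(O)CO", "water\tO"), tsv)
  mols <- readSmilesFile(tsv)
  expect_length(mols, 2L)
  expect_equal(moleculeName(mols[[1]]), "glycerol")

  writeLines(c("glycerol\tOCC(O)CO", "bad\tC=C"), tsv)
  expect_error(readSmilesFile(tsv), "line 2")

  js <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(name = "xylitol", atoms = c(rep("C", 5), rep("O", 5)),
         bonds = list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(1, 6),
                      c(2, 7), c(3, 8), c(4, 9), c(5, 10))),
    js, auto_unbox = TRUE)
  m <- readAdjacencyJson(js)
  expect_equal(firstZagrebIndex(m), 40L)
})

test_that("the valence registry is extensible", {
  expect_error(parseSmiles("B"), "unsupported atom symbol")
  registerValence("B", 3L)
  m <- parseSmiles("B")
  expect_equal(formulaCounts(m), c(B = 1L, H = 3L))
})
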