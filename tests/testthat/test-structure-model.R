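# Parsing structures into residue descriptors and extracting ligand contacts.

writeMiniPdb <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}

THREE_RES_PDB <- c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  CB  ALA A   1       2.000  -0.700   1.200  1.00  0.00           C",
  "ATOM      4  N   GLY A   2       3.300   1.500   0.000  1.00  0.00           N",
  "ATOM      5  CA  GLY A   2       4.000   2.800   0.000  1.00  0.00           C",
  "ATOM      6  CA  LYS A   3       7.000   3.000   1.000  1.00  0.00           C",
  "ATOM      7  CB  LYS A   3       8.000   3.500   1.000  1.00  0.00           C",
  "ATOM      8  NZ  LYS A   3      10.000   4.000   2.000  1.00  0.00           N",
  "HETATM    9  O   HOH A 101       5.000   5.000   5.000  1.00  0.00           O",
  "END")

test_that("a minimal PDB parses into one descriptor per standard residue", {
  q <- parseStructure(writeMiniPdb(THREE_RES_PDB))
  res <- residues(q)
  expect_equal(nResidues(q), 3L)
  expect_equal(res$aa, c("ALA", "GLY", "LYS"))
  # glycine has no side chain: centroid collapses onto C-alpha
  gly <- res[res$aa == "GLY", ]
  expect_equal(unlist(gly[, c("sc_x", "sc_y", "sc_z")], use.names = FALSE),
               unlist(gly[, c("ca_x", "ca_y", "ca_z")], use.names = FALSE))
  # lysine side-chain centroid is the mean of its heavy side-chain atoms
  lys <- res[res$aa == "LYS", ]
  expect_equal(lys$sc_x, mean(c(8.0, 10.0)))
  expect_equal(lys$sc_y, mean(c(3.5, 4.0)))
  expect_equal(lys$sc_z, mean(c(1.0, 2.0)))
  # the water never becomes a residue
  expect_false(any(res$resno == 101L))
})

test_that("an empty chain selection is an explicit error", {
  path <- writeMiniPdb(THREE_RES_PDB)
  expect_error(parseStructure(path, chains = "B"),
               class = "cliquesite_empty_structure")
  expect_error(parseStructure(tempfile(fileext = ".pdb")),
               class = "cliquesite_parse_error")
})

test_that("altlocs resolve to the highest-occupancy conformer", {
  path <- writeMiniPdb(c(
    "ATOM      1  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB AALA A   1       2.000  -0.700   1.200  0.60  0.00           C",
    "ATOM      3  CB BALA A   1       9.000   9.000   9.000  0.40  0.00           C",
    "ATOM      4  CA  ALA A   2       5.000   0.000   0.000  1.00  0.00           C",
    "ATOM      5  CA  ALA A   3       9.000   0.000   0.000  1.00  0.00           C",
    "END"))
  res <- residues(parseStructure(path))
  # hand-computed: the single side-chain atom of the 0.6 conformer
  expect_equal(unlist(res[1, c("sc_x", "sc_y", "sc_z")], use.names = FALSE),
               c(2.000, -0.700, 1.200))
})

test_that("MSE maps to MET and other non-standard residues drop with a warning", {
  path <- writeMiniPdb(c(
    "HETATM    1  CA  MSE A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2 SE   MSE A   1       1.500   1.000   0.000  1.00  0.00          SE",
    "ATOM      3  CA  ALA A   2       5.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  UNK A   3       9.000   0.000   0.000  1.00  0.00           C",
    "ATOM      5  CA  GLY A   4      12.000   0.000   0.000  1.00  0.00           C",
    "END"))
  expect_warning(q <- parseStructure(path), "UNK")
  expect_equal(residues(q)$aa, c("MET", "ALA", "GLY"))
})

test_that("chain filtering never yields residues outside the filter", {
  fx <- generatePlantedStructure(5, noiseSigma = 0, nDecoyResidues = 10,
                                 splitAcrossChains = c(3, 2), seed = 11)
  for (ch in c("A", "B")) {
    q <- parseStructure(fx$path, chains = ch)
    expect_setequal(unique(residues(q)$chain), ch)
  }
})

test_that("PDB round trip reproduces descriptors to coordinate precision", {
  for (seed in 1:5) {
    fx <- generatePlantedStructure(5, noiseSigma = 0.3, nDecoyResidues = 15,
                                   seed = seed)
    reparsed <- parseStructure(fx$path)
    a <- residues(fx$query); b <- residues(reparsed)
    expect_equal(a[, c("chain", "resno", "ins", "aa")],
                 b[, c("chain", "resno", "ins", "aa")])
    expect_lt(max(abs(as.matrix(a[, 5:10]) - as.matrix(b[, 5:10]))), 1e-3)
  }
})

test_that("ligand contacts honour the distance cutoff", {
  path <- makeHoloFixture(tempfile(fileext = ".pdb"), nNear = 5, nFar = 5)
  got <- extractLigandContacts(path, "XLG", contactCutoff = 4.0)
  # residues 1..5 sit 3 A from the single ligand atom, 6..10 at 12 A
  expect_equal(got$residues$resno, 1:5)
  expect_equal(nrow(extractLigandContacts(path, "XLG", 0.0)$residues), 0L)
})

test_that("a missing ligand code lists the HET codes present", {
  path <- makeHoloFixture(tempfile(fileext = ".pdb"))
  err <- expect_error(extractLigandContacts(path, "ZZZ", 4.0),
                      class = "cliquesite_ligand_not_found")
  expect_match(conditionMessage(err), "XLG")
})

test_that("an instance selector restricts contacts to that ligand copy", {
  # two copies of the same ligand code in disjoint pockets
  res <- data.frame(chain = "A", resno = 1:6, ins = "",
                    aa = rep(c("ALA", "LEU", "SER"), 2),
                    ca_x = c(2, -2, 0, 52, 48, 50),
                    ca_y = c(0, 0, 2, 0, 0, 2),
                    ca_z = c(0, 0, -2, 0, 0, -2),
                    sc_x = c(2.5, -2.5, 0, 52.5, 47.5, 50),
                    sc_y = c(0, 0, 2.5, 0, 0, 2.5),
                    sc_z = c(0, 0, -2.5, 0, 0, -2.5),
                    stringsAsFactors = FALSE)
  het <- data.frame(code = "XLG", chain = "L", resno = c(1L, 2L),
                    elety = "P1", x = c(0, 50), y = 0, z = 0,
                    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".pdb")
  writePdbFixture(res, path, het = het)
  first <- extractLigandContacts(path, "XLG", 4.0)
  expect_equal(first$instance, "L:1")
  expect_equal(first$residues$resno, 1:3)
  second <- extractLigandContacts(path, "XLG", 4.0, instance = "L:2")
  expect_equal(second$residues$resno, 4:6)
})
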