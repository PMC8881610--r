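test_that("a toy PDB echoes its atoms and coordinates on read", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "END"), tf)
  m <- readStructure(tf)
  expect_s4_class(m, "StructureModel")
  expect_equal(length(m), 2L)
  expect_equal(atoms(m)$elety, c("N", "CA"))
  expect_equal(coords(m)[1, ], c(11.104, 6.134, -6.504),
               ignore_attr = TRUE)
})

test_that("write/read round-trip preserves atom count exactly and coordinates
           within PDB fixed-width precision", {
  m <- buildIdealHelix("YAEGTFTSDYSKYLDE", aibPositions = 2)
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(m, tf)
  m2 <- readStructure(tf)
  expect_equal(length(m2), length(m))
  expect_lt(max(abs(coords(m2) - coords(m))), 1e-3)
  expect_true(any(atoms(m2)$resid == "AIB"))  # nonstandard residue retained
})

test_that("a minimal mmCIF file reads to the same model as its PDB twin", {
  tf <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_TOY", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 11.104 6.134 -6.504 1.00 0.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 11.639 6.071 -5.147 1.00 0.00 ? 1 ALA A CA 1",
    "#"), tf)
  m <- readStructure(tf)
  expect_equal(length(m), 2L)
  expect_equal(atoms(m)$elety, c("N", "CA"))
  expect_equal(atoms(m)$chain, c("A", "A"))
  expect_equal(coords(m)[2, ], c(11.639, 6.071, -5.147), ignore_attr = TRUE)
})

test_that("unparseable and empty files raise informative errors", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines("this is not a coordinate file", tf)
  expect_error(readStructure(tf), "parse|empty", ignore.case = TRUE)
  expect_error(readStructure(file.path(tempdir(), "nope.pdb")), "not found")
})

test_that("altloc resolution keeps the highest-occupancy conformer,
           ties broken by first altloc id", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BSER A   2       4.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA ASER A   2       3.000   0.000   0.000  0.50  0.00           C",
    "END"), tf)
  m <- readStructure(tf)
  expect_equal(length(m), 2L)
  expect_equal(atoms(m)$x, c(2, 3))  # occupancy winner, then altloc A on tie
})

test_that("waters and ions are excluded by default, retained on request", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  O   HOH A 101       5.000   0.000   0.000  1.00  0.00           O",
    "END"), tf)
  expect_equal(length(readStructure(tf)), 1L)
  expect_equal(length(readStructure(tf, keepWaters = TRUE)), 2L)
})

test_that("chain selection returns only that chain and errors on unknown
           chains", {
  h <- buildIdealHelix("GGGGAAAA")
  two <- structureModel(rbind(atoms(h), atoms(frameScaffold())))
  selP <- selectAtoms(two, "chain P")
  expect_setequal(unique(atoms(selP)$chain), "P")
  expect_equal(length(selP), length(h))
  expect_error(selectAtoms(two, "chain Q"), "unknown chain 'Q'")
})

test_that("selection supports residue ranges, atom names and is idempotent;
           empty selections are allowed", {
  h <- buildIdealHelix("GGGGAAAAGGGG")
  s1 <- selectAtoms(h, "resno 3-6 and name CA")
  expect_equal(atoms(s1)$resno, 3:6)
  expect_identical(atoms(selectAtoms(s1, "resno 3-6 and name CA")), atoms(s1))
  expect_equal(length(selectAtoms(h, "resno 100-200")), 0L)
})

test_that("region selection goes through the numbering map and echoes
           exactly the mapped residues", {
  h <- buildIdealHelix("GGGGAAAAGGGG", chain = "R")
  map <- numberingMap(chain = "R", auth_seq = 4:8,
                      generic_label = "", region = "ECL1")
  hm <- applyNumbering(h, map)
  sel <- selectAtoms(hm, "region ECL1")
  expect_setequal(unique(atoms(sel)$resno), 4:8)
  expect_error(selectAtoms(hm, "region ECL9"), "unknown region")
})

test_that("applyNumbering attaches labels without touching coordinates or
           atom counts; lookups by generic label work", {
  h <- buildIdealHelix("GGGGAAAAGGGG", chain = "R")
  map <- numberingMap(chain = "R", auth_seq = 5, res_name = "ALA",
                      generic_label = "6.35b", region = "TM6")
  hm <- applyNumbering(h, map)
  expect_equal(coords(hm), coords(h))
  expect_equal(length(hm), length(h))
  hit <- selectAtoms(hm, "label 6.35b")
  expect_setequal(unique(atoms(hit)$resno), 5)
})

test_that("an empty numbering map leaves the model unchanged and absent
           residues only warn", {
  h <- buildIdealHelix("GGGGAAAA", chain = "R")
  expect_identical(atoms(applyNumbering(h, numberingMap(
    chain = character(), auth_seq = integer()))), atoms(h))
  expect_warning(applyNumbering(h, numberingMap(chain = "R", auth_seq = 99)),
                 "absent")
})

test_that("numbering maps survive a TSV round trip including empty fields", {
  map <- numberingMap(chain = "R", auth_seq = c(344, 202),
                      res_name = c("LYS", "GLY"),
                      generic_label = c("6.35b", ""),
                      region = c("TM6", "ECL1"))
  tf <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(map@entries, tf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  m2 <- readNumberingMap(tf)
  expect_equal(m2@entries$generic_label, c("6.35b", ""))
  expect_equal(m2@entries$region, c("TM6", "ECL1"))
})

test_that("the numbering map validity rejects duplicate generic labels and
           helix/region mismatches", {
  expect_error(numberingMap(chain = "R", auth_seq = 1:2,
                            generic_label = c("6.35b", "6.35b"),
                            region = c("TM6", "TM6")), "unique")
  expect_error(numberingMap(chain = "R", auth_seq = 1,
                            generic_label = "6.35b", region = "TM2"),
               "inconsistent")
})

test_that("modeledResidueCount counts residues with at least one atom and
           errors on unknown chains", {
  h <- buildIdealHelix("GGGGAAAAGGGG")
  expect_equal(modeledResidueCount(h, "P"), 12L)
  expect_error(modeledResidueCount(h, "Z"), "unknown chain")
  # dropping every atom of a chain makes it unknown
  sub <- selectAtoms(h, "resno 1-4")
  expect_equal(modeledResidueCount(sub, "P"), 4L)
})
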