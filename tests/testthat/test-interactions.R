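test_that("the chemistry rule table echoes known residue groups", {
  h <- buildIdealHelix("GGRGGGGGGG")
  chem <- assignChemistry(h)
  # arginine: cationic group over the guanidinium, donors include NH1/NH2/NE
  expect_length(chem@cations, 1L)
  expect_setequal(chem@cations[[1]]$atoms, c("NH1", "NH2", "NE", "CZ"))
  argDonors <- chem@donors$atom[chem@donors$resid == "ARG"]
  expect_true(all(c("NH1", "NH2", "NE") %in% argDonors))
})

test_that("phenylalanine contributes one six-atom aromatic ring with a unit
           normal", {
  h <- buildIdealHelix("GGFGGGGGGG")
  chem <- assignChemistry(h)
  expect_length(chem@rings, 1L)
  expect_length(chem@rings[[1]]$atoms, 6L)
  expect_equal(sum(chem@rings[[1]]$normal^2), 1, tolerance = 1e-9)
})

test_that("Aib gets backbone donor/acceptor chemistry plus two hydrophobic
           methyl carbons", {
  h <- buildIdealHelix("GAGGGGGG", aibPositions = 2)
  chem <- assignChemistry(h)
  aibDon <- chem@donors[chem@donors$resid == "AIB", ]
  aibAcc <- chem@acceptors[chem@acceptors$resid == "AIB", ]
  aibApolar <- chem@apolar[chem@apolar$resid == "AIB", ]
  expect_equal(aibDon$atom, "N")
  expect_equal(aibAcc$atom, "O")
  expect_setequal(aibApolar$atom, c("CB1", "CB2"))
})

test_that("unknown residues fall back to element chemistry: C/S hydrophobic,
           N/O donor-and-acceptor", {
  lip <- structureModel(data.frame(
    chain = "P", resno = 1,
    resid = "LNK", elety = c("C1", "C2", "O1", "N1"),
    element = c("C", "C", "O", "N"),
    x = c(0, 1.5, 3.0, 4.5), y = 0, z = 0, het = TRUE))
  expect_message(chem <- assignChemistry(lip), "nonstandard")
  expect_setequal(chem@apolar$atom, c("C1", "C2"))
  expect_setequal(chem@donors$atom, c("O1", "N1"))
  expect_setequal(chem@acceptors$atom, c("O1", "N1"))
})

test_that("an ideal planted hydrogen bond is detected exactly once and a
           5 A analogue is silent", {
  h <- sparsePlantHelix()
  hit <- plantContact(h, "hbond", 3, list(distance = 2.9, angle = 165))
  ct <- detectContacts(hit$model, "chain P", "chain R")
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$type, "hbond")
  expect_equal(ct$distance, 2.9, tolerance = 1e-9)
  silent <- plantContact(h, "hbond", 3, list(distance = 5.0, angle = 165))
  expect_equal(nrow(silent$manifest), 0L)
  expect_equal(nrow(detectContacts(silent$model, "chain P", "chain R")), 0L)
})

test_that("every planted interaction type is recovered with its planted type
           and nothing else (manifest completeness)", {
  h <- sparsePlantHelix()
  pl <- plantContact(h, "hbond", 3, list(distance = 2.9, angle = 165))
  pl <- plantContact(pl$model, "salt_bridge", 10, list(distance = 3.5))
  pl <- plantContact(pl$model, "hydrophobic", 17, list(distance = 4.0))
  pl <- plantContact(pl$model, "pi_pi", 24,
                     list(distance = 5.0, normalAngle = 0))
  pl <- plantContact(pl$model, "cation_pi", 28, list(distance = 4.5))
  ct <- detectContacts(pl$model, "chain P", "chain R")
  got <- ct[ct$dominant, c("type", "pep_resno", "rec_resno")]
  got <- got[order(got$pep_resno), ]
  rownames(got) <- NULL
  want <- pl$manifest[order(pl$manifest$peptide_resno),
                      c("type", "peptide_resno", "receptor_resno")]
  names(want) <- names(got)
  rownames(want) <- NULL
  expect_identical(got, want)
  expect_equal(nrow(ct), nrow(pl$manifest))  # no extra multi-type rows
})

test_that("T-shaped ring geometry is detected as pi-pi and intermediate
           normal angles are not", {
  h <- sparsePlantHelix()
  tsh <- plantContact(h, "pi_pi", 24, list(distance = 5.0, normalAngle = 75))
  ct <- detectContacts(tsh$model, "chain P", "chain R")
  expect_true("pi_pi" %in% ct$type)
  expect_match(ct$geometry[ct$type == "pi_pi"], "T-shaped")
  # 45 degrees sits between the parallel and T-shaped windows: silent
  mid <- plantContact(h, "pi_pi", 24, list(distance = 5.0, normalAngle = 45))
  expect_equal(nrow(mid$manifest), 0L)
  ctMid <- detectContacts(mid$model, "chain P", "chain R")
  expect_false("pi_pi" %in% ctMid$type)
})

test_that("a salt bridge whose partners also satisfy hydrogen-bond geometry
           is reported as salt bridge only (precedence)", {
  h <- sparsePlantHelix()
  pl <- plantContact(h, "salt_bridge", 10, list(distance = 3.3))
  ct <- detectContacts(pl$model, "chain P", "chain R")
  pairRows <- ct[ct$pep_resno == 10, ]
  expect_true("salt_bridge" %in% pairRows$type)
  expect_false("hbond" %in% pairRows$type)
  expect_equal(pairRows$type[pairRows$dominant], "salt_bridge")
})

test_that("detection is invariant under a global rigid motion of the
           complex", {
  h <- sparsePlantHelix()
  pl <- plantContact(h, "hbond", 3, list(distance = 3.0, angle = 150))
  pl <- plantContact(pl$model, "cation_pi", 28, list(distance = 4.5))
  ct0 <- detectContacts(pl$model, "chain P", "chain R")
  moved <- perturbRigid(pl$model, angle = 123, axis = c(3, -1, 2),
                        translation = c(8, -6, 4))
  ct1 <- detectContacts(moved, "chain P", "chain R")
  expect_equal(ct1$type, ct0$type)
  expect_equal(ct1$distance, ct0$distance, tolerance = 1e-9)
})

test_that("contact counts are monotone non-increasing as cutoffs tighten", {
  h <- sparsePlantHelix()
  pl <- plantContact(h, "hbond", 3, list(distance = 3.1, angle = 165))
  pl <- plantContact(pl$model, "salt_bridge", 10, list(distance = 3.6))
  pl <- plantContact(pl$model, "hydrophobic", 17, list(distance = 4.1))
  scales <- c(1, 0.9, 0.8, 0.7)
  counts <- vapply(scales, function(f) {
    crit <- contactCriteria(hbondDistMax = 3.5 * f, saltDistMax = 4.0 * f,
                            hydrophobicDistMax = 4.5 * f, piDistMax = 5.5 * f,
                            cationPiDistMax = 6.0 * f)
    nrow(detectContacts(pl$model, "chain P", "chain R", crit))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("fingerprints keep empty positions, order deterministically, and
           byte-identical inputs give byte-identical output", {
  h <- sparsePlantHelix()
  pl <- plantContact(h, "hbond", 3, list(distance = 2.9, angle = 165))
  pl <- plantContact(pl$model, "salt_bridge", 10, list(distance = 3.5))
  ct <- detectContacts(pl$model, "chain P", "chain R")
  fp <- buildFingerprint(ct, 30, complexId = "toy")
  expect_length(fp, 30L)
  expect_equal(nrow(fp@positions[[1]]), 0L)   # empty position retained
  expect_equal(nrow(fp@positions[[3]]), 1L)
  fp2 <- buildFingerprint(detectContacts(pl$model, "chain P", "chain R"),
                          30, complexId = "toy")
  expect_identical(serialize(fp, NULL), serialize(fp2, NULL))
  # no contacts at all: every entry present and empty
  fp0 <- buildFingerprint(ct[0, ], 30)
  expect_length(fp0, 30L)
  expect_true(all(vapply(fp0@positions, nrow, 0L) == 0L))
})

test_that("fingerprint positions use attached peptide labels and reject
           out-of-range positions", {
  h <- sparsePlantHelix()
  pl <- plantContact(h, "hbond", 3, list(distance = 2.9, angle = 165))
  m <- applyNumbering(pl$model, numberingMap(
    chain = "P", auth_seq = 1:30, generic_label = paste0(1:30, "P")))
  ct <- detectContacts(m, "chain P", "chain R")
  expect_equal(ct$pep_label, "3P")
  expect_error(buildFingerprint(ct, 2), "outside 1..2")
})

test_that("a fingerprint diffed against itself is fully conserved and a
           planted removal shows up as exactly that lost contact", {
  h <- sparsePlantHelix()
  pl1 <- plantContact(h, "hbond", 3, list(distance = 2.9, angle = 165))
  pl2 <- plantContact(pl1$model, "salt_bridge", 10, list(distance = 3.5))
  ctA <- detectContacts(pl2$model, "chain P", "chain R")
  ctB <- detectContacts(pl1$model, "chain P", "chain R")
  fpA <- buildFingerprint(ctA, 30, "A")
  fpB <- buildFingerprint(ctB, 30, "B")
  self <- summary(diffFingerprints(fpA, fpA))
  expect_equal(unname(self), c(0L, 0L, nrow(as.data.frame(fpA))))
  d <- diffFingerprints(fpA, fpB)
  dd <- as.data.frame(d)
  lost <- dd[dd$status == "lost", ]
  expect_equal(nrow(lost), 1L)
  expect_equal(lost$position, 10)
  expect_equal(lost$type, "salt_bridge")
  expect_equal(summary(d)[["gained"]], 0L)
})

test_that("fingerprints of different register need a position map", {
  fpA <- buildFingerprint(data.frame(), 10, "A")
  fpB <- buildFingerprint(data.frame(), 12, "B")
  expect_error(diffFingerprints(fpA, fpB), "position map")
  pm <- stats::setNames(1:10, 1:10)
  expect_s4_class(diffFingerprints(fpA, fpB, positionMap = pm),
                  "FingerprintDiff")
})
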