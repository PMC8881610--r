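test_that("identical point clouds give the identity transform and zero RMSD", {
  set.seed(1)
  A <- matrix(rnorm(30), ncol = 3)
  fit <- kabschFit(A, A)
  expect_equal(fit@transform@rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit@transform@translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(fit@rmsd, 0, tolerance = 1e-9)
})

test_that("a 90-degree rotation about z is recovered exactly", {
  set.seed(2)
  A <- matrix(rnorm(30), ncol = 3)
  R90 <- rotationMatrix(90, c(0, 0, 1))
  B <- A %*% t(R90)
  fit <- kabschFit(A, B)
  expect_equal(fit@rmsd, 0, tolerance = 1e-9)
  # recovered rotation undoes the applied one
  expect_equal(fit@transform@rotation %*% R90, diag(3), tolerance = 1e-9)
})

test_that("the fit refuses degenerate input", {
  expect_error(kabschFit(matrix(rnorm(6), ncol = 3),
                         matrix(rnorm(6), ncol = 3)), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabschFit(line, line), "collinear")
})

test_that("Kabsch RMSD matches the brute-force rotation-search oracle and
           never exceeds any sampled rotation", {
  set.seed(3)
  for (i in 1:5) {
    A <- matrix(rnorm(30), ncol = 3)
    B <- matrix(rnorm(30), ncol = 3)
    k <- kabschFit(A, B)@rmsd
    o <- oracleRmsd(A, B)
    expect_lt(abs(k - o$value), 1e-6)
    expect_lte(k, o$value + 1e-9)  # minimality against the search
  }
})

test_that("C-alpha RMSD is zero against itself and a rigidly moved copy,
           and is symmetric", {
  h <- buildIdealHelix("YAEGTFTSDYSKYLDEQAAK")
  moved <- perturbRigid(h, angle = 25, axis = c(1, 2, 0),
                        translation = c(5, -3, 2))
  expect_equal(caRmsd(h, h)@rmsd, 0, tolerance = 1e-9)
  expect_equal(caRmsd(h, moved)@rmsd, 0, tolerance = 1e-9)
  noisy <- perturbRigid(h, angle = 10, axis = c(0, 1, 0), noiseSd = 0.4,
                        seed = 5)
  expect_equal(caRmsd(h, noisy)@rmsd, caRmsd(noisy, h)@rmsd,
               tolerance = 1e-9)
})

test_that("C-alpha pairing intersects author numbering and records the
           pairing for audit", {
  h <- buildIdealHelix("YAEGTFTSDYSK")
  partial <- selectAtoms(h, "resno 3-12")
  fit <- caRmsd(h, partial)
  expect_equal(fit@nPairs, 10L)
  expect_equal(nrow(fit@pairing), 10L)
})

test_that("region-filtered RMSD uses only the mapped region", {
  h <- buildIdealHelix("YAEGTFTSDYSKYLDEQAAK", chain = "R")
  map <- numberingMap(chain = "R", auth_seq = 1:10, generic_label = "",
                      region = "TM1")
  a <- applyNumbering(h, map)
  # distort residues outside TM1 only: region-filtered fit stays exact
  at <- atoms(h)
  at$x[at$resno > 10] <- at$x[at$resno > 10] + 3
  b <- applyNumbering(structureModel(at), map)
  expect_gt(caRmsd(a, b)@rmsd, 0.5)
  expect_equal(caRmsd(a, b, region = "TM1")@rmsd, 0, tolerance = 1e-9)
})

test_that("displacement is exactly zero for a model against itself", {
  h <- buildIdealHelix("GGGGAAAAGGGG")
  m <- structureModel(rbind(atoms(h), atoms(frameScaffold())))
  expect_equal(as.numeric(displacement(m, m, "chain R and name CA",
                                       "P:6:CA")), 0)
})

test_that("a loop moved 5 A while the frame stays fixed reads out as a
           5.000 A probe displacement", {
  h <- buildIdealHelix("GGGGAAAAGGGG")
  mA <- structureModel(rbind(atoms(h), atoms(frameScaffold())))
  mB <- moveChain(mA, "P", translation = c(0, 0, 5))
  d <- displacement(mA, mB, "chain R and name CA", "P:6:CA")
  expect_equal(as.numeric(d), 5, tolerance = 1e-9)
})

test_that("a missing probe names the offending residue", {
  h <- buildIdealHelix("GGGGAAAAGGGG")
  m <- structureModel(rbind(atoms(h), atoms(frameScaffold())))
  expect_error(displacement(m, m, "chain R and name CA", "P:99:CA"),
               "P:99:CA")
})

test_that("cross-atom distance recovers a planted offset between equivalent
           residues", {
  h <- buildIdealHelix("GGGGAAAAGGGG")
  mA <- structureModel(rbind(atoms(h), atoms(frameScaffold())))
  # same probe on identical models is zero
  expect_equal(as.numeric(crossAtomDistance(mA, mA, "chain R and name CA",
                                            "P:6:CA", "P:6:CA")), 0)
  # plant a 3.2 A offset at residue 6 of model B, frame untouched
  at <- atoms(mA)
  sel <- at$chain == "P" & at$resno == 6
  at$z[sel] <- at$z[sel] + 3.2
  mB <- structureModel(at)
  d <- crossAtomDistance(mA, mB, "chain R and name CA", "P:6:CA", "P:6:CA")
  expect_equal(as.numeric(d), 3.2, tolerance = 1e-9)
})

test_that("helix-axis rotation: identical models give 0 and a planted
           10-degree rotation is recovered within 0.1 degree", {
  h <- buildIdealHelix("GGGGAAAAGGGGAAAA")
  mA <- structureModel(rbind(atoms(h), atoms(frameScaffold())))
  expect_equal(as.numeric(axisRotationAngle(mA, mA, "chain R and name CA",
                                            "chain P and name CA")), 0)
  mB <- moveChain(mA, "P", angleDeg = 10, axis = c(1, 0, 0))
  ang <- axisRotationAngle(mA, mB, "chain R and name CA",
                           "chain P and name CA")
  expect_equal(as.numeric(ang), 10, tolerance = 0.1)
  expect_error(axisRotationAngle(mA, mB, "chain R and name CA",
                                 "chain P and resno 1-3"), ">= 6")
})

test_that("all superposition outputs are invariant under a common rigid
           motion of both inputs", {
  h <- buildIdealHelix("GGGGAAAAGGGGAAAA")
  mA <- structureModel(rbind(atoms(h), atoms(frameScaffold())))
  mB <- moveChain(mA, "P", angleDeg = 7, axis = c(0, 1, 0),
                  translation = c(1, 0, 2))
  d0 <- as.numeric(displacement(mA, mB, "chain R and name CA", "P:6:CA"))
  a0 <- as.numeric(axisRotationAngle(mA, mB, "chain R and name CA",
                                     "chain P and name CA"))
  r0 <- caRmsd(mA, mB)@rmsd
  for (seed in 1:3) {
    set.seed(seed)
    ax <- rnorm(3); tr <- rnorm(3, sd = 10); ang <- runif(1, 0, 180)
    gA <- perturbRigid(mA, ang, ax, tr)
    gB <- perturbRigid(mB, ang, ax, tr)
    expect_equal(as.numeric(displacement(gA, gB, "chain R and name CA",
                                         "P:6:CA")), d0, tolerance = 1e-6)
    expect_equal(as.numeric(axisRotationAngle(gA, gB, "chain R and name CA",
                                              "chain P and name CA")), a0,
                 tolerance = 1e-6)
    expect_equal(caRmsd(gA, gB)@rmsd, r0, tolerance = 1e-6)
  }
})

test_that("the Kabsch solution agrees with an established reference
           implementation on noisy pairs", {
  h <- buildIdealHelix("YAEGTFTSDYSKYLDEQAAK")
  noisy <- perturbRigid(h, angle = 40, axis = c(1, 1, 1),
                        translation = c(3, 2, 1), noiseSd = 0.5, seed = 9)
  ours <- kabschFit(coords(h), coords(noisy))@rmsd
  ref <- bio3d::rmsd(as.numeric(t(coords(h))), as.numeric(t(coords(noisy))),
                     fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)
})
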