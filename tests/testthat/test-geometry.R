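test_that("dihedral matches the independent projection oracle", {
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)), 180)
  set.seed(21)
  for (rep_ in 1:25) {
    pts <- lapply(1:4, function(i) rnorm(3, 0, 3))
    expect_equal(do.call(dihedral, pts),
                 dihedralOracle(pts[[1]], pts[[2]], pts[[3]], pts[[4]]),
                 tolerance = 1e-9)
  }
  # the stated branch of the +/-90 degree case
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)),
               dihedralOracle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                              c(1, 1, 1)))
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("dihedral is isometry-invariant and flips sign under reflection", {
  set.seed(22)
  pts <- list(c(0, 0, 0), c(1.5, 0, 0), c(2, 1.2, 0), c(3, 1.2, 1.1))
  base <- do.call(dihedral, pts)
  for (rep_ in 1:5) {
    mv <- randomRigidMotion()
    moved <- lapply(pts, function(p) as.numeric(mv$rotation %*% p) +
                      mv$translation)
    expect_equal(do.call(dihedral, moved), base, tolerance = 1e-9)
  }
  mirrored <- lapply(pts, function(p) p * c(1, 1, -1))
  expect_equal(do.call(dihedral, mirrored), -base, tolerance = 1e-9)
})

test_that("chi angles recover the construction values", {
  for (chi1 in c(-60, 75, 180)) {
    for (chi2 in c(-95, 30, 90)) {
      trp <- buildTrpResidue(chi1 = chi1, chi2 = chi2)
      chis <- chiAngles(trp)
      expect_equal(unname(chis["chi1"]), chi1, tolerance = 0.1 / 60)
      expect_equal(unname(chis["chi2"]), chi2, tolerance = 0.1 / 30)
    }
  }
  # rotating chi1 by +30 leaves chi2 unchanged
  a <- chiAngles(buildTrpResidue(chi1 = -60, chi2 = 90))
  b <- chiAngles(buildTrpResidue(chi1 = -30, chi2 = 90))
  expect_equal(unname(b["chi1"] - a["chi1"]), 30, tolerance = 1e-6)
  expect_equal(unname(b["chi2"]), unname(a["chi2"]), tolerance = 1e-6)
  noCG <- buildTrpResidue()
  noCG <- Structure(noCG[noCG$name != "CG", ])
  expect_error(chiAngles(noCG), "missing atom CG")
})

test_that("the protein axis tracks the dominant CA direction", {
  ca <- data.frame(serial = 1:10, name = "CA", altloc = "", resname = "ALA",
                   chain = "A", resno = 1:10, x = rnorm(10, 0, 0.1),
                   y = rnorm(10, 0, 0.1), z = seq(0, 13.5, length.out = 10),
                   element = "C", stringsAsFactors = FALSE)
  s <- Structure(ca)
  ax <- proteinAxis(s)
  expect_equal(abs(sum(ax * c(0, 0, 1))), 1, tolerance = 1e-3)
  expect_gt(sum(ax * c(0, 0, 1)), 0)  # sign follows residue numbering
  # equivariance: axis of the rotated structure is the rotated axis
  rot <- rotationMatrix(c(1, 2, 0.5), 55)
  s2 <- transformCoords(s, rotation = rot)
  ax2 <- proteinAxis(s2)
  expect_equal(abs(sum(ax2 * as.numeric(rot %*% ax))), 1, tolerance = 1e-6)
  # helix-like bundle built around a known axis
  set.seed(9)
  t_ <- seq(0, 6 * pi, length.out = 40)
  helix <- data.frame(serial = 1:40, name = "CA", altloc = "",
                      resname = "ALA", chain = "A", resno = 1:40,
                      x = 2.3 * cos(t_), y = 2.3 * sin(t_),
                      z = 1.5 * t_, element = "C",
                      stringsAsFactors = FALSE)
  axh <- proteinAxis(Structure(helix))
  angle <- acos(abs(sum(axh * c(0, 0, 1)))) * 180 / pi
  expect_lt(angle, 5)
  expect_error(proteinAxis(Structure(ca[1:2, ])), "at least 3")
})

test_that("flip classification thresholds the axis angle at 45 degrees", {
  trp <- buildTrpResidue(chi1 = -60, chi2 = 90)
  s <- Structure(trp)
  cb <- as.numeric(trp[trp$name == "CB", c("x", "y", "z")])
  ringAtoms <- c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3",
                 "CH2")
  centroid <- colMeans(as.matrix(trp[trp$name %in% ringAtoms,
                                     c("x", "y", "z")]))
  v <- centroid - cb
  v <- v / sqrt(sum(v^2))
  expect_identical(flipState(classifyFlip(s, 34, axis = v)), "flip-out")
  expect_equal(flipAngle(classifyFlip(s, 34, axis = v)), 0,
               tolerance = 1e-6)
  # rotate the reference axis away from the orientation vector
  perp <- vapply(list(c(1, 0, 0), c(0, 1, 0)), function(e) {
    w <- e - sum(e * v) * v; w / sqrt(sum(w^2))
  }, numeric(3))[, 1]
  for (ang in c(30, 60, 90)) {
    axis <- cos(ang * pi / 180) * v + sin(ang * pi / 180) * perp
    fl <- classifyFlip(s, 34, axis = axis)
    expect_equal(flipAngle(fl), ang, tolerance = 1e-6)
    expect_identical(flipState(fl), if (ang <= 45) "flip-out" else "flip-in")
  }
  # stability: a 0.01 A coordinate perturbation moves the angle < 1 degree
  set.seed(4)
  fl0 <- classifyFlip(s, 34, axis = perp)
  jit <- trp
  jit[, c("x", "y", "z")] <- jit[, c("x", "y", "z")] +
    matrix(runif(3 * nrow(jit), -0.01, 0.01), ncol = 3)
  fl1 <- classifyFlip(Structure(jit), 34, axis = perp)
  expect_lt(abs(flipAngle(fl1) - flipAngle(fl0)), 1)
  incomplete <- Structure(trp[trp$name != "CZ2", ])
  expect_error(classifyFlip(incomplete, 34, axis = v), "CZ2")
})

test_that("structure triage removes exactly the orientation outliers", {
  res <- triageStructures(genStructureMetadata())
  expect_setequal(res$removed$pdb_id, c("1OR3", "1B68"))
  expect_identical(nrow(res$selected), 6L)
  counts <- table(paste(res$selected$isoform, res$selected$category))
  expect_identical(as.integer(counts[c("E3 apo", "E4 apo", "E4 holo")]),
                   c(2L, 2L, 2L))
  # all-consistent tables lose nothing; empty tables stay empty
  clean <- res$selected
  res2 <- triageStructures(clean)
  expect_identical(nrow(res2$removed), 0L)
  expect_identical(res2$selected$pdb_id, clean$pdb_id)
  res3 <- triageStructures(genStructureMetadata()[0, ])
  expect_identical(nrow(res3$selected), 0L)
})

test_that("Kabsch superposition is optimal, proper and exact on rigid copies", {
  set.seed(31)
  ref <- matrix(rnorm(15, 0, 3), 5, 3)
  ident <- kabschSuperpose(ref, ref)
  expect_equal(ident$rmsd, 0, tolerance = 1e-10)
  expect_equal(ident$rotation, diag(3), tolerance = 1e-9)
  for (rep_ in 1:10) {
    mv <- randomRigidMotion()
    mob <- ref %*% t(mv$rotation) + matrix(mv$translation, 5, 3,
                                           byrow = TRUE)
    fit <- kabschSuperpose(ref, mob)
    expect_equal(fit$rmsd, 0, tolerance = 1e-9)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    expect_lt(fit$rmsd, rmsdRaw(ref, mob) + 1e-12)
  }
  expect_error(kabschSuperpose(ref[1:2, ], ref[1:2, ] + 1), "at least 3")
})

test_that("Kabsch RMSD matches the independent bio3d fit", {
  set.seed(35)
  for (rep_ in 1:5) {
    ref <- matrix(rnorm(24, 0, 2), 8, 3)
    mob <- ref + matrix(rnorm(24, 0, 0.4), 8, 3)
    fit <- kabschSuperpose(ref, mob)
    oracle <- bio3d::fit.xyz(fixed = as.numeric(t(ref)),
                             mobile = as.numeric(t(mob)),
                             fixed.inds = 1:24, mobile.inds = 1:24)
    oracleRmsd <- sqrt(mean(rowSums(
      (matrix(oracle, ncol = 3, byrow = TRUE) - ref)^2)))
    expect_equal(fit$rmsd, oracleRmsd, tolerance = 1e-3)
  }
  # the displaced-vertex case against a rotation grid refined locally
  ref <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  mob <- ref; mob[4, ] <- mob[4, ] + c(1, 0, 0)
  fit <- kabschSuperpose(ref, mob)
  gridMin <- gridSearchRmsd(ref, mob)
  expect_equal(fit$rmsd, gridMin, tolerance = 1e-3)
})

test_that("RMSD series separates backbone fit from ligand motion", {
  set.seed(41)
  protein <- matrix(rnorm(60, 0, 4), 20, 3)
  ligand <- matrix(rnorm(24, 0, 1), 8, 3) +
    matrix(c(6, 0, 0), 8, 3, byrow = TRUE)
  frame0 <- rbind(protein, ligand)
  backboneSel <- 1:20
  ligandSel <- 21:28
  same <- rmsdSeries(list(frame0, frame0, frame0), ligandSel, backboneSel)
  expect_equal(same$backbone_rmsd_A, rep(0, 3), tolerance = 1e-10)
  expect_equal(same$ligand_rmsd_A, rep(0, 3), tolerance = 1e-10)
  # rigidly transformed copies: all-zero after superposition
  frames <- lapply(1:4, function(i) {
    mv <- randomRigidMotion()
    frame0 %*% t(mv$rotation) + matrix(mv$translation, 28, 3, byrow = TRUE)
  })
  rigid <- rmsdSeries(c(list(frame0), frames), ligandSel, backboneSel)
  expect_lt(max(rigid$backbone_rmsd_A), 1e-9)
  expect_lt(max(rigid$ligand_rmsd_A), 1e-9)
  # isotropic ligand jitter: mean ligand RMSD ~ sigma * sqrt(3)
  sigma <- 0.5
  jitFrames <- c(list(frame0), lapply(1:60, function(i) {
    fr <- frame0
    fr[ligandSel, ] <- fr[ligandSel, ] + matrix(rnorm(24, 0, sigma), 8, 3)
    fr
  }))
  jit <- rmsdSeries(jitFrames, ligandSel, backboneSel)
  expect_equal(mean(jit$ligand_rmsd_A[-1]), sigma * sqrt(3),
               tolerance = 0.1)
  badFrames <- list(frame0, frame0[1:27, ])
  expect_error(rmsdSeries(badFrames, ligandSel, backboneSel), "frame 2")
})

test_that("flip fraction summarises state series", {
  expect_equal(flipFraction(rep("flip-in", 10)), 1)
  expect_equal(flipFraction(rep(c("flip-in", "flip-out"), 50)), 0.5)
  expect_error(flipFraction(character()), "at least one")
  expect_error(flipFraction(c("flip-in", "sideways")), "sideways")
})
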