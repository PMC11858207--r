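test_that("H-bond detection respects the cutoff and reports distances", {
  pose <- fullInteractionPose()
  hb <- detectHBonds(pose)
  expect_identical(sort(hb$protein_residue), c("ASP153", "ASP35"))
  expect_equal(hb$distance_A[hb$protein_residue == "ASP35"], 2.9,
               tolerance = 0.01 / 2.9)
  # a pair at 10 A is never reported at the default cutoff
  far <- transformCoords(ligandAtoms(pose), translation = c(0, 0, 50))
  poseFar <- PoseComplex(protein(pose), far)
  expect_identical(nrow(detectHBonds(poseFar)), 0L)
  # residue filter narrows the search
  only35 <- detectHBonds(pose, residues = "ASP35")
  expect_identical(unique(only35$protein_residue), "ASP35")
})

test_that("detectors are invariant under rigid-body isometries", {
  pose <- buildPoseComplex(poseSpec(
    hbondRequests = list(c("ASP35", 2.9)), pistackRequest = c(3.7, 15),
    seed = 1))
  hb0 <- detectHBonds(pose)
  ps0 <- detectPiStacking(pose)
  set.seed(77)
  for (rep_ in 1:5) {
    mv <- randomRigidMotion()
    moved <- transformCoords(pose, mv$rotation, mv$translation)
    hb <- detectHBonds(moved)
    expect_equal(hb$distance_A, hb0$distance_A, tolerance = 1e-6)
    ps <- detectPiStacking(moved)
    expect_equal(ps$centroid_distance_A, ps0$centroid_distance_A,
                 tolerance = 1e-6)
    expect_equal(ps$interplanar_angle_deg, ps0$interplanar_angle_deg,
                 tolerance = 1e-4)
    occ0 <- pocketOccupancy(pose)$count
    expect_identical(pocketOccupancy(moved)$count, occ0)
  }
})

test_that("detector counts are monotone in their cutoffs", {
  pose <- fullInteractionPose()
  hbCounts <- vapply(seq(2.0, 6.0, by = 0.5),
                     function(d) nrow(detectHBonds(pose, dMax = d)),
                     integer(1))
  expect_true(all(diff(hbCounts) >= 0))
  occCounts <- vapply(seq(6.0, 2.0, by = -0.5), function(cf) {
    pocketOccupancy(pose, cutoff = cf)$count
  }, integer(1))
  expect_true(all(diff(occCounts) <= 0))
})

test_that("pi-stacking applies both distance and angle thresholds", {
  near <- buildPoseComplex(poseSpec(pistackRequest = c(3.7, 0)))
  ps <- detectPiStacking(near)
  expect_gt(nrow(ps), 0)
  expect_equal(min(ps$centroid_distance_A), 3.7, tolerance = 1e-6)
  expect_lt(max(ps$interplanar_angle_deg), 1e-4)
  farRings <- buildPoseComplex(poseSpec(pistackRequest = c(8, 0)))
  expect_identical(nrow(detectPiStacking(farRings, dMax = 5.5)), 0L)
  perp <- buildPoseComplex(poseSpec(pistackRequest = c(3.7, 90)))
  expect_identical(nrow(detectPiStacking(perp, angleMax = 30)), 0L)
  expect_gt(nrow(detectPiStacking(perp, angleMax = 90)), 0)
  expect_error(detectPiStacking(near, ligandRings = list(1:2)),
               "at least 3")
})

test_that("pocket occupancy counts apolar contacts and labels fragments", {
  pose <- buildPoseComplex(poseSpec(occupancyRequest = 3))
  occ <- pocketOccupancy(pose)
  expect_identical(occ$count, 3L)
  far <- PoseComplex(protein(pose),
                     transformCoords(ligandAtoms(pose),
                                     translation = c(0, 0, 100)))
  expect_identical(pocketOccupancy(far)$count, 0L)
  expect_error(pocketOccupancy(pose, pocketResidues = "HIS140"), "HIS140")
})

test_that("checklists conjoin flip state, H-bonds and pocket fill", {
  full <- fullInteractionPose()
  flip <- classifyFlip(protein(full), 34, axis = c(0, 0, 1))
  chk <- buildChecklist(full, flip)
  expect_true(chk$hbond_asp35 && chk$hbond_asp153)
  expect_true(chk$all_key_interactions)
  # dropping the Asp153 H-bond breaks the conjunction, the profile of the
  # weakest published stabilizers
  partial <- buildPoseComplex(poseSpec(
    hbondRequests = list(c("ASP35", 2.9)), occupancyRequest = 3))
  chk2 <- buildChecklist(partial,
                         classifyFlip(protein(partial), 34, c(0, 0, 1)))
  expect_false(chk2$hbond_asp153)
  expect_false(chk2$all_key_interactions)
})

test_that("the published checklist counts six of eight full profiles", {
  chk <- knownLigandChecklist()
  expect_identical(sum(chk$trp34_orientation == "flip-in"), 8L)
  expect_identical(sum(chk$all_key_interactions), 6L)
  lacking <- chk$ligand_id[!chk$all_key_interactions]
  expect_setequal(lacking, c("83673143", "155530661"))
})

test_that("persistence fractions are per-frame indicator means", {
  frames <- data.frame(
    trp34_orientation = rep(c("flip-in", "flip-out"), c(75, 25)),
    hbond_asp35 = rep(c(TRUE, FALSE), c(60, 40)),
    hbond_asp153 = TRUE,
    pocket_contacts = rep(c(3L, 0L), 50))
  pp <- persistenceProfile(frames)
  expect_equal(unname(pp$fractions["trp34_flip_in"]), 0.75)
  expect_equal(unname(pp$fractions["hbond_asp35"]), 0.6)
  expect_equal(unname(pp$fractions["hbond_asp153"]), 1)
  expect_equal(unname(pp$fractions["pocket_filled"]), 0.5)
  expect_identical(pp$n_frames, 100L)
  # concatenating a trajectory with itself leaves fractions unchanged
  pp2 <- persistenceProfile(rbind(frames, frames))
  expect_equal(pp2$fractions, pp$fractions)
  expect_error(persistenceProfile(frames[0, ]), "at least one frame")
})
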