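# Toy pocket-ligand complex generator with prescribed interaction geometry.

#' Specification for a synthetic pocket-ligand pose
#'
#' @param hbondRequests list of `c(residue, distance)` pairs (or a 2-column
#'   data.frame), each asking for one ligand oxygen placed at the given
#'   heavy-atom distance (Angstrom) from the named residue's carboxylate
#'   OD1; residues available in the toy pocket are `"ASP35"` and
#'   `"ASP153"`
#' @param pistackRequest optional `c(distance, angle)`: a six-membered
#'   carbon ring with its centroid at `distance` Angstrom from the indole
#'   six-ring centroid along the ring normal, tilted by `angle` degrees
#' @param occupancyRequest optional count of ligand carbons to place in
#'   contact (about 4.0 Angstrom) with the Trp sidechain
#' @param seed integer seed (the construction is deterministic; the seed
#'   is part of the spec for interface uniformity)
#' @return validated list of class `"PoseSpec"`
#' @export
poseSpec <- function(hbondRequests = list(), pistackRequest = NULL,
                     occupancyRequest = NULL, seed = 1L) {
  if (is.data.frame(hbondRequests)) {
    hbondRequests <- lapply(seq_len(nrow(hbondRequests)), function(i) {
      list(residue = as.character(hbondRequests[i, 1L]),
           distance = as.numeric(hbondRequests[i, 2L]))
    })
  } else {
    hbondRequests <- lapply(hbondRequests, function(r) {
      if (is.list(r)) {
        list(residue = as.character(r$residue), distance = as.numeric(r$distance))
      } else {
        list(residue = as.character(r[[1L]]), distance = as.numeric(r[[2L]]))
      }
    })
  }
  for (r in hbondRequests) {
    if (!r$residue %in% c("ASP35", "ASP153")) {
      stop(sprintf("unknown H-bond residue '%s' (toy pocket has ASP35, ASP153)",
                   r$residue), call. = FALSE)
    }
    stopIfNotScalarNumber(r$distance, "hbond distance", 0, Inf, strict = TRUE)
  }
  if (length(hbondRequests) > 1L) {
    res <- vapply(hbondRequests, `[[`, character(1L), "residue")
    if (anyDuplicated(res)) {
      stop("at most one H-bond request per residue", call. = FALSE)
    }
  }
  if (!is.null(pistackRequest)) {
    stopIfNotScalarNumber(pistackRequest[[1L]], "pistack distance", 0, Inf,
                          strict = TRUE)
    stopIfNotScalarNumber(pistackRequest[[2L]], "pistack angle", 0, 90)
  }
  if (!is.null(occupancyRequest)) {
    stopIfNotScalarNumber(occupancyRequest, "occupancyRequest", 0, 6)
    occupancyRequest <- as.integer(occupancyRequest)
  }
  structure(list(hbondRequests = hbondRequests,
                 pistackRequest = pistackRequest,
                 occupancyRequest = occupancyRequest,
                 seed = as.integer(seed)),
            class = "PoseSpec")
}

hexagonRing <- function(center, normal, side = 1.39, tiltDeg = 0) {
  normal <- vunit(normal)
  ref <- if (abs(normal[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- vunit(vcross(normal, ref))
  e2 <- vcross(normal, e1)
  pts <- t(vapply(0:5, function(k) {
    a <- k * pi / 3
    center + side * (cos(a) * e1 + sin(a) * e2)
  }, numeric(3L)))
  if (tiltDeg != 0) {
    rot <- rotationAboutAxis(e1, tiltDeg)
    pts <- sweep(pts, 2L, center)
    pts <- pts %*% t(rot)
    pts <- sweep(pts, 2L, center, "+")
  }
  pts
}

rotationAboutAxis <- function(axis, angleDeg) {
  axis <- vunit(axis)
  a <- deg2rad(angleDeg)
  k <- matrix(c(0, axis[3L], -axis[2L],
                -axis[3L], 0, axis[1L],
                axis[2L], -axis[1L], 0), 3L, 3L)
  diag(3L) + sin(a) * k + (1 - cos(a)) * k %*% k
}

#' Build a toy pocket-ligand complex realizing requested interactions
#'
#' Assembles an idealized protein fragment (a tryptophan with full indole
#' at residue 34 and two aspartates at residues 35 and 153) and places
#' ligand atoms so that every requested interaction holds within 0.05
#' Angstrom / 2 degrees: one ligand oxygen per H-bond request on the
#' extension of the target carboxylate CG-OD1 axis, an optional stacking
#' ring over the indole six-ring, and optional pocket-contact carbons
#' placed 4.0 Angstrom off the indole ring atoms.  The construction is
#' verified against
#' the package's own detectors ([detectHBonds()], [detectPiStacking()],
#' [pocketOccupancy()]) before the pose is returned; an unrealizable
#' request errors.  The complex is oriented so the Trp34 sidechain is
#' flip-in relative to the z axis.
#'
#' @param spec a [poseSpec()]
#' @param ligandId identifier for the ligand pose
#' @return a [PoseComplex]
#' @export
buildPoseComplex <- function(spec, ligandId = "LIG1") {
  stopifnot(inherits(spec, "PoseSpec"))
  trp <- buildTrpResidue(chi1 = -60, chi2 = 90, resno = 34,
                         serialStart = 1L)
  asp35 <- buildAspResidue(resno = 35, serialStart = 101L)
  asp153 <- buildAspResidue(resno = 153, serialStart = 201L)
  # park the aspartates on opposite flanks, carboxylate tip at a fixed
  # anchor so H-bond oxygens extend away from everything else
  anchor <- list(ASP35 = c(8.5, 3, 0), ASP153 = c(-8.5, 3, 0))
  tip35 <- as.numeric(asp35[asp35$name == "OD1", c("x", "y", "z")])
  asp35 <- translateAtoms(asp35, anchor$ASP35 - tip35)
  tip153 <- as.numeric(asp153[asp153$name == "OD1", c("x", "y", "z")])
  asp153 <- rotateAtoms(asp153, rotationAboutAxis(c(0, 0, 1), 180))
  tip153 <- as.numeric(asp153[asp153$name == "OD1", c("x", "y", "z")])
  asp153 <- translateAtoms(asp153, anchor$ASP153 - tip153)
  protAtoms <- rbind(trp, asp35, asp153)

  ligNames <- character()
  ligCoords <- matrix(numeric(), 0L, 3L)
  ligElems <- character()
  addAtoms <- function(names, coords, elems) {
    ligNames <<- c(ligNames, names)
    ligCoords <<- rbind(ligCoords, coords)
    ligElems <<- c(ligElems, elems)
  }

  for (i in seq_along(spec$hbondRequests)) {
    r <- spec$hbondRequests[[i]]
    res <- protAtoms[residueLabel(protAtoms) == r$residue, , drop = FALSE]
    od1 <- as.numeric(res[res$name == "OD1", c("x", "y", "z")])
    cg <- as.numeric(res[res$name == "CG", c("x", "y", "z")])
    pos <- od1 + r$distance * vunit(od1 - cg)
    addAtoms(sprintf("O%d", i), matrix(pos, 1L), "O")
  }

  ringAtoms6 <- c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")
  hexXyz <- as.matrix(trp[trp$name %in% ringAtoms6, c("x", "y", "z")])
  hexFit <- planeFit(hexXyz)
  if (!is.null(spec$pistackRequest)) {
    d <- spec$pistackRequest[[1L]]
    ang <- spec$pistackRequest[[2L]]
    # stack on the ring face pointing away from the backbone
    ca <- as.numeric(trp[trp$name == "CA", c("x", "y", "z")])
    nrm <- vunit(hexFit$normal)
    if (sum(nrm * (hexFit$centroid - ca)) < 0) nrm <- -nrm
    center <- hexFit$centroid + d * nrm
    pts <- hexagonRing(center, nrm, tiltDeg = ang)
    addAtoms(sprintf("C%d", 10:15), pts, rep("C", 6L))
  }
  if (!is.null(spec$occupancyRequest) && spec$occupancyRequest > 0L) {
    # one carbon 4.0 A radially out from each of up to six hexagon atoms
    anchors <- c("CZ3", "CH2", "CE3", "CZ2", "CD2", "CE2")
    k <- spec$occupancyRequest
    pts <- t(vapply(seq_len(k), function(i) {
      av <- as.numeric(trp[trp$name == anchors[i], c("x", "y", "z")])
      av + 4.0 * vunit(av - hexFit$centroid)
    }, numeric(3L)))
    addAtoms(sprintf("C%d", 20 + seq_len(k)), pts, rep("C", k))
  }

  if (nrow(ligCoords) >= 2L) {
    dd <- pairwiseDistances(ligCoords, ligCoords)
    diag(dd) <- Inf
    if (min(dd) < 1.0) {
      stop("unrealizable pose request: ligand atoms closer than 1.0 A",
           call. = FALSE)
    }
  }
  if (!nrow(ligCoords)) {
    stop("pose spec requests no interactions; nothing to build",
         call. = FALSE)
  }

  ligAtoms <- makeAtomTable(ligNames, ligCoords, ligElems, "LIG",
                            resno = 900L, chain = "L", serialStart = 501L,
                            het = TRUE)
  pose <- PoseComplex(Structure(protAtoms, sourceId = "toy-pocket"),
                      Structure(ligAtoms, sourceId = ligandId),
                      poseId = ligandId, sourceStructure = "toy-pocket")

  # orient the whole complex so the Trp34 sidechain reads flip-in
  # against the canonical z axis
  fl <- classifyFlip(protein(pose), 34, axis = c(0, 0, 1))
  rot <- rotationBetween(fl@orientationVector, c(1, 0, 0))
  pose <- transformCoords(pose, rotation = rot)

  verifyPose(pose, spec)
  pose
}

# Closed-loop self-check: every requested interaction must be detected at
# its requested geometry, and no unrequested interaction of a checked
# class may appear.
verifyPose <- function(pose, spec) {
  requestedRes <- vapply(spec$hbondRequests, `[[`, character(1L), "residue")
  for (r in spec$hbondRequests) {
    hb <- detectHBonds(pose, dMax = r$distance + 0.06,
                       residues = r$residue)
    ok <- any(abs(hb$distance_A - r$distance) <= 0.05)
    if (!ok) {
      stop(sprintf("pose construction failed: H-bond at %s not realized at %.2f A",
                   r$residue, r$distance), call. = FALSE)
    }
  }
  hbAll <- detectHBonds(pose, dMax = 3.5)
  stray <- setdiff(unique(hbAll$protein_residue), requestedRes)
  if (length(stray)) {
    stop(sprintf("pose construction failed: unrequested H-bond at %s",
                 paste(stray, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(spec$pistackRequest)) {
    d <- spec$pistackRequest[[1L]]
    ang <- spec$pistackRequest[[2L]]
    ps <- detectPiStacking(pose, dMax = d + 0.1, angleMax = min(90, ang + 2))
    ok <- any(abs(ps$centroid_distance_A - d) <= 0.05 &
                abs(ps$interplanar_angle_deg - ang) <= 2)
    if (!ok) {
      stop("pose construction failed: requested pi-stack not realized",
           call. = FALSE)
    }
  } else {
    ps <- detectPiStacking(pose)
    if (nrow(ps)) {
      stop("pose construction failed: unrequested pi-stack detected",
           call. = FALSE)
    }
  }
  if (!is.null(spec$occupancyRequest)) {
    occ <- pocketOccupancy(pose)
    want <- spec$occupancyRequest
    ok <- if (is.null(spec$pistackRequest)) occ$count == want
          else occ$count >= want
    if (!ok) {
      stop(sprintf("pose construction failed: pocket occupancy %d, requested %d",
                   occ$count, want), call. = FALSE)
    }
  }
  invisible(TRUE)
}
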