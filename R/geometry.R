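# Dihedral, axis, flip-classification and superposition geometry.

#' Signed dihedral angle of four points
#'
#' Standard atan2 torsion: the angle between the plane through p1,p2,p3 and
#' the plane through p2,p3,p4, signed by the right-hand rule about the
#' p2->p3 axis, returned in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom)
#' @return signed angle in degrees
#' @examples
#' dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0))  # 180
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b1) < 1e-9 || vnorm(b2) < 1e-9 || vnorm(b3) < 1e-9) {
    stop("undefined dihedral: coincident consecutive points", call. = FALSE)
  }
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9) {
    stop("undefined dihedral: collinear points", call. = FALSE)
  }
  x <- sum(n1 * n2)
  y <- sum(vcross(n1, n2) * vunit(b2))
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

getResidueAtom <- function(atoms, resno, name, chain = NULL) {
  sel <- atoms$resno == resno & atoms$name == name
  if (!is.null(chain)) sel <- sel & atoms$chain == chain
  hit <- atoms[sel, , drop = FALSE]
  if (nrow(hit) == 0L) {
    stop(sprintf("missing atom %s in residue %s", name, resno), call. = FALSE)
  }
  as.numeric(hit[1L, c("x", "y", "z")])
}

#' Sidechain chi1/chi2 angles of a residue
#'
#' chi1 is the N-CA-CB-CG torsion, chi2 the CA-CB-CG-CD1 torsion (CD1 as
#' the terminal reference atom, the usual convention for tryptophan).
#'
#' @param residue a [Structure] or atom data.frame containing one residue
#'   with atoms N, CA, CB, CG, CD1
#' @param resno residue number to use when several residues are present
#' @return named numeric vector `c(chi1 = ..., chi2 = ...)` in degrees
#' @export
chiAngles <- function(residue, resno = NULL) {
  atoms <- if (is(residue, "Structure")) atomRecords(residue) else residue
  if (is.null(resno)) resno <- atoms$resno[1L]
  atoms <- atoms[atoms$resno == resno, , drop = FALSE]
  pts <- lapply(c("N", "CA", "CB", "CG", "CD1"), function(nm) {
    sel <- atoms$name == nm
    if (!any(sel)) stop(sprintf("missing atom %s", nm), call. = FALSE)
    as.numeric(atoms[which(sel)[1L], c("x", "y", "z")])
  })
  names(pts) <- c("N", "CA", "CB", "CG", "CD1")
  c(chi1 = dihedral(pts$N, pts$CA, pts$CB, pts$CG),
    chi2 = dihedral(pts$CA, pts$CB, pts$CG, pts$CD1))
}

#' Principal axis of a protein fragment
#'
#' Direction of largest variance of the centred CA coordinates; the sign is
#' fixed so that the axis points from the lowest-numbered towards the
#' highest-numbered CA residue.
#'
#' @param structure a [Structure]
#' @param selection optional logical/integer index into the atom table
#' @return unit 3-vector
#' @export
proteinAxis <- function(structure, selection = NULL) {
  atoms <- atomRecords(structure)
  if (!is.null(selection)) atoms <- atoms[selection, , drop = FALSE]
  ca <- atoms[atoms$name == "CA", , drop = FALSE]
  if (nrow(ca) < 3L) {
    stop("need at least 3 CA atoms to define a protein axis", call. = FALSE)
  }
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  cxyz <- scale(xyz, center = TRUE, scale = FALSE)
  sv <- svd(cxyz)
  if (sv$d[1L] < 1e-9 || sv$d[1L] - sv$d[2L] < 1e-9 && sv$d[2L] < 1e-9) {
    stop("degenerate CA geometry: no principal axis", call. = FALSE)
  }
  ax <- sv$v[, 1L]
  ord <- order(ca$resno)
  span <- as.numeric(xyz[ord[nrow(ca)], ] - xyz[ord[1L], ])
  if (sum(ax * span) < 0) ax <- -ax
  vunit(ax)
}

INDOLE_RING_ATOMS <- c("CG", "CD1", "CD2", "NE1", "CE2", "CE3",
                       "CZ2", "CZ3", "CH2")

#' Classify the Trp sidechain as flip-in or flip-out
#'
#' The orientation vector runs from CB to the centroid of the nine indole
#' ring atoms; its angle to the supplied protein axis is folded into
#' [0, 90] degrees via the absolute cosine, so axis sign does not matter.
#' Angles at or below `threshold` count as parallel to the axis, i.e. the
#' ApoE4-like "flip-out" state; larger angles are perpendicular,
#' "flip-in", the ApoE2/E3-like state.
#'
#' @param structure a [Structure] containing the tryptophan residue
#' @param trpResno residue number of the tryptophan (default 34)
#' @param axis unit 3-vector protein axis (see [proteinAxis()])
#' @param threshold classification boundary in degrees (default 45)
#' @return a [FlipClassification]
#' @export
classifyFlip <- function(structure, trpResno = 34, axis, threshold = 45) {
  atoms <- atomRecords(structure)
  res <- atoms[atoms$resno == trpResno, , drop = FALSE]
  miss <- setdiff(c("CB", INDOLE_RING_ATOMS), res$name)
  if (length(miss)) {
    stop(sprintf("incomplete Trp residue %s: missing %s", trpResno,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  cb <- as.numeric(res[res$name == "CB", c("x", "y", "z")][1L, ])
  ring <- as.matrix(res[res$name %in% INDOLE_RING_ATOMS, c("x", "y", "z")])
  v <- vunit(colMeans(ring) - cb)
  ax <- vunit(axis)
  ang <- rad2deg(acos(min(1, abs(sum(v * ax)))))
  state <- if (ang <= threshold) "flip-out" else "flip-in"
  new("FlipClassification", angleToAxis = ang, state = state,
      threshold = threshold, orientationVector = v)
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares superposition of `mobile` onto `reference` via SVD of the
#' cross-covariance matrix, with the reflection corrected so the rotation
#' is always proper (determinant +1).
#'
#' @param reference n-by-3 coordinate matrix
#' @param mobile n-by-3 coordinate matrix, matched row-for-row
#' @param selection optional row index used to fit the transform; the RMSD
#'   is reported over the selected rows
#' @return list with `rotation` (3x3), `translation` (3-vector such that
#'   transformed = mobile %*% t(rotation) + translation), `rmsd` (Angstrom)
#'   and `transform(x)` applying the fit to any n-by-3 matrix
#' @export
kabschSuperpose <- function(reference, mobile, selection = NULL) {
  reference <- as.matrix(reference)
  mobile <- as.matrix(mobile)
  if (!all(dim(reference) == dim(mobile)) || ncol(reference) != 3L) {
    stop("reference and mobile must be matched n-by-3 matrices", call. = FALSE)
  }
  if (is.null(selection)) selection <- seq_len(nrow(reference))
  refs <- reference[selection, , drop = FALSE]
  mobs <- mobile[selection, , drop = FALSE]
  if (nrow(refs) < 3L) {
    stop("need at least 3 matched atoms for superposition", call. = FALSE)
  }
  cr <- colMeans(refs)
  cm <- colMeans(mobs)
  a <- sweep(mobs, 2L, cm)
  b <- sweep(refs, 2L, cr)
  if (svd(b)$d[2L] < 1e-9) {
    stop("degenerate (collinear) reference selection", call. = FALSE)
  }
  h <- t(a) %*% b
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cr - as.numeric(rot %*% cm)
  fitted <- a %*% t(rot) + matrix(cr, nrow(a), 3L, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - refs)^2)))
  transform <- function(x) {
    x <- as.matrix(x)
    x %*% t(rot) + matrix(trans, nrow(x), 3L, byrow = TRUE)
  }
  list(rotation = rot, translation = trans, rmsd = rmsd,
       transform = transform)
}

rmsdBetween <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Ligand and backbone RMSD series over a trajectory
#'
#' Each frame is superposed onto the first frame using the backbone
#' selection only; the backbone RMSD is that of the fit, and the ligand
#' RMSD is measured after the same transform without re-fitting, the usual
#' convention for pocket-stability analyses.
#'
#' @param frames list of n-by-3 coordinate matrices with identical atom
#'   ordering across frames
#' @param ligandSel integer/logical row index of ligand atoms
#' @param backboneSel integer/logical row index of backbone atoms
#' @param frameIntervalNs time between frames in nanoseconds
#' @return data.frame with columns frame, time_ns, backbone_rmsd_A,
#'   ligand_rmsd_A
#' @export
rmsdSeries <- function(frames, ligandSel, backboneSel,
                       frameIntervalNs = 0.1) {
  if (!length(frames)) stop("empty trajectory", call. = FALSE)
  ref <- as.matrix(frames[[1L]])
  n <- nrow(ref)
  out <- data.frame(frame = seq_along(frames),
                    time_ns = (seq_along(frames) - 1L) * frameIntervalNs,
                    backbone_rmsd_A = NA_real_, ligand_rmsd_A = NA_real_)
  for (i in seq_along(frames)) {
    fr <- as.matrix(frames[[i]])
    if (nrow(fr) != n) {
      stop(sprintf("atom-set mismatch at frame %d (%d vs %d atoms)",
                   i, nrow(fr), n), call. = FALSE)
    }
    fit <- kabschSuperpose(ref, fr, selection = backboneSel)
    moved <- fit$transform(fr)
    out$backbone_rmsd_A[i] <- rmsdBetween(moved[backboneSel, , drop = FALSE],
                                          ref[backboneSel, , drop = FALSE])
    out$ligand_rmsd_A[i] <- rmsdBetween(moved[ligandSel, , drop = FALSE],
                                        ref[ligandSel, , drop = FALSE])
  }
  out
}

#' Fraction of trajectory frames in the flip-in state
#'
#' @param x a dihedral/flip series data.frame with a `state` column, a
#'   character vector of states, or a list of [FlipClassification] objects
#' @return fraction in [0, 1]
#' @export
flipFraction <- function(x) {
  states <- if (is.data.frame(x)) {
    x$state
  } else if (is.list(x) && length(x) && is(x[[1L]], "FlipClassification")) {
    vapply(x, flipState, character(1L))
  } else {
    as.character(x)
  }
  if (!length(states)) stop("need at least one frame", call. = FALSE)
  bad <- setdiff(unique(states), c("flip-in", "flip-out"))
  if (length(bad)) {
    stop(sprintf("unknown flip state: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  mean(states == "flip-in")
}
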