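# Idealized amino-acid builders used by the synthetic pose and trajectory
# generators.  Geometry is standard (bond lengths/angles of ideal residues,
# exactly planar rings); no real ApoE coordinates are involved.

makeAtomTable <- function(names, coords, elements, resname, resno,
                          chain = "A", serialStart = 1L, het = FALSE) {
  data.frame(
    serial = seq_along(names) + serialStart - 1L,
    name = names,
    altloc = "",
    resname = resname,
    chain = chain,
    resno = as.integer(resno),
    x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
    element = elements,
    het = het,
    stringsAsFactors = FALSE)
}

# Planar indole template (2D): fused regular pentagon/hexagon, side sRing,
# CG at the origin, CD1 along +x, CD2 at positive y.
indoleTemplate <- function(sRing = 1.39) {
  r5 <- sRing / (2 * sin(pi / 5))
  ang0 <- pi / 2
  pent <- t(vapply(0:4, function(k) {
    a <- ang0 + k * 2 * pi / 5
    r5 * c(cos(a), sin(a))
  }, numeric(2L)))
  rownames(pent) <- c("CG", "CD1", "NE1", "CE2", "CD2")
  pent <- sweep(pent, 2L, pent["CG", ])
  th <- atan2(pent["CD1", 2L], pent["CD1", 1L])
  rot <- matrix(c(cos(-th), sin(-th), -sin(-th), cos(-th)), 2L, 2L)
  pent <- pent %*% t(rot)
  if (pent["CD2", 2L] < 0) pent[, 2L] <- -pent[, 2L]
  # hexagon fused on the CD2-CE2 edge, centred on the far side of the edge
  mid <- (pent["CD2", ] + pent["CE2", ])
  mid <- mid / 2
  pentCenter <- colMeans(pent)
  edge <- pent["CE2", ] - pent["CD2", ]
  nrm <- c(-edge[2L], edge[1L]) / sqrt(sum(edge^2))
  if (sum(nrm * (pentCenter - mid)) > 0) nrm <- -nrm
  hexCenter <- mid + nrm * sRing * sqrt(3) / 2
  angOf <- function(p) atan2(p[2L] - hexCenter[2L], p[1L] - hexCenter[1L])
  aCD2 <- angOf(pent["CD2", ])
  aCE2 <- angOf(pent["CE2", ])
  step <- aCE2 - aCD2
  step <- atan2(sin(step), cos(step))  # signed 60 degrees
  rHex <- sRing
  hexAt <- function(a) hexCenter + rHex * c(cos(a), sin(a))
  extra <- rbind(
    CZ2 = hexAt(aCE2 + step),
    CH2 = hexAt(aCE2 + 2 * step),
    CZ3 = hexAt(aCE2 + 3 * step),
    CE3 = hexAt(aCE2 + 4 * step))
  rbind(pent, extra)
}

.templateCache <- new.env(parent = emptyenv())

getIndoleTemplate <- function() {
  if (is.null(.templateCache$indole)) {
    .templateCache$indole <- indoleTemplate()
  }
  .templateCache$indole
}

backboneAtoms <- function() {
  n <- c(1.458, 0, 0)
  ca <- c(0, 0, 0)
  cc <- 1.525 * c(cos(deg2rad(111)), sin(deg2rad(111)), 0)
  o <- placeAtom(n, ca, cc, 1.23, 120.5, -45)
  cb <- placeAtom(cc, n, ca, 1.53, 110.4, 122.5)
  list(N = n, CA = ca, C = cc, O = o, CB = cb)
}

#' Build an idealized tryptophan residue with prescribed chi angles
#'
#' Backbone at a canonical position (CA at the origin), sidechain placed
#' by internal coordinates so that chi1 = N-CA-CB-CG and
#' chi2 = CA-CB-CG-CD1 take the requested values exactly; the nine-atom
#' indole is an exactly planar fused pentagon/hexagon with 1.39 Angstrom
#' sides.
#'
#' @param chi1,chi2 sidechain dihedrals in degrees
#' @param resno residue number (default 34)
#' @param chain chain identifier
#' @param serialStart first atom serial number
#' @return atom data.frame (see [Structure()])
#' @export
buildTrpResidue <- function(chi1 = -60, chi2 = 90, resno = 34,
                            chain = "A", serialStart = 1L) {
  bb <- backboneAtoms()
  cg <- placeAtom(bb$N, bb$CA, bb$CB, 1.52, 113.6, chi1)
  cd1 <- placeAtom(bb$CA, bb$CB, cg, 1.39, 127.0, chi2)
  cd2 <- placeAtom(bb$CA, bb$CB, cg, 1.43, 126.6, chi2 + 180)
  e1 <- vunit(cd1 - cg)
  w <- cd2 - cg
  e2 <- vunit(w - sum(w * e1) * e1)
  tmpl <- getIndoleTemplate()
  ring <- t(apply(tmpl, 1L, function(p) cg + p[1L] * e1 + p[2L] * e2))
  names_ <- c("N", "CA", "C", "O", "CB", rownames(tmpl))
  coords <- rbind(bb$N, bb$CA, bb$C, bb$O, bb$CB, ring)
  elements <- ifelse(names_ %in% c("N", "NE1"), "N",
                     ifelse(names_ == "O", "O", "C"))
  makeAtomTable(names_, coords, elements, "TRP", resno, chain, serialStart)
}

#' Build an idealized aspartate residue
#'
#' @param chi1,chi2 sidechain dihedrals in degrees
#' @param resno residue number
#' @param chain chain identifier
#' @param serialStart first atom serial number
#' @return atom data.frame (see [Structure()])
#' @export
buildAspResidue <- function(chi1 = -70, chi2 = -20, resno = 35,
                            chain = "A", serialStart = 1L) {
  bb <- backboneAtoms()
  cg <- placeAtom(bb$N, bb$CA, bb$CB, 1.52, 113.0, chi1)
  od1 <- placeAtom(bb$CA, bb$CB, cg, 1.25, 118.5, chi2)
  od2 <- placeAtom(bb$CA, bb$CB, cg, 1.25, 118.5, chi2 + 180)
  names_ <- c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2")
  coords <- rbind(bb$N, bb$CA, bb$C, bb$O, bb$CB, cg, od1, od2)
  elements <- c("N", "C", "C", "O", "C", "C", "O", "O")
  makeAtomTable(names_, coords, elements, "ASP", resno, chain, serialStart)
}

translateAtoms <- function(atoms, shift) {
  atoms$x <- atoms$x + shift[1L]
  atoms$y <- atoms$y + shift[2L]
  atoms$z <- atoms$z + shift[3L]
  atoms
}

rotateAtoms <- function(atoms, rot, about = c(0, 0, 0)) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2L, about)
  xyz <- xyz %*% t(rot)
  xyz <- sweep(xyz, 2L, about, "+")
  atoms$x <- xyz[, 1L]; atoms$y <- xyz[, 2L]; atoms$z <- xyz[, 3L]
  atoms
}

#' Apply a rigid transform to a Structure or PoseComplex
#'
#' @param x a [Structure] or [PoseComplex]
#' @param rotation 3x3 rotation matrix
#' @param translation 3-vector
#' @return transformed object of the same class
#' @export
transformCoords <- function(x, rotation = diag(3), translation = c(0, 0, 0)) {
  if (is(x, "PoseComplex")) {
    return(PoseComplex(
      transformCoords(protein(x), rotation, translation),
      transformCoords(ligandAtoms(x), rotation, translation),
      poseId = x@poseId, sourceStructure = x@sourceStructure))
  }
  at <- rotateAtoms(atomRecords(x), rotation)
  at <- translateAtoms(at, translation)
  Structure(at, sourceId = x@sourceId)
}
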