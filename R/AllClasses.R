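# S4 classes for the screening data containers.

STRUCTURE_CATEGORIES <- c("apoE3", "free-apoE4", "holo-apoE4")

#' ScoreMatrix: ligand-by-structure docking scores or ranks
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single assay of docking scores (kcal/mol, lower is better) or per-column
#' ranks (1 = best).  Rows are ligands, columns are receptor structures;
#' `colData(x)$category` tags each structure as `"apoE3"`, `"free-apoE4"`
#' or `"holo-apoE4"`, the grouping the consensus score is built on.
#'
#' @slot .Data inherited SummarizedExperiment representation
#' @seealso [ScoreMatrix()], [buildConsensusTable()]
#' @export
setClass("ScoreMatrix", contains = "SummarizedExperiment")

#' Structure: atom records with coordinates
#'
#' Minimal coordinate container for geometry operations: one row per atom
#' with PDB-style identification (serial, atom name, altloc, residue name,
#' chain, residue number), Cartesian coordinates in Angstrom and an element
#' symbol.
#'
#' @slot atoms data.frame with columns serial, name, altloc, resname,
#'   chain, resno, x, y, z, element
#' @slot sourceId character identifier for provenance (e.g. a PDB id)
#' @export
setClass("Structure",
         representation(atoms = "data.frame", sourceId = "character"))

setValidity("Structure", function(object) {
  at <- object@atoms
  need <- c("serial", "name", "altloc", "resname", "chain", "resno",
            "x", "y", "z", "element")
  miss <- setdiff(need, names(at))
  if (length(miss)) {
    return(sprintf("atoms is missing column(s): %s",
                   paste(miss, collapse = ", ")))
  }
  if (nrow(at)) {
    xyz <- as.matrix(at[, c("x", "y", "z")])
    if (!all(is.finite(xyz))) return("non-finite coordinates")
    key <- paste(at$chain, at$resno, at$name, at$altloc)
    if (anyDuplicated(key)) {
      return("duplicate (chain, resno, name, altloc) atom records")
    }
  }
  TRUE
})

#' PoseComplex: a protein fragment plus a docked ligand pose
#'
#' @slot protein [Structure] with the receptor atoms
#' @slot ligand [Structure] with the ligand atoms (HETATM-style records)
#' @slot poseId identifier of the pose
#' @slot sourceStructure identifier of the receptor the pose was docked into
#' @export
setClass("PoseComplex",
         representation(protein = "Structure", ligand = "Structure",
                        poseId = "character", sourceStructure = "character"))

setValidity("PoseComplex", function(object) {
  pk <- with(object@protein@atoms, paste(chain, resno, name))
  lk <- with(object@ligand@atoms, paste(chain, resno, name))
  if (length(intersect(pk, lk))) return("ligand and protein atom sets overlap")
  TRUE
})

#' FlipClassification: Trp sidechain orientation relative to the protein axis
#'
#' The orientation vector runs from CB to the centroid of the nine-atom
#' indole ring; the angle to the protein axis is folded into [0, 90] degrees
#' by the absolute-cosine convention, so the sign of the axis is irrelevant.
#' The sidechain is called `"flip-out"` (ApoE4-like, parallel to the axis)
#' when the angle is at most `threshold`, `"flip-in"` (ApoE2/E3-like,
#' perpendicular) otherwise.
#'
#' @slot angleToAxis angle in degrees, in [0, 90]
#' @slot state `"flip-in"` or `"flip-out"`
#' @slot threshold classification boundary in degrees
#' @slot orientationVector unit 3-vector, CB to indole centroid
#' @export
setClass("FlipClassification",
         representation(angleToAxis = "numeric", state = "character",
                        threshold = "numeric",
                        orientationVector = "numeric"))

setValidity("FlipClassification", function(object) {
  if (object@angleToAxis < -1e-9 || object@angleToAxis > 90 + 1e-9) {
    return("angleToAxis must lie in [0, 90]")
  }
  if (!object@state %in% c("flip-in", "flip-out")) {
    return("state must be 'flip-in' or 'flip-out'")
  }
  expected <- if (object@angleToAxis <= object@threshold) "flip-out" else "flip-in"
  if (object@state != expected) {
    return("state inconsistent with angleToAxis and threshold")
  }
  if (abs(vnorm(object@orientationVector) - 1) > 1e-6) {
    return("orientationVector must be a unit vector")
  }
  TRUE
})

setMethod("show", "Structure", function(object) {
  cat(sprintf("Structure '%s': %d atoms, %d residues\n",
              object@sourceId, nrow(object@atoms),
              length(unique(paste(object@atoms$chain, object@atoms$resno)))))
})

setMethod("show", "PoseComplex", function(object) {
  cat(sprintf("PoseComplex '%s' in receptor '%s': %d protein / %d ligand atoms\n",
              object@poseId, object@sourceStructure,
              nrow(object@protein@atoms), nrow(object@ligand@atoms)))
})

setMethod("show", "FlipClassification", function(object) {
  cat(sprintf("Trp sidechain %s (%.1f deg to axis, threshold %.0f deg)\n",
              object@state, object@angleToAxis, object@threshold))
})
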