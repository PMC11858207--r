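# Generics and accessors for the S4 containers.

#' @rdname ScoreMatrix-class
#' @param x a `ScoreMatrix`
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))

#' @rdname ScoreMatrix-class
#' @export
setGeneric("valueKind", function(x) standardGeneric("valueKind"))

#' @rdname ScoreMatrix-class
#' @export
setGeneric("structureCategory", function(x) standardGeneric("structureCategory"))

#' @rdname ScoreMatrix-class
#' @export
setGeneric("ligandIds", function(x) standardGeneric("ligandIds"))

#' @rdname ScoreMatrix-class
#' @export
setGeneric("structureIds", function(x) standardGeneric("structureIds"))

#' @rdname ScoreMatrix-class
#' @export
setGeneric("asRankMatrix", function(x) standardGeneric("asRankMatrix"))

#' @rdname Structure-class
#' @param x a `Structure` or `PoseComplex`
#' @export
setGeneric("atomRecords", function(x) standardGeneric("atomRecords"))

#' @rdname Structure-class
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname PoseComplex-class
#' @export
setGeneric("protein", function(x) standardGeneric("protein"))

#' @rdname PoseComplex-class
#' @export
setGeneric("ligandAtoms", function(x) standardGeneric("ligandAtoms"))

#' @rdname FlipClassification-class
#' @param x a `FlipClassification`
#' @export
setGeneric("flipState", function(x) standardGeneric("flipState"))

#' @rdname FlipClassification-class
#' @export
setGeneric("flipAngle", function(x) standardGeneric("flipAngle"))

setMethod("scoreValues", "ScoreMatrix", function(x) {
  m <- assay(x, 1L)
  storage.mode(m) <- "double"
  m
})

setMethod("valueKind", "ScoreMatrix", function(x) metadata(x)$valueKind)

setMethod("structureCategory", "ScoreMatrix", function(x) {
  setNames(as.character(colData(x)$category), colnames(x))
})

setMethod("ligandIds", "ScoreMatrix", function(x) rownames(x))

setMethod("structureIds", "ScoreMatrix", function(x) colnames(x))

setMethod("asRankMatrix", "ScoreMatrix", function(x) {
  if (valueKind(x) == "rank") return(x)
  m <- scoreValues(x)
  if (anyNA(m)) {
    stop("cannot rank a score matrix with missing cells", call. = FALSE)
  }
  ranks <- apply(m, 2L, rankScores)
  dimnames(ranks) <- dimnames(m)
  ScoreMatrix(ranks, categories = structureCategory(x), valueKind = "rank")
})

setMethod("atomRecords", "Structure", function(x) x@atoms)

setMethod("coords", "Structure", function(x) {
  m <- as.matrix(x@atoms[, c("x", "y", "z")])
  rownames(m) <- NULL
  m
})

setMethod("protein", "PoseComplex", function(x) x@protein)

setMethod("ligandAtoms", "PoseComplex", function(x) x@ligand)

setMethod("atomRecords", "PoseComplex", function(x) {
  rbind(x@protein@atoms, x@ligand@atoms)
})

setMethod("flipState", "FlipClassification", function(x) x@state)

setMethod("flipAngle", "FlipClassification", function(x) x@angleToAxis)

#' Construct a ScoreMatrix
#'
#' @param values numeric matrix, ligands in rows (rownames = ligand ids),
#'   structures in columns (colnames = structure ids)
#' @param categories character vector, one of `"apoE3"`, `"free-apoE4"`,
#'   `"holo-apoE4"` per column (recycled by name if named)
#' @param valueKind `"score"` for docking scores (kcal/mol, lower better)
#'   or `"rank"` for per-column ranks (1 = best)
#' @return a [ScoreMatrix] object
#' @examples
#' m <- matrix(c(1, 2, 2, 1, 1, 2, 1, 2, 2, 1, 2, 1), nrow = 2,
#'             dimnames = list(c("ligA", "ligB"),
#'                             c("E3a", "E3b", "F4a", "F4b", "H4a", "H4b")))
#' sm <- ScoreMatrix(m, categories = c("apoE3", "apoE3", "free-apoE4",
#'                                     "free-apoE4", "holo-apoE4",
#'                                     "holo-apoE4"), valueKind = "rank")
#' structureCategory(sm)
#' @export
ScoreMatrix <- function(values, categories,
                        valueKind = c("score", "rank")) {
  valueKind <- match.arg(valueKind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must carry ligand row names and structure column names",
         call. = FALSE)
  }
  if (!is.null(names(categories))) {
    categories <- categories[colnames(values)]
  }
  if (length(categories) != ncol(values) || anyNA(categories)) {
    stop("'categories' must supply one category per structure column",
         call. = FALSE)
  }
  bad <- setdiff(unique(categories), STRUCTURE_CATEGORIES)
  if (length(bad)) {
    stop(sprintf("unknown structure category: %s (expected %s)",
                 paste(bad, collapse = ", "),
                 paste(STRUCTURE_CATEGORIES, collapse = ", ")),
         call. = FALSE)
  }
  se <- SummarizedExperiment(
    assays = setNames(list(values), valueKind),
    colData = DataFrame(category = as.character(categories),
                        row.names = colnames(values)),
    metadata = list(valueKind = valueKind))
  out <- new("ScoreMatrix", se)
  validObject(out)
  out
}

setValidity("ScoreMatrix", function(object) {
  vk <- metadata(object)$valueKind
  if (is.null(vk) || !vk %in% c("score", "rank")) {
    return("metadata valueKind must be 'score' or 'rank'")
  }
  if (!"category" %in% names(colData(object))) {
    return("colData must contain a 'category' column")
  }
  m <- assay(object, 1L)
  if (vk == "rank" && nrow(m)) {
    for (j in seq_len(ncol(m))) {
      col <- m[, j]
      if (anyNA(col)) next  # incomplete columns are allowed, flagged not imputed
      if (any(col <= 0)) return(sprintf("ranks in column '%s' must be positive",
                                        colnames(m)[j]))
    }
  }
  TRUE
})

#' Construct a Structure from an atom table
#'
#' @param atoms data.frame with columns serial, name, altloc, resname,
#'   chain, resno, x, y, z, element
#' @param sourceId provenance identifier
#' @return a [Structure]
#' @export
Structure <- function(atoms, sourceId = "unknown") {
  rownames(atoms) <- NULL
  new("Structure", atoms = atoms, sourceId = as.character(sourceId))
}

#' Construct a PoseComplex
#'
#' @param protein receptor [Structure]
#' @param ligand ligand [Structure]
#' @param poseId pose identifier
#' @param sourceStructure receptor identifier the pose belongs to
#' @return a [PoseComplex]
#' @export
PoseComplex <- function(protein, ligand, poseId = "pose",
                        sourceStructure = protein@sourceId) {
  new("PoseComplex", protein = protein, ligand = ligand,
      poseId = as.character(poseId),
      sourceStructure = as.character(sourceStructure))
}
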