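# Bundled reference tables: published benchmark data for the eight known
# ApoE4 stabilizers (docking ranks and NMR Kd), the two top-25 screening
# hit lists, the induced-fit interaction checklist and the SPR flavonoid
# binding panel.  All are small plain-text TSVs under inst/extdata and are
# loaded through the package's own readers.

extdataPath <- function(name) {
  p <- system.file("extdata", name, package = "apoescreen",
                   mustWork = FALSE)
  if (!nzchar(p)) stop(sprintf("bundled data file '%s' not found", name),
                       call. = FALSE)
  p
}

ENSEMBLE_CATEGORIES <- c(
  "1NFN" = "apoE3", "1BZ4" = "apoE3",
  "8CE0" = "free-apoE4", "8CDY" = "free-apoE4",
  "6NCN" = "holo-apoE4", "6NCO" = "holo-apoE4")

#' Docking ranks of the eight known ApoE4 stabilizers
#'
#' Published AutoDock-Vina best-score ranks of the eight known ApoE4
#' stabilizer ligands (PubChem CIDs) within the ~1250-molecule screening
#' library, against the six ensemble structures: two apo ApoE3 (1NFN,
#' 1BZ4), two free ApoE4 (8CE0, 8CDY) and two holo ApoE4 (6NCN, 6NCO).
#'
#' @return a [ScoreMatrix] with valueKind `"rank"`
#' @export
knownLigandRanks <- function() {
  readScoreTable(extdataPath("known_ligand_ranks.tsv"),
                 categories = ENSEMBLE_CATEGORIES, valueKind = "rank")
}

#' NMR Kd values of the eight known ApoE4 stabilizers
#'
#' @return data.frame of Kd records (micromolar; `"<5"` entries carry a
#'   `below` censor flag)
#' @export
knownLigandKd <- function() {
  readKdTable(extdataPath("known_ligand_kd.tsv"))
}

#' Induced-fit interaction checklist of the known ApoE4 stabilizers
#'
#' Per-ligand Trp34 orientation after induced-fit docking, H-bond flags
#' for Asp35 and Asp153, and the hydrophobic group occupying the Trp34
#' pocket.
#'
#' @return checklist data.frame (see [readInteractionTable()])
#' @export
knownLigandChecklist <- function() {
  readInteractionTable(extdataPath("ifd_interaction_checklist.tsv"))
}

#' SPR binding panel of Isobavachin and related flavonoids
#'
#' Long-format Kd records of nine flavonoids against ApoE3, ApoE4 and the
#' negative-control protein DNPH1, with `">100"` and `"No binding"`
#' censoring.
#'
#' @return data.frame of Kd records with a `protein` column
#' @export
flavonoidBindingTable <- function() {
  readKdTable(extdataPath("spr_flavonoid_kd.tsv"))
}

#' Library-wide consensus ranks of the known ApoE4 stabilizers
#'
#' The published consensus ranks of the eight known stabilizers within the
#' full ~1250-molecule screening library (the library-wide counterpart of
#' the eight-ligand ordering computable from [knownLigandRanks()]).
#'
#' @return data.frame with columns ligand_id, library_consensus_rank
#' @export
knownLigandLibraryRanks <- function() {
  read.delim(extdataPath("known_ligand_library_ranks.tsv"), sep = "\t",
             colClasses = c("character", "integer"))
}

#' Top-25 hit lists of the docking and shape-screening branches
#'
#' The consensus-docking and combined shape-similarity top-25 PubChem CID
#' lists of the screening campaign, in rank order.
#'
#' @return list with elements `docking` and `shape`, each a data.frame
#'   (rank, ligand_id)
#' @export
screeningHitLists <- function() {
  rd <- function(f) read.delim(extdataPath(f), sep = "\t",
                               colClasses = c("integer", "character"))
  list(docking = rd("docking_hits_top25.tsv"),
       shape = rd("shape_hits_top25.tsv"))
}
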