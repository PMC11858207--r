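# ApoE crystal-structure metadata fixture and orientation-based triage.

#' Metadata for the eight candidate ApoE crystal structures
#'
#' Returns the shortlist of natural, non-mutant, high-resolution (<= 2 A)
#' ApoE X-ray structures used for ensemble docking: three apo ApoE3
#' (1NFN, 1BZ4, 1OR3), three apo ApoE4 (1B68, 8CE0, 8CDY) and two
#' holo ApoE4 structures bound to small-molecule stabilizers (6NCN, 6NCO),
#' each labelled with its observed tryptophan-34 sidechain orientation.
#' 1OR3 is an ApoE3 structure whose Trp34 sits in the ApoE4-like flip-out
#' position, and 1B68 an ApoE4 structure with an ApoE3-like flip-in Trp34;
#' both are the expected triage casualties.  The holo structures carry
#' flip-in, the orientation the bound stabilizers induce.  Resolution
#' values are plausible synthetic placeholders at or below the 2 A
#' selection cutoff; only the cutoff predicate matters downstream.
#'
#' @return data.frame with columns pdb_id, isoform, category, method,
#'   resolution_A, mutant, trp34_orientation
#' @export
genStructureMetadata <- function() {
  data.frame(
    pdb_id = c("1NFN", "1BZ4", "1OR3", "1B68", "8CE0", "8CDY",
               "6NCN", "6NCO"),
    isoform = c("E3", "E3", "E3", "E4", "E4", "E4", "E4", "E4"),
    category = c("apo", "apo", "apo", "apo", "apo", "apo", "holo", "holo"),
    method = "X-ray",
    resolution_A = c(1.8, 1.8, 1.8, 2.0, 1.9, 1.9, 1.8, 1.9),
    mutant = FALSE,
    trp34_orientation = c("flip-in", "flip-in", "flip-out", "flip-in",
                          "flip-out", "flip-out", "flip-in", "flip-in"),
    stringsAsFactors = FALSE
  )
}

# Expected Trp34 orientation per (isoform, category).
expectedOrientation <- function(isoform, category) {
  ifelse(category == "holo", "flip-in",
         ifelse(isoform %in% c("E2", "E3"), "flip-in", "flip-out"))
}

#' Shortlist ensemble structures by quality and Trp34 orientation
#'
#' Keeps X-ray entries at or below the resolution cutoff and non-mutant,
#' then removes structures whose observed tryptophan-34 orientation
#' contradicts the expectation for their class: apo ApoE2/E3 are expected
#' flip-in, apo ApoE4 flip-out, and holo (stabilizer-bound) ApoE4 flip-in.
#'
#' @param metadata data.frame as returned by [genStructureMetadata()]
#' @param maxResolutionA resolution cutoff in Angstrom (default 2)
#' @param strict error (rather than drop) on `"unknown"` orientations
#' @return list with `selected` (kept rows), `removed` (data.frame of
#'   pdb_id + reason)
#' @export
triageStructures <- function(metadata, maxResolutionA = 2, strict = FALSE) {
  need <- c("pdb_id", "isoform", "category", "method", "resolution_A",
            "mutant", "trp34_orientation")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) {
    stop(sprintf("metadata is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  removed <- data.frame(pdb_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  drop <- function(ids, reason) {
    if (length(ids)) {
      removed <<- rbind(removed, data.frame(pdb_id = ids, reason = reason,
                                            stringsAsFactors = FALSE))
    }
  }
  keep <- rep(TRUE, nrow(metadata))

  bad <- keep & (metadata$method != "X-ray")
  drop(metadata$pdb_id[bad], "not an X-ray structure")
  keep <- keep & !bad

  bad <- keep & (metadata$resolution_A > maxResolutionA)
  drop(metadata$pdb_id[bad],
       sprintf("resolution above %g A", maxResolutionA))
  keep <- keep & !bad

  bad <- keep & metadata$mutant
  drop(metadata$pdb_id[bad], "mutant construct")
  keep <- keep & !bad

  unknown <- keep & (metadata$trp34_orientation == "unknown")
  if (any(unknown) && strict) {
    stop(sprintf("unknown Trp34 orientation for: %s",
                 paste(metadata$pdb_id[unknown], collapse = ", ")),
         call. = FALSE)
  }
  drop(metadata$pdb_id[unknown], "Trp34 orientation unknown")
  keep <- keep & !unknown

  expct <- expectedOrientation(metadata$isoform, metadata$category)
  bad <- keep & (metadata$trp34_orientation != expct)
  reasons <- paste0("Trp34 ", metadata$trp34_orientation,
                    " contradicts expected ", expct)
  drop(metadata$pdb_id[bad], reasons[bad])
  keep <- keep & !bad

  list(selected = metadata[keep, , drop = FALSE], removed = removed)
}
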