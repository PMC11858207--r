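# Geometric protein-ligand interaction detectors and checklist assembly.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")
HALOGENS <- c("F", "CL", "BR", "I")

pairwiseDistances <- function(a, b) {
  # a: n x 3, b: m x 3 -> n x m distance matrix
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

residueLabel <- function(atoms) paste0(atoms$resname, atoms$resno)

#' Detect interface hydrogen bonds by heavy-atom distance
#'
#' Reports every protein N/O - ligand N/O pair across the interface within
#' `dMax` Angstrom.  Crystal and docked poses typically lack hydrogens, so
#' the heavy-atom donor-acceptor distance is the standard criterion; no
#' attempt is made to assign donor vs acceptor roles.
#'
#' @param pose a [PoseComplex]
#' @param dMax heavy-atom distance cutoff in Angstrom (default 3.5)
#' @param residues optional character vector of residue labels (e.g.
#'   `"ASP35"`) restricting the protein side
#' @return data.frame with protein_atom, protein_residue, ligand_atom,
#'   distance_A (possibly zero rows)
#' @export
detectHBonds <- function(pose, dMax = 3.5, residues = NULL) {
  stopIfNotScalarNumber(dMax, "dMax", 0, Inf, strict = TRUE)
  pat <- atomRecords(protein(pose))
  lat <- atomRecords(ligandAtoms(pose))
  pat <- pat[toupper(pat$element) %in% c("N", "O"), , drop = FALSE]
  lat <- lat[toupper(lat$element) %in% c("N", "O"), , drop = FALSE]
  if (!is.null(residues)) {
    pat <- pat[residueLabel(pat) %in% residues, , drop = FALSE]
  }
  if (!nrow(pat) || !nrow(lat)) {
    return(data.frame(protein_atom = character(),
                      protein_residue = character(),
                      ligand_atom = character(), distance_A = numeric(),
                      stringsAsFactors = FALSE))
  }
  d <- pairwiseDistances(as.matrix(pat[, c("x", "y", "z")]),
                         as.matrix(lat[, c("x", "y", "z")]))
  hit <- which(d <= dMax, arr.ind = TRUE)
  out <- data.frame(
    protein_atom = pat$name[hit[, 1L]],
    protein_residue = residueLabel(pat)[hit[, 1L]],
    ligand_atom = lat$name[hit[, 2L]],
    distance_A = d[hit],
    stringsAsFactors = FALSE)
  out[order(out$distance_A), , drop = FALSE]
}

# Bonded adjacency from covalent distance (heavy atoms; <= 1.8 A).
connectivity <- function(xyz, maxBond = 1.8) {
  n <- nrow(xyz)
  if (n < 2L) return(matrix(FALSE, n, n))
  d <- pairwiseDistances(xyz, xyz)
  adj <- d <= maxBond & d > 1e-6
  adj
}

# All simple cycles of length 5 or 6 in a small adjacency matrix,
# deduplicated by atom set.
findRings <- function(adj, sizes = c(5L, 6L)) {
  n <- nrow(adj)
  rings <- list()
  seen <- character()
  path <- integer(max(sizes))
  recurse <- function(start, current, depth) {
    nbrs <- which(adj[current, ])
    for (nxt in nbrs) {
      if (nxt == start && depth >= min(sizes)) {
        if (depth %in% sizes) {
          key <- paste(sort(path[seq_len(depth)]), collapse = "-")
          if (!key %in% seen) {
            seen <<- c(seen, key)
            rings[[length(rings) + 1L]] <<- path[seq_len(depth)]
          }
        }
      } else if (depth < max(sizes) && nxt > start &&
                 !nxt %in% path[seq_len(depth)]) {
        path[depth + 1L] <<- nxt
        recurse(start, nxt, depth + 1L)
      }
    }
  }
  for (s in seq_len(n)) {
    path[1L] <- s
    recurse(s, s, 1L)
  }
  rings
}

planeFit <- function(xyz) {
  centered <- scale(xyz, center = TRUE, scale = FALSE)
  sv <- svd(centered)
  list(centroid = colMeans(xyz), normal = sv$v[, 3L],
       planarity = sv$d[3L] / sqrt(nrow(xyz)))
}

ringsOf <- function(atoms, supplied = NULL, maxBond = 1.8,
                    planarityTol = 0.15) {
  if (!is.null(supplied)) {
    return(lapply(supplied, function(idx) {
      if (length(idx) < 3L) {
        stop("a ring needs at least 3 atoms", call. = FALSE)
      }
      idx
    }))
  }
  ringAtoms <- which(toupper(atoms$element) %in% c("C", "N"))
  if (length(ringAtoms) < 5L) return(list())
  xyz <- as.matrix(atoms[ringAtoms, c("x", "y", "z")])
  adj <- connectivity(xyz, maxBond)
  rings <- findRings(adj)
  rings <- lapply(rings, function(r) ringAtoms[r])
  # keep near-planar (aromatic-like) rings only
  Filter(function(r) {
    pf <- planeFit(as.matrix(atoms[r, c("x", "y", "z")]))
    pf$planarity < planarityTol
  }, rings)
}

#' Detect parallel pi-stacking between ligand and protein rings
#'
#' Rings are perceived from covalent distance-based connectivity
#' (bonds taken as heavy-atom pairs within 1.8 Angstrom; 5- and 6-membered
#' near-planar C/N rings) or supplied explicitly as atom-index sets.  A
#' pair qualifies when the ring-centroid distance is at most `dMax` and
#' the angle between ring-plane normals at most `angleMax` (parallel
#' stacking only; T-shaped contacts are not scored).
#'
#' @param pose a [PoseComplex]
#' @param dMax centroid-centroid cutoff in Angstrom (default 5.5)
#' @param angleMax interplanar angle cutoff in degrees (default 30)
#' @param proteinRings,ligandRings optional lists of atom-index vectors
#'   (rows of the respective atom tables) overriding ring perception
#' @return data.frame with protein_residue, centroid_distance_A,
#'   interplanar_angle_deg, one row per qualifying pair
#' @export
detectPiStacking <- function(pose, dMax = 5.5, angleMax = 30,
                             proteinRings = NULL, ligandRings = NULL) {
  stopIfNotScalarNumber(dMax, "dMax", 0, Inf, strict = TRUE)
  stopIfNotScalarNumber(angleMax, "angleMax", 0, 90)
  pat <- atomRecords(protein(pose))
  lat <- atomRecords(ligandAtoms(pose))
  pr <- ringsOf(pat, proteinRings)
  lr <- ringsOf(lat, ligandRings)
  out <- data.frame(protein_residue = character(),
                    centroid_distance_A = numeric(),
                    interplanar_angle_deg = numeric(),
                    stringsAsFactors = FALSE)
  for (rp in pr) {
    fp <- planeFit(as.matrix(pat[rp, c("x", "y", "z")]))
    for (rl in lr) {
      fl <- planeFit(as.matrix(lat[rl, c("x", "y", "z")]))
      dist <- vnorm(fp$centroid - fl$centroid)
      ang <- rad2deg(acos(min(1, abs(sum(vunit(fp$normal) *
                                           vunit(fl$normal))))))
      if (dist <= dMax && ang <= angleMax) {
        out <- rbind(out, data.frame(
          protein_residue = residueLabel(pat[rp[1L], , drop = FALSE]),
          centroid_distance_A = dist,
          interplanar_angle_deg = ang,
          stringsAsFactors = FALSE))
      }
    }
  }
  out[order(out$centroid_distance_A), , drop = FALSE]
}

#' Hydrophobic pocket occupancy
#'
#' Counts ligand carbon and halogen atoms within `cutoff` Angstrom of any
#' sidechain atom of the pocket residues, and labels the connected ligand
#' fragment contributing most contacts (e.g. a prenyl chain or a chlorine
#' atom).
#'
#' @param pose a [PoseComplex]
#' @param pocketResidues residue labels lining the pocket (default
#'   `"TRP34"`)
#' @param cutoff contact distance in Angstrom (default 4.5)
#' @return list with `count`, `fragment_label` (empty string when no
#'   contact), `fragment_atoms`
#' @export
pocketOccupancy <- function(pose, pocketResidues = "TRP34", cutoff = 4.5) {
  stopIfNotScalarNumber(cutoff, "cutoff", 0, Inf, strict = TRUE)
  pat <- atomRecords(protein(pose))
  known <- unique(residueLabel(pat))
  badRes <- setdiff(pocketResidues, known)
  if (length(badRes)) {
    stop(sprintf("unknown pocket residue label(s): %s (present: %s)",
                 paste(badRes, collapse = ", "),
                 paste(known, collapse = ", ")), call. = FALSE)
  }
  side <- pat[residueLabel(pat) %in% pocketResidues &
                !pat$name %in% BACKBONE_ATOMS, , drop = FALSE]
  lat <- atomRecords(ligandAtoms(pose))
  apolar <- which(toupper(lat$element) %in% c("C", HALOGENS))
  if (!nrow(side) || !length(apolar)) {
    return(list(count = 0L, fragment_label = "", fragment_atoms = character()))
  }
  d <- pairwiseDistances(as.matrix(lat[apolar, c("x", "y", "z")]),
                         as.matrix(side[, c("x", "y", "z")]))
  contact <- apply(d, 1L, min) <= cutoff
  count <- sum(contact)
  if (count == 0L) {
    return(list(count = 0L, fragment_label = "", fragment_atoms = character()))
  }
  # connected components of the full ligand graph; label the fragment
  # contributing the most contacting atoms
  xyz <- as.matrix(lat[, c("x", "y", "z")])
  adj <- connectivity(xyz)
  comp <- rep(NA_integer_, nrow(lat))
  cid <- 0L
  for (s in seq_len(nrow(lat))) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      a <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(comp[a])) next
      comp[a] <- cid
      queue <- c(queue, which(adj[a, ] & is.na(comp)))
    }
  }
  contactComp <- comp[apolar[contact]]
  bestComp <- as.integer(names(which.max(table(contactComp))))
  fragAtoms <- lat$name[comp == bestComp]
  elems <- toupper(lat$element[comp == bestComp])
  label <- if (length(fragAtoms) == 1L && elems %in% HALOGENS) {
    paste0(substr(elems, 1L, 1L),
           tolower(substr(elems, 2L, nchar(elems))), " atom")
  } else {
    sprintf("C%d fragment", sum(elems == "C"))
  }
  list(count = count, fragment_label = label, fragment_atoms = fragAtoms)
}

#' Assemble a per-pose interaction checklist
#'
#' Combines the flip classification with the hydrogen-bond detectors for
#' Asp35 and Asp153 and the hydrophobic pocket occupancy into one record;
#' `all_key_interactions` is the conjunction flip-in AND both H-bonds AND
#' non-zero pocket fill, the profile shared by the strongest ApoE4
#' stabilizers.
#'
#' @param pose a [PoseComplex]
#' @param flip a [FlipClassification] for the receptor's Trp34
#' @param dMaxHBond H-bond heavy-atom cutoff (default 3.5 Angstrom)
#' @param pocketResidues pocket residue labels (default `"TRP34"`)
#' @param pocketCutoff occupancy contact cutoff (default 4.5 Angstrom)
#' @return one-row data.frame checklist record
#' @export
buildChecklist <- function(pose, flip, dMaxHBond = 3.5,
                           pocketResidues = "TRP34", pocketCutoff = 4.5) {
  stopifnot(is(pose, "PoseComplex"), is(flip, "FlipClassification"))
  hb <- detectHBonds(pose, dMax = dMaxHBond)
  occ <- pocketOccupancy(pose, pocketResidues = pocketResidues,
                         cutoff = pocketCutoff)
  hbond35 <- any(hb$protein_residue == "ASP35")
  hbond153 <- any(hb$protein_residue == "ASP153")
  data.frame(
    ligand_id = pose@poseId,
    trp34_orientation = flipState(flip),
    hbond_asp35 = hbond35,
    hbond_asp153 = hbond153,
    pocket_fill = occ$fragment_label,
    pocket_contacts = occ$count,
    all_key_interactions = flipState(flip) == "flip-in" && hbond35 &&
      hbond153 && occ$count > 0L,
    stringsAsFactors = FALSE)
}

#' Per-interaction persistence fractions over a trajectory
#'
#' @param checklists data.frame of per-frame checklist records (one row
#'   per frame) with logical/numeric interaction columns, e.g. rbind-ed
#'   output of [buildChecklist()]
#' @param columns interaction columns to summarise (default: the logical
#'   H-bond flags, flip-in indicator and non-zero pocket fill)
#' @return list with `fractions` (named, each the mean per-frame
#'   indicator, in [0, 1]) and `n_frames`
#' @export
persistenceProfile <- function(checklists,
                               columns = c("trp34_flip_in", "hbond_asp35",
                                           "hbond_asp153", "pocket_filled")) {
  if (!is.data.frame(checklists) || !nrow(checklists)) {
    stop("need at least one frame of checklist records", call. = FALSE)
  }
  df <- checklists
  if ("trp34_orientation" %in% names(df)) {
    df$trp34_flip_in <- df$trp34_orientation == "flip-in"
  }
  if ("pocket_contacts" %in% names(df)) {
    df$pocket_filled <- df$pocket_contacts > 0
  }
  columns <- intersect(columns, names(df))
  if (!length(columns)) {
    stop("no interaction columns found to summarise", call. = FALSE)
  }
  fr <- vapply(columns, function(cn) mean(as.logical(df[[cn]])), numeric(1L))
  list(fractions = fr, n_frames = nrow(df))
}
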