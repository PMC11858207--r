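# Readers and writers: Vina-style docking logs, censored Kd tables,
# PDB coordinate files (via bio3d), score and interaction tables.

VINA_HEADER <- "mode |   affinity | dist from best mode"
VINA_UNITS <- "     | (kcal/mol) | rmsd l.b.| rmsd u.b."
VINA_SEP <- "-----+------------+----------+----------"

#' Parse a Vina-style docking log
#'
#' Reads the binding-mode table of an AutoDock-Vina-style log (mode index,
#' affinity in kcal/mol, RMSD lower/upper bound to the best mode) and
#' exposes the best affinity.  Inverse of [writeVinaLog()].
#'
#' @param text character vector of log lines, or a single string with
#'   embedded newlines, or a file path
#' @return list with `ligand_id`, `modes` (data.frame mode, affinity,
#'   rmsd_lb, rmsd_ub) and `best_affinity`
#' @export
parseVinaLog <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text)
  } else if (length(text) == 1L) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  }
  sepLine <- which(startsWith(trimws(text), "-----+"))
  if (!length(sepLine)) {
    stop(sprintf("not a Vina log: missing separator line '%s' under the mode table header",
                 VINA_SEP), call. = FALSE)
  }
  sepLine <- sepLine[1L]
  ligand <- NA_character_
  idLine <- grep("^Ligand:", text, value = TRUE)
  if (length(idLine)) ligand <- trimws(sub("^Ligand:", "", idLine[1L]))
  rows <- list()
  for (i in seq(sepLine + 1L, length(text))) {
    line <- trimws(text[i])
    if (!nzchar(line)) break
    fields <- strsplit(line, "\\s+")[[1L]]
    if (length(fields) != 4L || anyNA(suppressWarnings(as.numeric(fields)))) {
      stop(sprintf("garbled mode-table row at line %d: '%s'", i, text[i]),
           call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- as.numeric(fields)
  }
  if (!length(rows)) {
    stop(sprintf("empty mode table after separator at line %d", sepLine),
         call. = FALSE)
  }
  modes <- do.call(rbind, rows)
  modes <- data.frame(mode = as.integer(modes[, 1L]), affinity = modes[, 2L],
                      rmsd_lb = modes[, 3L], rmsd_ub = modes[, 4L])
  if (!identical(modes$mode, seq_len(nrow(modes)))) {
    stop("mode indices must run 1..k consecutively", call. = FALSE)
  }
  if (is.unsorted(modes$affinity)) {
    stop("affinities must be non-decreasing down the mode table",
         call. = FALSE)
  }
  list(ligand_id = ligand, modes = modes,
       best_affinity = modes$affinity[1L])
}

#' Write a Vina-style docking log
#'
#' @param result list as returned by [parseVinaLog()] (fields `ligand_id`,
#'   `modes`)
#' @param file optional path; when `NULL` the lines are returned invisibly
#' @return character vector of log lines, invisibly
#' @export
writeVinaLog <- function(result, file = NULL) {
  modes <- result$modes
  lines <- c(
    if (!is.null(result$ligand_id) && !is.na(result$ligand_id))
      paste0("Ligand: ", result$ligand_id),
    VINA_HEADER, VINA_UNITS, VINA_SEP,
    sprintf("%4d %12.1f %10.3f %10.3f",
            modes$mode, modes$affinity, modes$rmsd_lb, modes$rmsd_ub))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Parse censored dissociation-constant text
#'
#' Accepted forms: `"38"`, `"900 ± 108"` (also `"+/-"`), `"<5"`,
#' `">100"`, `"No binding"`.  Censoring is encoded as an explicit factor,
#' never as a sentinel number, so downstream statistics can see that
#' `"<5"` is a bound rather than a measurement.
#'
#' @param kdText character vector of Kd strings (micromolar)
#' @return data.frame with columns kd_um, censor (none/below/above/
#'   no_binding), uncertainty_um
#' @export
parseKdText <- function(kdText) {
  n <- length(kdText)
  out <- data.frame(kd_um = rep(NA_real_, n),
                    censor = rep("none", n),
                    uncertainty_um = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  bad <- integer()
  for (i in seq_len(n)) {
    s <- trimws(kdText[i])
    if (grepl("^no binding$", s, ignore.case = TRUE)) {
      out$censor[i] <- "no_binding"
    } else if (grepl("^<", s)) {
      v <- suppressWarnings(as.numeric(trimws(sub("^<", "", s))))
      if (is.na(v) || v <= 0) { bad <- c(bad, i); next }
      out$kd_um[i] <- v; out$censor[i] <- "below"
    } else if (grepl("^>", s)) {
      v <- suppressWarnings(as.numeric(trimws(sub("^>", "", s))))
      if (is.na(v) || v <= 0) { bad <- c(bad, i); next }
      out$kd_um[i] <- v; out$censor[i] <- "above"
    } else {
      parts <- strsplit(s, "±|\\+/-")[[1L]]
      v <- suppressWarnings(as.numeric(trimws(parts[1L])))
      if (is.na(v) || v <= 0) { bad <- c(bad, i); next }
      out$kd_um[i] <- v
      if (length(parts) > 1L) {
        u <- suppressWarnings(as.numeric(trimws(parts[2L])))
        if (is.na(u)) { bad <- c(bad, i); next }
        out$uncertainty_um[i] <- u
      }
    }
  }
  if (length(bad)) {
    stop(sprintf("unparseable Kd text in row(s) %s: %s",
                 paste(bad, collapse = ", "),
                 paste(sprintf("'%s'", kdText[bad]), collapse = ", ")),
         call. = FALSE)
  }
  out
}

#' Read a Kd table with censoring marks
#'
#' @param file TSV/CSV path with a header containing `ligand_id` and
#'   `kd_text` (any further columns, e.g. `protein`, are carried through)
#' @param sep field separator (default tab)
#' @return data.frame of Kd records: input columns plus kd_um, censor,
#'   uncertainty_um
#' @export
readKdTable <- function(file, sep = "\t") {
  tab <- read.delim(file, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
  need <- c("ligand_id", "kd_text")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop(sprintf("Kd table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (!nrow(tab)) stop("no data rows in Kd table", call. = FALSE)
  cbind(tab, parseKdText(tab$kd_text))
}

#' Read a PDB file into a Structure
#'
#' Fixed-column ATOM/HETATM parsing is delegated to [bio3d::read.pdb];
#' alternate locations other than blank or 'A' are dropped with a warning
#' reporting the count (the common crystallographic convention).
#'
#' @param file path to a PDB file
#' @param sourceId provenance identifier (default: file name)
#' @return a [Structure]
#' @export
readPDB <- function(file, sourceId = sub("\\.pdb$", "", basename(file))) {
  pdb <- bio3d::read.pdb(file, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  if (any(!keep)) {
    warning(sprintf("dropped %d atom(s) with altloc other than blank/'A'",
                    sum(!keep)), call. = FALSE)
    at <- at[keep, , drop = FALSE]
  }
  atoms <- data.frame(
    serial = at$eleno,
    name = at$elety,
    altloc = ifelse(is.na(at$alt), "", at$alt),
    resname = at$resid,
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    x = at$x, y = at$y, z = at$z,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     substr(trimws(at$elety), 1L, 1L), trimws(at$elesy)),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE)
  Structure(atoms, sourceId = sourceId)
}

#' Write a Structure to a PDB file
#'
#' @param structure a [Structure]
#' @param file output path
#' @return `file`, invisibly
#' @export
writePDB <- function(structure, file) {
  at <- atomRecords(structure)
  het <- if ("het" %in% names(at)) at$het else rep(FALSE, nrow(at))
  bio3d::write.pdb(
    file = file,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    type = ifelse(het, "HETATM", "ATOM"),
    resno = at$resno, resid = at$resname, eleno = at$serial,
    elety = at$name, chain = ifelse(at$chain == "", " ", at$chain),
    alt = ifelse(at$altloc == "", NA, at$altloc),
    o = rep(1, nrow(at)), b = rep(0, nrow(at)),
    elesy = at$element)
  invisible(file)
}

#' Read a wide score/rank table into a ScoreMatrix
#'
#' Expects a header row with `ligand_id` followed by one column per
#' structure id (the Kd column, if present as `kd_text`, is ignored here
#' and read by [readKdTable()]).  Missing cells stay `NA`: they are
#' flagged by downstream consumers, never imputed.
#'
#' @param file TSV/CSV path
#' @param categories named character vector mapping structure ids to
#'   `"apoE3"` / `"free-apoE4"` / `"holo-apoE4"`
#' @param valueKind `"rank"` or `"score"`
#' @param sep field separator (default tab)
#' @return a [ScoreMatrix]
#' @export
readScoreTable <- function(file, categories, valueKind = c("rank", "score"),
                           sep = "\t") {
  valueKind <- match.arg(valueKind)
  tab <- read.delim(file, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!"ligand_id" %in% names(tab)) {
    stop("score table must have a 'ligand_id' column", call. = FALSE)
  }
  if (!nrow(tab)) stop("no data rows in score table", call. = FALSE)
  structCols <- setdiff(names(tab), c("ligand_id", "kd_text"))
  if (!length(structCols)) {
    stop("score table has no structure columns", call. = FALSE)
  }
  m <- as.matrix(tab[, structCols, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab$ligand_id)
  ScoreMatrix(m, categories = categories, valueKind = valueKind)
}

#' Write a ScoreMatrix as a wide TSV
#'
#' @param x a [ScoreMatrix]
#' @param file output path
#' @return `file`, invisibly
#' @export
writeScoreTable <- function(x, file) {
  tab <- data.frame(ligand_id = ligandIds(x), scoreValues(x),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read an interaction checklist table
#'
#' Expects columns `ligand_id`, `trp34_orientation` (Flip-in/Flip-out),
#' `asp35_interaction`, `asp153_interaction` (H-bond or a dash string for
#' absent) and `pocket_fill` (occupying group label, empty when none).
#'
#' @param file TSV path
#' @param sep field separator
#' @return data.frame of checklist records with logical columns
#'   hbond_asp35, hbond_asp153, pocket filled flag and the
#'   all_key_interactions conjunction
#' @export
readInteractionTable <- function(file, sep = "\t") {
  tab <- read.delim(file, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
  need <- c("ligand_id", "trp34_orientation", "asp35_interaction",
            "asp153_interaction", "pocket_fill")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop(sprintf("interaction table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (!nrow(tab)) stop("no data rows in interaction table", call. = FALSE)
  ori <- tolower(trimws(tab$trp34_orientation))
  bad <- which(!ori %in% c("flip-in", "flip-out"))
  if (length(bad)) {
    stop(sprintf("unknown trp34_orientation in row(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  isHbond <- function(s) grepl("h-?bond", s, ignore.case = TRUE)
  noFill <- function(s) {
    s <- trimws(s)
    !nzchar(s) | grepl("^[-–—]+$", s)
  }
  out <- data.frame(
    ligand_id = as.character(tab$ligand_id),
    trp34_orientation = ori,
    hbond_asp35 = isHbond(tab$asp35_interaction),
    hbond_asp153 = isHbond(tab$asp153_interaction),
    pocket_fill = trimws(tab$pocket_fill),
    pocket_filled = !noFill(tab$pocket_fill),
    stringsAsFactors = FALSE)
  out$all_key_interactions <- out$trp34_orientation == "flip-in" &
    out$hbond_asp35 & out$hbond_asp153 & out$pocket_filled
  out
}
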