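# Ensemble consensus ranking, Kd diagnostics, enrichment, hit-list algebra.

#' Rank docking scores within one structure column
#'
#' Average ranks for ties; rank 1 is the best value under the stated
#' direction (most negative score for `lower_better`, the docking-score
#' convention).
#'
#' @param values numeric vector of finite scores
#' @param direction `"lower_better"` (docking scores) or `"higher_better"`
#'   (similarity scores)
#' @return numeric vector of ranks
#' @examples
#' rankScores(c(-9.1, -8.5, -9.1))  # 1.5 3 1.5
#' @export
rankScores <- function(values, direction = c("lower_better", "higher_better")) {
  direction <- match.arg(direction)
  if (!length(values)) stop("need at least one value", call. = FALSE)
  if (!all(is.finite(values))) {
    stop("non-finite values cannot be ranked", call. = FALSE)
  }
  if (direction == "lower_better") rank(values) else rank(-values)
}

#' Ensemble consensus score: mean holo rank over mean free rank
#'
#' The consensus score of a ligand is its average docking rank against the
#' holo (stabilizer-bound) ApoE4 structures divided by its average rank
#' against the free ApoE4 structures.  Strong candidates rank well where
#' the pocket is open (holo, flip-in Trp34) and poorly where it is closed
#' (free, flip-out), so lower is better; the score is dimensionless and
#' invariant under uniform positive rescaling of all ranks.
#'
#' @param holoRanks positive ranks against the holo-ApoE4 structures
#' @param freeRanks positive ranks against the free-ApoE4 structures
#' @return consensus score (dimensionless, lower = better)
#' @examples
#' consensusScore(c(61, 25), c(519, 505))  # 43/512
#' @export
consensusScore <- function(holoRanks, freeRanks) {
  if (!length(holoRanks) || !length(freeRanks)) {
    stop("need at least one holo and one free rank", call. = FALSE)
  }
  if (any(!is.finite(holoRanks)) || any(!is.finite(freeRanks)) ||
      any(holoRanks <= 0) || any(freeRanks <= 0)) {
    stop("ranks must be positive finite numbers", call. = FALSE)
  }
  mean(holoRanks) / mean(freeRanks)
}

#' Build the consensus table for a score matrix
#'
#' Scores are converted to per-column ranks when needed, then every ligand
#' receives its average holo-ApoE4 rank, average free-ApoE4 rank, the
#' consensus score (their ratio) and the library-wide consensus rank
#' (ascending score, average ties).
#'
#' @param x a [ScoreMatrix] with at least one `"holo-apoE4"` and one
#'   `"free-apoE4"` column
#' @return data.frame with columns ligand_id, avg_holo_rank,
#'   avg_free_rank, consensus_score, consensus_rank (input ligand order)
#' @export
buildConsensusTable <- function(x) {
  stopifnot(is(x, "ScoreMatrix"))
  cat_ <- structureCategory(x)
  for (need in c("holo-apoE4", "free-apoE4")) {
    if (!any(cat_ == need)) {
      stop(sprintf("score matrix has no '%s' structure column", need),
           call. = FALSE)
    }
  }
  m <- scoreValues(x)
  if (anyNA(m)) {
    stop("score matrix contains missing cells; complete it before ranking",
         call. = FALSE)
  }
  ranks <- if (valueKind(x) == "rank") m else apply(m, 2L, rankScores)
  holo <- ranks[, cat_ == "holo-apoE4", drop = FALSE]
  free <- ranks[, cat_ == "free-apoE4", drop = FALSE]
  score <- rowMeans(holo) / rowMeans(free)
  data.frame(
    ligand_id = ligandIds(x),
    avg_holo_rank = rowMeans(holo),
    avg_free_rank = rowMeans(free),
    consensus_score = score,
    consensus_rank = rank(score),
    row.names = NULL, stringsAsFactors = FALSE)
}

# Numeric Kd under a censoring policy; NA = unusable under the policy.
kdUnderPolicy <- function(kd, policy) {
  v <- kd$kd_um
  v[kd$censor == "no_binding"] <- NA_real_
  if (policy == "drop") {
    v[kd$censor %in% c("below", "above")] <- NA_real_
  } else if (policy == "midpoint") {
    v[kd$censor == "below"] <- kd$kd_um[kd$censor == "below"] / 2
    v[kd$censor == "above"] <- kd$kd_um[kd$censor == "above"] * 2
  }
  # policy "substitute": bounds used at face value, flag retained
  v
}

#' Correlate per-structure ranks and the consensus score with Kd
#'
#' One coefficient per structure column (docking rank vs Kd) plus one for
#' the consensus score.  Positive coefficients mean better docking ranks
#' go with tighter binding.  Censored Kd entries enter according to
#' `kdPolicy`: `"substitute"` uses the bound at face value (flag
#' retained), `"drop"` removes them, `"midpoint"` halves below-bounds and
#' doubles above-bounds; `"No binding"` records never contribute.
#'
#' @param x a [ScoreMatrix]
#' @param kd data.frame of Kd records (`ligand_id`, `kd_um`, `censor`),
#'   e.g. from [readKdTable()]
#' @param method correlation method (default `"spearman"`: rank vs Kd is
#'   an ordinal association)
#' @param kdPolicy censored-Kd policy (see above)
#' @return list with `per_structure` (named coefficients),
#'   `consensus` (coefficient), `method`, `kd_policy`, `n_used`
#' @export
correlationDiagnostics <- function(x, kd,
                                   method = c("spearman", "pearson",
                                              "kendall"),
                                   kdPolicy = c("substitute", "drop",
                                                "midpoint")) {
  method <- match.arg(method)
  kdPolicy <- match.arg(kdPolicy)
  stopifnot(is(x, "ScoreMatrix"))
  kd <- kd[match(ligandIds(x), kd$ligand_id), , drop = FALSE]
  v <- kdUnderPolicy(kd, kdPolicy)
  usable <- which(!is.na(v))
  if (length(usable) < 3L) {
    stop(sprintf("need at least 3 ligands with usable Kd under policy '%s' (have %d)",
                 kdPolicy, length(usable)), call. = FALSE)
  }
  m <- scoreValues(x)
  ranks <- if (valueKind(x) == "rank") m else apply(m, 2L, rankScores)
  perStruct <- apply(ranks[usable, , drop = FALSE], 2L, function(col) {
    cor(col, v[usable], method = method)
  })
  cons <- buildConsensusTable(x)$consensus_score
  consCor <- if (sd(cons[usable]) < .Machine$double.eps) {
    NA_real_  # degenerate: constant consensus score
  } else {
    cor(cons[usable], v[usable], method = method)
  }
  list(per_structure = perStruct,
       consensus = consCor,
       method = method, kd_policy = kdPolicy, n_used = length(usable))
}

#' Enrichment of known actives in the top of the consensus ranking
#'
#' @param entries consensus table from [buildConsensusTable()]
#' @param actives character vector of active ligand ids (must be a subset
#'   of the library)
#' @param topFraction fraction of the library counted as the top list,
#'   in (0, 1]
#' @return list with `top_fraction`, `n_top`, `n_actives_in_top`,
#'   `enrichment_factor` ((actives-in-top / total-actives) / top_fraction)
#'   and `min_fraction_containing_all_actives`
#'   (worst active consensus rank / library size)
#' @export
enrichment <- function(entries, actives, topFraction) {
  stopIfNotScalarNumber(topFraction, "topFraction", 0, 1, strict = FALSE)
  if (topFraction <= 0) {
    stop("'topFraction' must be in (0, 1]", call. = FALSE)
  }
  missing_ <- setdiff(actives, entries$ligand_id)
  if (length(missing_)) {
    stop(sprintf("active ligand(s) not in the library: %s",
                 paste(missing_, collapse = ", ")), call. = FALSE)
  }
  n <- nrow(entries)
  nTop <- floor(topFraction * n + 1e-9)
  activeRanks <- entries$consensus_rank[entries$ligand_id %in% actives]
  nIn <- sum(activeRanks <= nTop)
  list(top_fraction = topFraction,
       n_top = nTop,
       n_actives_in_top = nIn,
       enrichment_factor = (nIn / length(activeRanks)) / topFraction,
       min_fraction_containing_all_actives = max(activeRanks) / n)
}

#' Combine shape-similarity scores from several query ligands
#'
#' Per-ligand combined score is the maximum TanimotoCombo-style similarity
#' over the queries (a single strong query match is preserved), with ties
#' broken by the mean score across queries and then lexicographically by
#' ligand id.  Scores are higher-better.
#'
#' @param tables named list of data.frames, each with columns `ligand_id`
#'   and `score`
#' @param mode `"intersect"` (error unless ligand sets coincide) or
#'   `"union"` (missing scores treated as absent)
#' @return hit-list data.frame (ligand_id, combined_score, per-query
#'   scores), ordered best-first
#' @export
combineShapeQueries <- function(tables, mode = c("intersect", "union")) {
  mode <- match.arg(mode)
  if (!length(tables)) stop("need at least one query table", call. = FALSE)
  tables <- lapply(tables, function(t) {
    if (!all(c("ligand_id", "score") %in% names(t))) {
      stop("each query table needs 'ligand_id' and 'score' columns",
           call. = FALSE)
    }
    t
  })
  ids <- lapply(tables, function(t) as.character(t$ligand_id))
  if (mode == "intersect") {
    common <- Reduce(intersect, ids)
    if (!length(common) || any(lengths(ids) != length(common))) {
      stop("ligand sets differ across queries; use mode = 'union'",
           call. = FALSE)
    }
    all_ids <- sort(common)
  } else {
    all_ids <- sort(Reduce(union, ids))
  }
  scores <- sapply(tables, function(t) {
    t$score[match(all_ids, as.character(t$ligand_id))]
  })
  scores <- matrix(scores, nrow = length(all_ids),
                   dimnames = list(all_ids, names(tables)))
  combined <- apply(scores, 1L, max, na.rm = TRUE)
  meanScore <- rowMeans(scores, na.rm = TRUE)
  ord <- order(-combined, -meanScore, all_ids)
  out <- data.frame(ligand_id = all_ids[ord],
                    combined_score = combined[ord],
                    scores[ord, , drop = FALSE],
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out
}

#' Intersect the top-n entries of two hit lists
#'
#' @param a,b hit lists: data.frames with a `ligand_id` column ordered
#'   best-first, or plain character vectors of ids in rank order
#' @param n how many top entries of each list to intersect
#' @return data.frame of common ligand ids with their positions in each
#'   list, ordered by position sum then id
#' @export
intersectHitLists <- function(a, b, n = 25) {
  idsOf <- function(x) {
    if (is.data.frame(x)) as.character(x$ligand_id) else as.character(x)
  }
  ia <- idsOf(a); ib <- idsOf(b)
  if (n > length(ia) || n > length(ib)) {
    stop(sprintf("n = %d exceeds a hit-list length (%d, %d)",
                 n, length(ia), length(ib)), call. = FALSE)
  }
  topA <- ia[seq_len(n)]; topB <- ib[seq_len(n)]
  common <- intersect(topA, topB)
  if (!length(common)) {
    return(data.frame(ligand_id = character(), pos_a = integer(),
                      pos_b = integer(), stringsAsFactors = FALSE))
  }
  posA <- match(common, topA); posB <- match(common, topB)
  ord <- order(posA + posB, common)
  data.frame(ligand_id = common[ord], pos_a = posA[ord], pos_b = posB[ord],
             stringsAsFactors = FALSE)
}

#' Select ligands binding every requested protein below a Kd threshold
#'
#' A ligand passes for one protein when its Kd record is an uncensored
#' value below the threshold, or a below-bound whose bound does not exceed
#' the threshold.  Above-bounds and `"No binding"` records never pass.
#' The ligand is returned only if it passes for every protein in
#' `proteins`.
#'
#' @param records long-format Kd records: data.frame with `ligand_id`,
#'   `protein`, `kd_um`, `censor`
#' @param thresholdUm Kd activity threshold in micromolar
#' @param proteins proteins that must all be bound (default: every protein
#'   present in `records`)
#' @return character vector of binder ligand ids
#' @export
kdTriage <- function(records, thresholdUm, proteins = NULL) {
  stopIfNotScalarNumber(thresholdUm, "thresholdUm", 0, Inf, strict = TRUE)
  if (!nrow(records)) return(character())
  if (is.null(proteins)) proteins <- unique(records$protein)
  records <- records[records$protein %in% proteins, , drop = FALSE]
  passes <- with(records,
                 (censor == "none" & kd_um < thresholdUm) |
                 (censor == "below" & kd_um <= thresholdUm))
  ok <- vapply(split(seq_len(nrow(records)), records$ligand_id),
               function(idx) {
                 have <- records$protein[idx]
                 all(proteins %in% have) && all(passes[idx])
               }, logical(1L))
  sort(names(ok)[ok])
}
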