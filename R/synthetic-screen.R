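# Seeded synthetic screening campaign: ligand-by-structure docking scores
# with the holo-positive / free-negative coupling pattern, a censored Kd
# table and ground-truth active flags.

SYNTH_STRUCTURES <- c("APOE3-1", "APOE3-2", "FREE4-1", "FREE4-2",
                      "HOLO4-1", "HOLO4-2")
SYNTH_CATEGORIES <- setNames(
  c("apoE3", "apoE3", "free-apoE4", "free-apoE4", "holo-apoE4",
    "holo-apoE4"), SYNTH_STRUCTURES)

#' Specification for a synthetic screening campaign
#'
#' Defaults emulate the screening conditions of the original campaign:
#' a library of about 1000 molecules containing a small panel of genuine
#' binders (actives are ligands with Kd below 30 micromolar, the activity
#' cutoff used for the consensus-enrichment claim), docking scores whose
#' ranks correlate positively with activity on the holo-ApoE4 structures
#' and negatively on the free-ApoE4 structures, and a Kd detection floor
#' of 5 micromolar below which values are reported as censored
#' `"<floor"` strings.
#'
#' @param nDecoys number of inactive library molecules
#' @param nActives number of genuine binders
#' @param holoCoupling rank coupling of holo-ApoE4 scores to latent
#'   activity, in [-1, 1]
#' @param freeCoupling rank coupling of free-ApoE4 scores, in [-1, 1]
#'   (negative: good binders of the open holo pocket dock poorly into the
#'   closed free-ApoE4 pocket)
#' @param kdRangeUm `c(low, high)` Kd range in micromolar spanned by the
#'   library
#' @param detectionFloorUm Kd below which the assay reports `"<floor"`
#' @param noiseSd extra Gaussian score noise (kcal/mol)
#' @param seed integer seed; same spec and seed give bit-identical output
#' @return validated list of class `"ScreenSpec"`
#' @export
screenSpec <- function(nDecoys = 990, nActives = 10, holoCoupling = 0.9,
                       freeCoupling = -0.9, kdRangeUm = c(1, 1000),
                       detectionFloorUm = 5, noiseSd = 0.25, seed = 1L) {
  stopIfNotScalarNumber(nDecoys, "nDecoys", 0, Inf)
  stopIfNotScalarNumber(nActives, "nActives", 0, Inf)
  if (nDecoys + nActives < 2) {
    stop("'nDecoys' + 'nActives' must be at least 2", call. = FALSE)
  }
  stopIfNotScalarNumber(holoCoupling, "holoCoupling", -1, 1)
  stopIfNotScalarNumber(freeCoupling, "freeCoupling", -1, 1)
  if (length(kdRangeUm) != 2L || !all(is.finite(kdRangeUm)) ||
      kdRangeUm[1L] <= 0 || kdRangeUm[1L] >= kdRangeUm[2L]) {
    stop("'kdRangeUm' must be c(low, high) with 0 < low < high",
         call. = FALSE)
  }
  stopIfNotScalarNumber(detectionFloorUm, "detectionFloorUm", 0, Inf,
                        strict = TRUE)
  stopIfNotScalarNumber(noiseSd, "noiseSd", 0, Inf)
  structure(list(nDecoys = as.integer(nDecoys),
                 nActives = as.integer(nActives),
                 holoCoupling = holoCoupling, freeCoupling = freeCoupling,
                 kdRangeUm = as.numeric(kdRangeUm),
                 detectionFloorUm = detectionFloorUm,
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "ScreenSpec")
}

ACTIVITY_CUTOFF_UM <- 30  # Kd below this counts as an active binder

#' Generate a synthetic screening campaign
#'
#' Latent activity is the log10 Kd, drawn uniformly: actives below the 30
#' micromolar activity cutoff, decoys above it, within `kdRangeUm`.  Each
#' structure column's docking score is coupled to the activity through a
#' Gaussian copula (normal scores of the library-wide activity ranks),
#' with coupling `holoCoupling` for the two holo-ApoE4 columns,
#' `freeCoupling` for the two free-ApoE4 columns and 0.75 x holoCoupling
#' for the two apoE3 columns (the apo-E3 pocket resembles the holo pocket
#' but correlates less sharply), plus independent Gaussian noise.  Kd
#' values below the detection floor are emitted as censored `"<floor"`
#' strings.
#'
#' @param spec a [screenSpec()]
#' @return list of class `"SyntheticScreen"` with elements `scores`
#'   (a [ScoreMatrix], valueKind `"score"`), `kd` (data.frame ligand_id,
#'   kd_text plus parsed columns), `active` (named logical ground truth),
#'   `activity` (named latent normal scores) and `spec`
#' @export
genScreen <- function(spec) {
  stopifnot(inherits(spec, "ScreenSpec"))
  n <- spec$nDecoys + spec$nActives
  withSeed(spec$seed, {
    ids <- sprintf("LIG%05d", seq_len(n))
    active <- c(rep(TRUE, spec$nActives), rep(FALSE, spec$nDecoys))
    lo <- log10(spec$kdRangeUm[1L])
    hi <- log10(spec$kdRangeUm[2L])
    split_ <- min(max(log10(ACTIVITY_CUTOFF_UM), lo + 0.05 * (hi - lo)),
                  hi - 0.05 * (hi - lo))
    logKd <- numeric(n)
    logKd[active] <- runif(spec$nActives, lo, split_)
    logKd[!active] <- runif(spec$nDecoys, split_, hi)
    # Gaussian copula: normal scores of the library-wide activity ranks
    z <- qnorm((rank(-logKd) - 0.5) / n)
    couplings <- c(0.75 * spec$holoCoupling, 0.75 * spec$holoCoupling,
                   spec$freeCoupling, spec$freeCoupling,
                   spec$holoCoupling, spec$holoCoupling)
    scores <- vapply(couplings, function(cj) {
      w <- cj * z + sqrt(1 - cj^2) * rnorm(n)
      -7 - 1.5 * w + rnorm(n, 0, spec$noiseSd)
    }, numeric(n))
    dimnames(scores) <- list(ids, SYNTH_STRUCTURES)
    kdUm <- 10^logKd
    kdText <- ifelse(kdUm < spec$detectionFloorUm,
                     paste0("<", format(spec$detectionFloorUm)),
                     formatC(kdUm, digits = 3, format = "g"))
    kd <- data.frame(ligand_id = ids, kd_text = kdText,
                     stringsAsFactors = FALSE)
    kd <- cbind(kd, parseKdText(kd$kd_text))
    structure(list(
      scores = ScoreMatrix(scores, categories = SYNTH_CATEGORIES,
                           valueKind = "score"),
      kd = kd,
      active = setNames(active, ids),
      activity = setNames(z, ids),
      spec = spec), class = "SyntheticScreen")
  })
}

#' @export
print.SyntheticScreen <- function(x, ...) {
  cat(sprintf("SyntheticScreen: %d ligands (%d actives) x %d structures, seed %d\n",
              length(x$active), sum(x$active), ncol(x$scores), x$spec$seed))
  invisible(x)
}
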