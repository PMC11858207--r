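# Two-state Trp sidechain flip trajectory generator.

# chi-angle centers of the two orientation states; the flip-out center
# defines the reference axis, the flip-in center is rotated about chi1 so
# the CB->indole-centroid direction swings roughly perpendicular.
FLIP_OUT_CENTER <- c(chi1 = -60, chi2 = 90)
FLIP_IN_CENTER <- c(chi1 = 150, chi2 = -60)

#' Specification for a synthetic Trp flip trajectory
#'
#' @param nFrames number of frames (>= 1)
#' @param frameIntervalNs time between recorded frames in nanoseconds
#'   (default 0.1, i.e. one frame per 100 ps)
#' @param pStay per-frame persistence probability in (0, 1): with this
#'   probability the chain keeps its current orientation state, otherwise
#'   it redraws from the stationary distribution
#' @param stationaryFlipIn stationary probability of the flip-in state,
#'   in (0, 1)
#' @param noiseSdDeg angular noise around the state's chi centers
#'   (degrees)
#' @param seed integer seed
#' @return validated list of class `"TrajectorySpec"`
#' @export
trajectorySpec <- function(nFrames = 1000, frameIntervalNs = 0.1,
                           pStay = 0.95, stationaryFlipIn = 0.8,
                           noiseSdDeg = 8, seed = 1L) {
  stopIfNotScalarNumber(nFrames, "nFrames", 1, Inf)
  stopIfNotScalarNumber(frameIntervalNs, "frameIntervalNs", 0, Inf,
                        strict = TRUE)
  stopIfNotScalarNumber(pStay, "pStay", 0, 1, strict = TRUE)
  stopIfNotScalarNumber(stationaryFlipIn, "stationaryFlipIn", 0, 1,
                        strict = TRUE)
  stopIfNotScalarNumber(noiseSdDeg, "noiseSdDeg", 0, 45)
  structure(list(nFrames = as.integer(nFrames),
                 frameIntervalNs = frameIntervalNs, pStay = pStay,
                 stationaryFlipIn = stationaryFlipIn,
                 noiseSdDeg = noiseSdDeg, seed = as.integer(seed)),
            class = "TrajectorySpec")
}

wrapAngle <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

#' Generate a two-state Trp sidechain flip trajectory
#'
#' Simulates a two-state Markov chain over the flip-in / flip-out
#' orientations of a tryptophan-like sidechain.  At each step the chain
#' keeps its state with probability `pStay` and otherwise redraws from the
#' stationary Bernoulli(`stationaryFlipIn`) distribution, so the
#' stationary occupancy is exact by construction and `pStay` sets the
#' temporal persistence.  Each state maps to a (chi1, chi2) rotamer
#' center with Gaussian angular noise; per-frame coordinates of an
#' idealized tryptophan residue built at those chi angles can be attached.
#'
#' @param spec a [trajectorySpec()]
#' @param includeCoords also build per-frame residue coordinates
#'   (a list of atom tables); disable for very long chains where only the
#'   dihedral series is needed
#' @return list of class `"FlipTrajectory"`: `series` (data.frame frame,
#'   time_ns, chi1_deg, chi2_deg, state), `frames` (list of atom tables or
#'   `NULL`), `axis` (unit vector: the CB->indole-centroid direction of
#'   the flip-out rotamer center, against which the flip states read
#'   flip-out/flip-in) and `spec`
#' @export
genFlipTrajectory <- function(spec, includeCoords = TRUE) {
  stopifnot(inherits(spec, "TrajectorySpec"))
  n <- spec$nFrames
  withSeed(spec$seed, {
    keep <- runif(n) < spec$pStay
    redraw <- runif(n) < spec$stationaryFlipIn
    state <- logical(n)  # TRUE = flip-in
    state[1L] <- redraw[1L]
    for (t_ in seq_len(n)[-1L]) {
      state[t_] <- if (keep[t_]) state[t_ - 1L] else redraw[t_]
    }
    centers1 <- ifelse(state, FLIP_IN_CENTER["chi1"], FLIP_OUT_CENTER["chi1"])
    centers2 <- ifelse(state, FLIP_IN_CENTER["chi2"], FLIP_OUT_CENTER["chi2"])
    chi1 <- wrapAngle(centers1 + rnorm(n, 0, spec$noiseSdDeg))
    chi2 <- wrapAngle(centers2 + rnorm(n, 0, spec$noiseSdDeg))
    series <- data.frame(
      frame = seq_len(n),
      time_ns = (seq_len(n) - 1L) * spec$frameIntervalNs,
      chi1_deg = chi1, chi2_deg = chi2,
      state = ifelse(state, "flip-in", "flip-out"),
      stringsAsFactors = FALSE)
    frames <- NULL
    if (includeCoords) {
      frames <- lapply(seq_len(n), function(i) {
        buildTrpResidue(chi1 = chi1[i], chi2 = chi2[i])
      })
    }
    structure(list(series = series, frames = frames,
                   axis = flipReferenceAxis(), spec = spec),
              class = "FlipTrajectory")
  })
}

# CB -> indole-centroid unit vector of the flip-out rotamer center.
flipReferenceAxis <- function() {
  trp <- buildTrpResidue(chi1 = FLIP_OUT_CENTER["chi1"],
                         chi2 = FLIP_OUT_CENTER["chi2"])
  cb <- as.numeric(trp[trp$name == "CB", c("x", "y", "z")])
  ring <- as.matrix(trp[trp$name %in% INDOLE_RING_ATOMS, c("x", "y", "z")])
  vunit(colMeans(ring) - cb)
}

#' @export
print.FlipTrajectory <- function(x, ...) {
  cat(sprintf("FlipTrajectory: %d frames at %g ns, flip-in fraction %.3f\n",
              nrow(x$series), x$spec$frameIntervalNs,
              mean(x$series$state == "flip-in")))
  invisible(x)
}
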