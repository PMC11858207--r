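# Shared helpers: independent geometry oracles and small random fixtures.

# Independent torsion oracle: projects the outer bonds onto the plane
# orthogonal to the central bond and takes the signed angle between the
# projections (a formulation distinct from the triple-product atan2 in
# the implementation).
dihedralOracle <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  u <- b2 / sqrt(sum(b2^2))
  proj <- function(v) v - sum(v * u) * u
  a <- proj(p1 - p2)
  b <- proj(p4 - p3)
  cosang <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  cosang <- max(-1, min(1, cosang))
  ang <- acos(cosang) * 180 / pi
  cr <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  if (sum(cr * u) < 0) ang <- -ang
  ang
}

rotationMatrix <- function(axis, angleDeg) {
  axis <- axis / sqrt(sum(axis^2))
  a <- angleDeg * pi / 180
  k <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(a) * k + (1 - cos(a)) * k %*% k
}

randomRigidMotion <- function() {
  ax <- rnorm(3)
  list(rotation = rotationMatrix(ax, runif(1, 0, 360)),
       translation = rnorm(3, 0, 10))
}

# A reference two-H-bond, filled-pocket pose used across detector tests.
fullInteractionPose <- function() {
  buildPoseComplex(poseSpec(
    hbondRequests = list(c("ASP35", 2.9), c("ASP153", 3.0)),
    occupancyRequest = 3, seed = 1L))
}

expectedConsensusOrder <- c("155557185", "155563897", "155511476",
                            "155552638", "155538646", "137796780",
                            "83673143", "155530661")

rmsdRaw <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# Brute-force superposition oracle: coarse Euler-angle grid followed by a
# local simplex refinement, centroids pre-aligned.
gridSearchRmsd <- function(ref, mob, coarseDeg = 20) {
  a <- sweep(mob, 2, colMeans(mob))
  b <- sweep(ref, 2, colMeans(ref))
  eulerRot <- function(p) {
    rotationMatrix(c(0, 0, 1), p[1]) %*%
      rotationMatrix(c(0, 1, 0), p[2]) %*%
      rotationMatrix(c(1, 0, 0), p[3])
  }
  obj <- function(p) {
    r <- eulerRot(p)
    sqrt(mean(rowSums((a %*% t(r) - b)^2)))
  }
  grid <- seq(0, 360 - coarseDeg, by = coarseDeg)
  best <- NULL
  for (e1 in grid) for (e2 in grid) for (e3 in grid) {
    v <- obj(c(e1, e2, e3))
    if (is.null(best) || v < best$v) best <- list(p = c(e1, e2, e3), v = v)
  }
  opt <- optim(best$p, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}
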