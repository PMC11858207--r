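# Internal numeric / RNG helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring global state
#'
#' All generators in the package route their randomness through this helper
#' so that calls are pure functions of their spec (seed included) and never
#' perturb the caller's random stream.
#'
#' @param seed single integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
#' @noRd
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != round(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalise a zero-length vector", call. = FALSE)
  a / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Place an atom from internal coordinates (bond, angle, torsion)
#'
#' Natural-extension reference frame placement: returns the position `d`
#' such that |c-d| = bond, angle(b,c,d) = `angle` degrees and the torsion
#' a-b-c-d equals `torsion` degrees under the same sign convention as
#' [dihedral()].
#'
#' @keywords internal
#' @noRd
placeAtom <- function(a, b, c, bond, angle, torsion) {
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

#' Random proper rotation matrix (uniform over SO(3))
#' @keywords internal
#' @noRd
randomRotation <- function() {
  m <- matrix(stats::rnorm(9L), 3L, 3L)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  d <- diag(qr.R(qr_))
  q <- q %*% diag(sign(d))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# Rotation matrix taking unit vector u onto unit vector v.
rotationBetween <- function(u, v) {
  u <- vunit(u); v <- vunit(v)
  w <- vcross(u, v)
  s <- vnorm(w)
  cth <- sum(u * v)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3L))
    # antiparallel: rotate 180 deg about any axis orthogonal to u
    axis <- vunit(vcross(u, if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
    k <- matrix(c(0, axis[3L], -axis[2L],
                  -axis[3L], 0, axis[1L],
                  axis[2L], -axis[1L], 0), 3L, 3L)
    return(diag(3L) + 2 * k %*% k)
  }
  k <- matrix(c(0, w[3L], -w[2L],
                -w[3L], 0, w[1L],
                w[2L], -w[1L], 0), 3L, 3L)
  diag(3L) + k + k %*% k * ((1 - cth) / s^2)
}

stopIfNotScalarNumber <- function(x, name, lower = -Inf, upper = Inf,
                                  strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  ok <- if (strict) (x > lower && x < upper) else (x >= lower && x <= upper)
  if (!ok) {
    stop(sprintf("'%s' = %g is outside its valid range %s%g, %g%s",
                 name, x,
                 if (strict) "(" else "[", lower, upper,
                 if (strict) ")" else "]"),
         call. = FALSE)
  }
  invisible(x)
}
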