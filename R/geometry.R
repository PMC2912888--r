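## Small 3-vector helpers. All angles in degrees unless noted.

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Dihedral angle defined by four points
#'
#' Signed torsion angle a-b-c-d using the IUPAC convention (cis = 0, range
#' (-180, 180]).
#'
#' @param a,b,c,d numeric 3-vectors (coordinates in Angstrom).
#' @return angle in degrees.
#' @keywords internal
dihedral_angle <- function(a, b, c, d) {
  b0 <- a - b
  b1 <- vunit(c - b)
  b2 <- d - c
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(vcross(b1, v) * w)
  rad2deg(atan2(y, x))
}

bond_angle <- function(a, b, c) {
  v1 <- vunit(a - b)
  v2 <- vunit(c - b)
  rad2deg(acos(max(-1, min(1, sum(v1 * v2)))))
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Given three reference positions a-b-c, places atom d so that |c-d| =
#' `length`, angle b-c-d = `angle` and dihedral a-b-c-d = `dihedral`.
#'
#' @param a,b,c numeric 3-vectors.
#' @param length bond length c-d in Angstrom.
#' @param angle bond angle b-c-d in degrees.
#' @param dihedral torsion a-b-c-d in degrees.
#' @return coordinates of d.
#' @keywords internal
place_atom <- function(a, b, c, length, angle, dihedral) {
  theta <- deg2rad(angle)
  chi <- deg2rad(dihedral)
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- length * c(-cos(theta), sin(theta) * cos(chi), sin(theta) * sin(chi))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

## Wrap an angular difference into (-180, 180].
angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

## Seed-scoped RNG: runs `expr` under a fixed seed and restores the caller's
## RNG state afterwards, so package randomness never perturbs user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  force(expr)
}
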