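#' Angle geometry on the torus
#'
#' Backbone dihedral angles live on a torus: \eqn{\phi = -179°} and
#' \eqn{\phi = 181°} are the same conformation. All arithmetic in this
#' package therefore goes through the 4-dimensional trigonometric embedding
#' \eqn{v = (\cos\phi, \sin\phi, \cos\psi, \sin\psi)} or through the
#' periodicity-corrected difference \code{angular_difference()}.
#'
#' Angles are degrees in the half-open interval \[-180, 180); +180 is
#' canonicalised to -180. An undefined dihedral (phi at the N-terminus,
#' psi at the C-terminus) is carried as `NA`.
#'
#' @name angle-geometry
NULL

DEG2RAD <- pi / 180

#' Wrap angles into the canonical interval
#'
#' @param theta numeric vector of angles in degrees (NA allowed).
#' @return angles wrapped into \[-180, 180).
#' @examples
#' wrap_angle(c(180, 360, -540, 25))
#' @export
wrap_angle <- function(theta) {
  ((theta + 180) %% 360) - 180
}

#' Convert dihedral angle pairs to trigonometric 4-vectors
#'
#' @param phi,psi numeric vectors of angles in degrees; must be defined
#'   (non-`NA`) and of equal length.
#' @return a numeric matrix with columns `v0 = cos(phi)`, `v1 = sin(phi)`,
#'   `v2 = cos(psi)`, `v3 = sin(psi)`.
#' @examples
#' to_vector(-60, -45)
#' @export
to_vector <- function(phi, psi) {
  if (length(phi) != length(psi)) {
    stop("`phi` and `psi` must have equal length", call. = FALSE)
  }
  if (anyNA(phi) || anyNA(psi)) {
    stop("undefined angle: `to_vector()` requires both angles defined",
         call. = FALSE)
  }
  pr <- phi * DEG2RAD
  sr <- psi * DEG2RAD
  out <- cbind(cos(pr), sin(pr), cos(sr), sin(sr))
  dimnames(out) <- list(NULL, c("v0", "v1", "v2", "v3"))
  out
}

#' Recover dihedral angles from trigonometric 4-vectors
#'
#' The inverse of [to_vector()]: \eqn{\phi = \mathrm{atan2}(v_1, v_0)} and
#' \eqn{\psi = \mathrm{atan2}(v_3, v_2)}, mapped to degrees in \[-180, 180).
#'
#' @param v numeric matrix (or length-4 vector) of `(v0, v1, v2, v3)` rows;
#'   each `(v0, v1)` and `(v2, v3)` pair must have unit norm within `tol`.
#' @param tol unit-norm tolerance (default `1e-6`).
#' @return a tibble with columns `phi`, `psi` in degrees.
#' @export
to_angles <- function(v, tol = 1e-6) {
  v <- vec_as_matrix(v)
  n1 <- sqrt(v[, 1]^2 + v[, 2]^2)
  n2 <- sqrt(v[, 3]^2 + v[, 4]^2)
  if (any(abs(n1 - 1) > tol) || any(abs(n2 - 1) > tol)) {
    stop("non-unit (cos, sin) pair: normalize with `normalize_pairs()` first",
         call. = FALSE)
  }
  tibble::tibble(
    phi = wrap_angle(atan2(unname(v[, 2]), unname(v[, 1])) / DEG2RAD),
    psi = wrap_angle(atan2(unname(v[, 4]), unname(v[, 3])) / DEG2RAD)
  )
}

#' Renormalize raw 4-vectors into valid angle vectors
#'
#' Divides each `(v0, v1)` and `(v2, v3)` pair by its Euclidean norm, so the
#' result encodes an actual angle pair. Raw k-means centers and
#' probability-weighted center mixtures are not unit vectors; this is the
#' pairwise renormalization applied to both.
#'
#' @param v numeric matrix (or length-4 vector) of raw `(v0, v1, v2, v3)`
#'   rows.
#' @param min_norm pairs with norm below this are degenerate (default
#'   `1e-8`).
#' @return a matrix of the same shape satisfying the unit-pair invariant.
#' @export
normalize_pairs <- function(v, min_norm = 1e-8) {
  v <- vec_as_matrix(v)
  n1 <- sqrt(v[, 1]^2 + v[, 2]^2)
  n2 <- sqrt(v[, 3]^2 + v[, 4]^2)
  if (any(n1 < min_norm) || any(n2 < min_norm)) {
    stop("degenerate vector: (cos, sin) pair norm below ", min_norm,
         call. = FALSE)
  }
  out <- cbind(v[, 1] / n1, v[, 2] / n1, v[, 3] / n2, v[, 4] / n2)
  dimnames(out) <- list(NULL, c("v0", "v1", "v2", "v3"))
  out
}

#' Periodicity-corrected absolute angular difference
#'
#' The distance between two angles on the circle: the smaller of
#' \eqn{d = |a - b| \bmod 360} and \eqn{360 - d}. The difference between
#' -179 and 179 is 2 degrees, not 358.
#'
#' @param a,b numeric vectors of angles in degrees (recycled).
#' @return absolute differences in degrees, in \[0, 180\].
#' @examples
#' angular_difference(-179, 179)  # 2
#' @export
angular_difference <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# Accept a length-4 vector or an n x 4 matrix.
vec_as_matrix <- function(v) {
  if (is.null(dim(v))) {
    if (length(v) != 4L) stop("expected 4 components", call. = FALSE)
    v <- matrix(v, nrow = 1L)
  }
  if (ncol(v) != 4L) stop("expected 4 columns", call. = FALSE)
  v
}

#' Circular mean and periodic variance of an angle sample
#'
#' The mean is the direction of the summed unit vectors,
#' \eqn{\mathrm{atan2}(\sum\sin\theta_i, \sum\cos\theta_i)}; the variance is
#' the mean squared periodic deviation about that mean, in squared degrees,
#' so it is directly comparable to a mean absolute error in degrees.
#'
#' @param theta numeric vector of angles in degrees; `NA` dropped.
#' @return a list with `mean` (degrees in \[-180, 180)), `var` (degrees
#'   squared) and `rbar` (mean resultant length in \[0, 1\]).
#' @export
circular_summary <- function(theta) {
  theta <- theta[!is.na(theta)]
  if (length(theta) == 0L) {
    stop("empty angle sample", call. = FALSE)
  }
  tr <- theta * DEG2RAD
  s <- mean(sin(tr))
  c <- mean(cos(tr))
  m <- wrap_angle(atan2(s, c) / DEG2RAD)
  list(
    mean = m,
    var = mean(angular_difference(theta, m)^2),
    rbar = sqrt(s^2 + c^2)
  )
}
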