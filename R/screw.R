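#' Screw (rigid) transform with axis/angle/axial-shift decomposition
#'
#' A screw transform is a proper rigid motion: rotation by some angle about
#' an axis in space plus a translation along that axis. Screw transforms are
#' the generators of helical lattices, and extracting the screw parameters
#' relating two subunits of a filament recovers its helical twist and rise.
#'
#' @param rotation 3x3 orthonormal rotation matrix, det +1 (checked to 1e-8).
#' @param translation Length-3 translation vector (Angstrom).
#' @return An object of class `"screw_transform"`: a list with `rotation`,
#'   `translation` and the decomposition fields `axis` (unit vector),
#'   `axis_point` (a point on the screw axis), `angle_deg`, `axial_shift_A`
#'   and `degenerate` (flag set for near-identity or pure-translation input,
#'   where the axis is not uniquely defined).
#' @seealso [screw_decompose()] for the decomposition itself.
#' @export
screw_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be proper (det +1)")
  dec <- screw_decompose(rotation, translation)
  structure(c(list(rotation = rotation, translation = translation), dec),
            class = "screw_transform")
}

#' @export
print.screw_transform <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat(sprintf("Screw transform (degenerate: %s)\n", x$degenerate_reason))
  } else {
    cat(sprintf(
      "Screw transform: %.4g deg about axis (%.3f, %.3f, %.3f), shift %.4g A\n",
      x$angle_deg, x$axis[1], x$axis[2], x$axis[3], x$axial_shift_A))
  }
  invisible(x)
}

#' Apply a screw transform to coordinates
#'
#' @param tr A [screw_transform()].
#' @param xyz A length-3 vector or an n x 3 coordinate matrix.
#' @return Transformed coordinates of the same shape.
#' @export
apply_screw <- function(tr, xyz) {
  stopifnot(inherits(tr, "screw_transform"))
  if (is.null(dim(xyz))) {
    as.numeric(tr$rotation %*% xyz + tr$translation)
  } else {
    sweep(xyz %*% t(tr$rotation), 2, -tr$translation)
  }
}

#' Compose two screw transforms
#'
#' `compose_screw(a, b)` returns the transform equivalent to applying `b`
#' first and `a` second.
#'
#' @param a,b [screw_transform()] objects.
#' @return A [screw_transform()].
#' @export
compose_screw <- function(a, b) {
  stopifnot(inherits(a, "screw_transform"), inherits(b, "screw_transform"))
  screw_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Decompose a rigid transform into screw parameters
#'
#' Any proper rigid motion is a rotation by `angle_deg` about an axis through
#' `axis_point` in direction `axis`, plus a translation `axial_shift_A` along
#' that axis (Chasles' theorem). Degenerate cases are flagged explicitly:
#' a (near-)identity rotation has no unique axis; for a pure translation the
#' axis is taken parallel to the translation and flagged; the identity with
#' zero translation is flagged fully degenerate.
#'
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation Length-3 vector.
#' @param angle_tol_deg Below this rotation angle the transform is treated as
#'   rotation-free (default 1e-4 degrees, safely below any meaningful helical
#'   twist while absorbing numerical noise in superpositions of identical
#'   chains).
#' @return A list: `axis`, `axis_point`, `angle_deg`, `axial_shift_A`,
#'   `degenerate` (logical), `degenerate_reason` (NULL or character).
#' @export
screw_decompose <- function(rotation, translation, angle_tol_deg = 1e-4) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be proper orthonormal")
  tr <- sum(diag(rotation))
  ang <- acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
  if (ang < angle_tol_deg) {
    # no rotation: pure translation (axis parallel to t) or full identity
    tn <- sqrt(sum(translation^2))
    if (tn < 1e-12) {
      return(list(axis = c(0, 0, 1), axis_point = c(0, 0, 0), angle_deg = 0,
                  axial_shift_A = 0, degenerate = TRUE,
                  degenerate_reason = "identity transform"))
    }
    return(list(axis = translation / tn, axis_point = c(0, 0, 0), angle_deg = 0,
                axial_shift_A = tn, degenerate = TRUE,
                degenerate_reason = "pure translation (no rotation)"))
  }
  # axis from the skew-symmetric part; near 180 deg use the symmetric part
  if (ang < 179) {
    v <- c(rotation[3, 2] - rotation[2, 3],
           rotation[1, 3] - rotation[3, 1],
           rotation[2, 1] - rotation[1, 2])
    axis <- v / sqrt(sum(v^2))
  } else {
    m <- (rotation + diag(3)) / 2
    k <- which.max(diag(m))
    axis <- m[, k] / sqrt(m[k, k])
    axis <- axis / sqrt(sum(axis^2))
  }
  shift <- sum(translation * axis)
  # axis point: solve (I - R) p = t_perp in the plane perpendicular to axis
  t_perp <- translation - shift * axis
  a_mat <- diag(3) - rotation
  # least-squares solution constrained to the perpendicular plane
  p <- tryCatch({
    sv <- svd(a_mat)
    keep <- sv$d > 1e-10
    as.numeric(sv$v[, keep, drop = FALSE] %*%
                 ((t(sv$u[, keep, drop = FALSE]) %*% t_perp) / sv$d[keep]))
  }, error = function(e) c(0, 0, 0))
  list(axis = axis, axis_point = p, angle_deg = ang, axial_shift_A = shift,
       degenerate = FALSE, degenerate_reason = NULL)
}

#' Recompose a screw decomposition into (rotation, translation)
#'
#' Inverse of [screw_decompose()]: builds the rigid transform performing a
#' right-handed rotation by `angle_deg` about the axis through `axis_point`
#' in direction `axis`, plus `axial_shift_A` along the axis.
#'
#' @param axis Unit axis direction.
#' @param angle_deg Rotation angle (degrees).
#' @param axial_shift_A Translation along the axis (Angstrom).
#' @param axis_point A point on the axis.
#' @return A list with `rotation` and `translation`.
#' @export
screw_compose_axis <- function(axis, angle_deg, axial_shift_A,
                               axis_point = c(0, 0, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  t <- angle_deg * pi / 180
  k <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  rot <- diag(3) + sin(t) * k + (1 - cos(t)) * (k %*% k)
  trans <- axial_shift_A * axis + as.numeric((diag(3) - rot) %*% axis_point)
  list(rotation = rot, translation = trans)
}
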