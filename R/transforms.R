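#' Rigid-body transform
#'
#' A proper rigid transform in three dimensions: \code{x -> R x + t} with a
#' rotation matrix \code{R} (orthonormal, determinant +1) and a translation
#' vector \code{t} in Angstrom. Carrier for helical symmetry operators and
#' superposition results.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation numeric length-3 translation vector (Angstrom).
#' @param tol orthonormality tolerance for validation.
#' @return An object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0), tol = 1e-9) {
  rotation <- unname(as.matrix(rotation))
  translation <- unname(as.numeric(translation))
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > tol)
    stop("rotation matrix is not orthonormal within tolerance ", tol)
  if (det(rotation) < 0)
    stop("rotation matrix is a reflection (det < 0); proper rotations only")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Identity transform
#' @return A \code{rigid_transform} that leaves coordinates unchanged.
#' @export
rt_identity <- function() rigid_transform(diag(3), c(0, 0, 0))

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying \code{b} first, then \code{a}:
#' \code{(a \%then\% b)(x) = a(b(x))}.
#'
#' @param a,b \code{rigid_transform} objects.
#' @return A \code{rigid_transform}.
#' @export
rt_compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation,
                  tol = 1e-6)
}

#' Invert a rigid transform
#' @param x a \code{rigid_transform}.
#' @return The inverse \code{rigid_transform}.
#' @export
rt_invert <- function(x) {
  stopifnot(inherits(x, "rigid_transform"))
  rigid_transform(t(x$rotation), as.numeric(-t(x$rotation) %*% x$translation),
                  tol = 1e-6)
}

#' Apply a rigid transform to coordinates
#'
#' @param x a \code{rigid_transform}.
#' @param coords numeric matrix with 3 columns (one row per atom), or a
#'   length-3 vector.
#' @return Transformed coordinates with the same shape as the input.
#' @export
apply_transform <- function(x, coords) {
  stopifnot(inherits(x, "rigid_transform"))
  if (is.null(dim(coords))) {
    stopifnot(length(coords) == 3L)
    return(as.numeric(x$rotation %*% coords) + x$translation)
  }
  stopifnot(ncol(coords) == 3L)
  sweep(coords %*% t(x$rotation), 2L, x$translation, "+")
}

#' Rotation matrix about the z axis
#' @param angle_deg rotation angle in degrees (right-handed about +z).
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_z <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), -sin(a), 0,
           sin(a),  cos(a), 0,
           0,       0,      1), 3, 3, byrow = TRUE)
}

#' Decompose a rigid transform as a screw motion
#'
#' Extracts the rotation angle, rotation axis, and axial translation of a
#' rigid transform interpreted as a screw motion. The axis direction is
#' chosen so that the axial translation component is non-negative; the
#' rotation angle is signed about that axis.
#'
#' @param x a \code{rigid_transform}.
#' @return list with \code{angle_deg}, \code{axis} (unit vector), and
#'   \code{axial_translation} (component of the translation along the axis).
#' @export
screw_decompose <- function(x) {
  stopifnot(inherits(x, "rigid_transform"))
  R <- x$rotation
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  ang <- acos(ct)
  if (abs(sin(ang)) > 1e-8) {
    axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
      (2 * sin(ang))
  } else if (ct > 0) {
    # near-identity rotation: axis ill-defined, use translation direction
    axis <- x$translation
    if (sum(axis^2) < 1e-20) axis <- c(0, 0, 1)
    axis <- axis / sqrt(sum(axis^2))
  } else {
    # 180 degree rotation: axis from R + I columns
    M <- R + diag(3)
    axis <- M[, which.max(colSums(M^2))]
    axis <- axis / sqrt(sum(axis^2))
  }
  rise <- sum(axis * x$translation)
  if (rise < 0) {
    axis <- -axis
    ang <- -ang
    rise <- -rise
  }
  list(angle_deg = ang * 180 / pi, axis = axis, axial_translation = rise)
}
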