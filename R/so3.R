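#' Rotation-group primitives
#'
#' All orientation computations in headkin are carried out directly on 3x3
#' rotation matrices (elements of SO(3)); Euler angles are used for display
#' only. Matrices act on column vectors: a head-pose rotation maps head-frame
#' coordinates into its reference frame, so its columns are the head axes
#' expressed in that reference frame.
#'
#' @name so3
#' @keywords internal
NULL

.ORTHO_TOL <- 1e-8

#' Test whether a matrix is a valid rotation
#'
#' A matrix qualifies when \code{t(R) \%*\% R} is within \code{tol} of the
#' identity in Frobenius norm and \code{det(R)} is within \code{tol} of 1.
#'
#' @param R a 3x3 numeric matrix.
#' @param tol orthogonality tolerance (Frobenius norm); default 1e-8.
#' @return logical scalar.
#' @export
is_rotation <- function(R, tol = .ORTHO_TOL) {
  if (!is.matrix(R) || !all(dim(R) == c(3L, 3L)) || !is.numeric(R) ||
      anyNA(R) || any(!is.finite(R))) {
    return(FALSE)
  }
  d <- crossprod(R) - diag(3)
  sqrt(sum(d^2)) <= tol && abs(det(R) - 1) <= tol
}

.check_rotation <- function(R, arg = "R") {
  if (!is_rotation(R)) {
    stop("'", arg, "' is not a valid rotation matrix (orthogonality/",
         "determinant tolerance 1e-8); pass corrupt data through ",
         "project_rotation() explicitly", call. = FALSE)
  }
  invisible(R)
}

#' Project a matrix onto the rotation group
#'
#' Returns the special-orthogonal matrix nearest to \code{M} in Frobenius
#' norm (via SVD, with the sign of the smallest singular direction flipped
#' when needed to enforce determinant +1). Idempotent on valid rotations.
#'
#' @param M a nonsingular 3x3 numeric matrix.
#' @return a 3x3 rotation matrix.
#' @export
project_rotation <- function(M) {
  if (!is.matrix(M) || !all(dim(M) == c(3L, 3L)) || anyNA(M)) {
    stop("'M' must be a numeric 3x3 matrix without missing values",
         call. = FALSE)
  }
  s <- svd(M)
  if (min(s$d) <= 1e-12 * max(s$d)) {
    stop("singular matrix: orientation data invalid (rank < 3)",
         call. = FALSE)
  }
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    if (abs(s$d[3]) > 1e-8 * s$d[1] && s$d[2] - s$d[3] < 1e-12 * s$d[1]) {
      # nearest SO(3) point not unique; still return the canonical flip
    }
    R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  }
  if (det(R) < 0) {
    stop("input is reflection-dominated: no nearby proper rotation",
         call. = FALSE)
  }
  R
}

#' Logarithm map on SO(3)
#'
#' Principal matrix logarithm, returned as an axis-angle 3-vector (radians)
#' in the tangent space so(3). For rotation angle exactly pi the two-valued
#' branch is resolved deterministically: the axis representation whose first
#' nonzero component is positive is returned.
#'
#' @param R a valid rotation matrix.
#' @return numeric 3-vector with norm in [0, pi].
#' @export
rot_log <- function(R) {
  .check_rotation(R)
  # computed through the unit-quaternion parameterisation, which keeps full
  # precision both near the identity and near angle pi (the trace-acos
  # formula loses half the significant digits at both ends)
  q <- .mat_to_quat(R)
  v <- q[2:4]
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) {
    # first-order: R ~ I + [w]x
    return(c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2)
  }
  theta <- 2 * atan2(nv, q[1])
  axis <- v / nv
  if (pi - theta < 1e-6) {
    # two-valued branch at pi: first nonzero axis component made positive
    nz <- which(abs(axis) > 1e-12)
    if (length(nz) && axis[nz[1]] < 0) axis <- -axis
  }
  theta * axis
}

#' Exponential map on SO(3)
#'
#' Rodrigues closed form: maps an axis-angle tangent vector (radians) to a
#' rotation matrix. \code{rot_exp(c(0,0,0))} is the identity and the rotation
#' angle of the result equals \code{norm(v) mod 2*pi}.
#'
#' @param v numeric 3-vector (radians).
#' @return a 3x3 rotation matrix.
#' @export
rot_exp <- function(v) {
  stopifnot(is.numeric(v), length(v) == 3L, all(is.finite(v)))
  theta <- sqrt(sum(v^2))
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  if (theta < 1e-8) {
    # second-order Taylor, exact to machine precision at this scale
    return(diag(3) + K + 0.5 * (K %*% K))
  }
  diag(3) + sin(theta) / theta * K +
    (1 - cos(theta)) / theta^2 * (K %*% K)
}

#' Geodesic distance between two rotations
#'
#' The minimal angular displacement separating \code{R1} and \code{R2}:
#' \code{acos((tr(t(R1) R2) - 1)/2)}, with the trace argument clamped to
#' [-1, 1]. Symmetric and bi-invariant; value in [0, pi] radians.
#'
#' @param R1,R2 valid rotation matrices.
#' @return angle in radians.
#' @export
rot_dist <- function(R1, R2) {
  .check_rotation(R1, "R1")
  .check_rotation(R2, "R2")
  ca <- (sum(diag(crossprod(R1, R2))) - 1) / 2
  ca <- min(1, max(-1, ca))
  if (ca > 0.7) {
    # equivalent closed form ||R1 - R2||_F = 2 sqrt(2) |sin(theta/2)|,
    # which keeps full precision for small angles where acos(trace) loses
    # half the significant digits
    2 * asin(min(1, sqrt(sum((R1 - R2)^2)) / (2 * sqrt(2))))
  } else {
    acos(ca)
  }
}

#' Relative rotation
#'
#' Returns \code{t(r_from) \%*\% r_to}, the rotation carrying \code{r_from}
#' to \code{r_to}.
#'
#' @param r_from,r_to valid rotation matrices.
#' @return a 3x3 rotation matrix.
#' @export
rot_rel <- function(r_from, r_to) {
  .check_rotation(r_from, "r_from")
  .check_rotation(r_to, "r_to")
  crossprod(r_from, r_to)
}

#' Rotation angle of a single rotation
#'
#' Geodesic distance to the identity, i.e. the rotation magnitude.
#'
#' @param R a valid rotation matrix.
#' @return angle in radians.
#' @export
rot_angle <- function(R) {
  .check_rotation(R)
  ca <- (sum(diag(R)) - 1) / 2
  ca <- min(1, max(-1, ca))
  if (ca > 0.7) {
    2 * asin(min(1, sqrt(sum((R - diag(3))^2)) / (2 * sqrt(2))))
  } else {
    acos(ca)
  }
}

#' Random rotations
#'
#' Without \code{sigma}, draws uniformly (Haar measure) on SO(3) via
#' normalised 4-dimensional Gaussian quaternions. With \code{sigma}, draws
#' \code{rot_exp(e)} with \code{e ~ N(0, sigma^2 I3)} — an isotropic
#' tangent-space perturbation with per-axis standard deviation \code{sigma}
#' radians.
#'
#' @param n number of rotations.
#' @param sigma optional concentration (radians, per tangent axis); 0 gives
#'   the identity.
#' @return a single 3x3 matrix when \code{n = 1}, else a 3x3xn array.
#' @export
rand_rotation <- function(n = 1L, sigma = NULL) {
  stopifnot(n >= 1L)
  if (!is.null(sigma) && sigma < 0) stop("'sigma' must be >= 0", call. = FALSE)
  out <- array(0, c(3, 3, n))
  for (i in seq_len(n)) {
    if (is.null(sigma)) {
      q <- stats::rnorm(4)
      q <- q / sqrt(sum(q^2))
      out[, , i] <- .quat_to_mat(q)
    } else if (sigma == 0) {
      out[, , i] <- diag(3)
    } else {
      out[, , i] <- rot_exp(stats::rnorm(3, sd = sigma))
    }
  }
  if (n == 1L) out[, , 1] else out
}

# unit quaternion (w, x, y, z) -> rotation matrix
.quat_to_mat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

# rotation matrix -> unit quaternion (w >= 0); internal oracle helper
.mat_to_quat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

#' Elementary axis rotations
#'
#' @param deg angle in degrees.
#' @return a 3x3 rotation matrix.
#' @export
rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' @rdname rot_x
#' @export
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' @rdname rot_x
#' @export
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Euler angles for display
#'
#' Intrinsic z-y'-x'' (yaw-pitch-roll) decomposition, degrees. This
#' convention is for visualisation and human-readable summaries only; all
#' computation in the package stays on rotation matrices. Within 1 degree of
#' gimbal lock (|pitch| >= 89 deg) the decomposition is degenerate: roll is
#' set to 0 and the result is flagged.
#'
#' @param R a valid rotation matrix.
#' @return named numeric vector (yaw, pitch, roll) in degrees, with
#'   attribute \code{gimbal_lock} (logical).
#' @export
euler_from_rotation <- function(R) {
  .check_rotation(R)
  sp <- -R[3, 1]
  sp <- min(1, max(-1, sp))
  pitch <- asin(sp)
  lock <- abs(pitch) >= 89 * pi / 180
  if (lock) {
    roll <- 0
    yaw <- atan2(-R[1, 2], R[2, 2])
  } else {
    yaw <- atan2(R[2, 1], R[1, 1])
    roll <- atan2(R[3, 2], R[3, 3])
  }
  out <- c(yaw = yaw, pitch = pitch, roll = roll) * 180 / pi
  attr(out, "gimbal_lock") <- lock
  out
}

#' @rdname euler_from_rotation
#' @param yaw,pitch,roll angles in degrees.
#' @export
rotation_from_euler <- function(yaw, pitch, roll) {
  rot_z(yaw) %*% rot_y(pitch) %*% rot_x(roll)
}
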